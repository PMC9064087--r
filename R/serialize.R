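#' Serialize and restore fitted topic models
#'
#' A fit is written as a directory of plain-text artifacts: `phi.tsv`
#' (topics x genes with a gene header and topic row names), `theta.tsv`
#' (cells x topics), and `model.json` carrying priors, seed, fixed mask,
#' convergence state and the ELBO trace. Numbers are written with full
#' precision so a rerun with the same configuration and seed reproduces
#' the files byte for byte.
#'
#' @param fit A `topic_fit`.
#' @param path Output directory (created if needed).
#' @return `path` (write) / a `topic_fit` (read).
#' @export
write_topic_fit <- function(fit, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_named_matrix(fit$phi, file.path(path, "phi.tsv"), "topic")
  write_named_matrix(fit$theta, file.path(path, "theta.tsv"), "cell_id")
  meta <- list(alpha = fit$alpha, beta = fit$beta,
               fixed_mask = fit$fixed_mask, seed = fit$seed,
               n_iter = fit$n_iter, converged = fit$converged,
               elbo_trace = fit$elbo_trace,
               cell_labels = as.list(fit$cell_labels %||% list()))
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_named_matrix <- function(m, path, id_col) {
  df <- data.frame(id = rownames(m),
                   format(m, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_topic_fit
#' @export
read_topic_fit <- function(path) {
  phi <- read_named_matrix(file.path(path, "phi.tsv"))
  theta <- read_named_matrix(file.path(path, "theta.tsv"))
  meta <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
  labels <- NULL
  if (length(meta$cell_labels))
    labels <- unlist(meta$cell_labels)
  structure(list(phi = phi, theta = theta,
                 gamma = NULL,
                 fixed_mask = as.logical(meta$fixed_mask),
                 alpha = as.numeric(meta$alpha), beta = as.numeric(meta$beta),
                 elbo_trace = as.numeric(meta$elbo_trace),
                 n_iter = as.integer(meta$n_iter),
                 converged = isTRUE(meta$converged),
                 seed = as.integer(meta$seed),
                 cell_ids = rownames(theta), gene_ids = colnames(phi),
                 cell_labels = labels),
            class = "topic_fit")
}

read_named_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
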