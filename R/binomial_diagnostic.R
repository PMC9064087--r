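#' Reference-only cell-topic weights
#'
#' Builds the reference-only explanation of each cell: the new-topic
#' columns of the cell-topic matrix are set to 0 and each row is
#' renormalized to sum to 1. Cells whose entire weight sits on new topics
#' cannot be renormalized and are flagged (`all_new`) rather than divided
#' by zero.
#'
#' @param fit A `topic_fit` from [fit_lda_fixed()] (new topics are the
#'   non-fixed ones), or any `topic_fit` with `new_topics` given.
#' @param new_topics Indices (or names) of the new topics; defaults to the
#'   non-fixed topics of the fit.
#' @return A list with `delta` (cells x topics matrix, new columns all 0)
#'   and logical `all_new` per cell.
#' @export
reference_only_weights <- function(fit, new_topics = NULL) {
  theta <- fit$theta
  idx <- resolve_new_topics(fit, new_topics)
  if (length(idx) >= ncol(theta))
    abort("`new_topics` cannot cover every topic.")
  delta <- theta
  delta[, idx] <- 0
  mass <- rowSums(delta)
  all_new <- mass <= 0
  delta[!all_new, ] <- delta[!all_new, , drop = FALSE] / mass[!all_new]
  list(delta = delta, all_new = all_new)
}

resolve_new_topics <- function(fit, new_topics) {
  if (is.null(new_topics)) {
    idx <- which(!fit$fixed_mask)
    if (!length(idx) || all(!fit$fixed_mask))
      abort("Fit has no fixed topics; supply `new_topics` explicitly.")
    return(idx)
  }
  if (is.character(new_topics)) {
    idx <- match(new_topics, rownames(fit$phi))
    if (anyNA(idx)) abort("Unknown topic name in `new_topics`.")
    return(idx)
  }
  as.integer(new_topics)
}

#' Mixture of binomial tail probabilities
#'
#' For observed count `x` out of `n` total counts in a cell, computes
#' `sum_k weights[k] * P(Binomial(n, probs[k]) >= x)` via the numerically
#' stable survival function. This is the probability, under a weighted
#' mixture of per-topic binomials, of seeing the observed count or more.
#'
#' @param x Non-negative integer count for the gene (`x <= n`).
#' @param n Positive integer total count for the cell.
#' @param probs Per-topic success probabilities for the gene (length K).
#' @param weights Topic weights summing to 1 (theta or delta row).
#' @return A probability in `[0, 1]`.
#' @export
mixture_tail <- function(x, n, probs, weights) {
  stopifnot(length(probs) == length(weights))
  if (x > n)
    abort("Gene count exceeds the cell total.",
          class = "pictopics_validation_error")
  if (x <= 0) return(1)
  sum(weights * pbinom(x - 1, n, probs, lower.tail = FALSE))
}

#' Compare full-model and reference-only explanations of a gene
#'
#' The diagnostic behind the need for new topics: for each cell, the
#' probability of observing the gene's count or more is computed under a
#' mixture of per-topic binomials weighted by the full cell-topic weights
#' (`p_theta`, all topics) and by the reference-only weights (`p_delta`,
#' new topics zeroed and renormalized). For a gene upregulated by
#' interaction, `p_theta` should exceed `p_delta`; for an unaffected gene
#' the two should be similar. Fractional counts (from injection) are
#' ceiled, which keeps the binomial argument integral and the tail
#' conservative. Cells whose weight is entirely on new topics are excluded
#' (they have no reference-only explanation).
#'
#' @param fit A `topic_fit` from [fit_lda_fixed()].
#' @param cm The [count_matrix()] the fit was computed on.
#' @param gene Gene id (or index).
#' @param cells `"expressed"` (default: cells with nonzero count for the
#'   gene) or `"all"`.
#' @param new_topics See [reference_only_weights()].
#' @return A tibble with columns `cell_id`, `x`, `n`, `p_theta`,
#'   `p_delta`.
#' @export
compare_models_for_gene <- function(fit, cm, gene,
                                    cells = c("expressed", "all"),
                                    new_topics = NULL) {
  cells <- match.arg(cells)
  cm <- align_to_fit(cm, fit)
  g <- if (is.character(gene)) match(gene, fit$gene_ids) else as.integer(gene)
  if (is.na(g)) abort(paste0("Unknown gene: ", gene))
  ro <- reference_only_weights(fit, new_topics)
  counts <- cm$counts[, g]
  totals <- Matrix::rowSums(cm$counts)
  use <- !ro$all_new & (if (cells == "expressed") counts > 0 else totals > 0)
  idx <- which(use)
  pg <- fit$phi[, g]
  rows <- purrr::map(idx, function(d) {
    x <- unname(ceiling(counts[d]))
    n <- unname(ceiling(totals[d]))
    tibble(cell_id = fit$cell_ids[d], x = x, n = n,
           p_theta = mixture_tail(x, n, pg, fit$theta[d, ]),
           p_delta = mixture_tail(x, n, pg, ro$delta[d, ]))
  })
  dplyr::bind_rows(rows)
}

#' @describeIn compare_models_for_gene Strip plot of per-cell tail
#'   probabilities under the two models for one or more genes.
#' @param genes Character vector of gene ids.
#' @export
plot_tail_comparison <- function(fit, cm, genes, new_topics = NULL) {
  df <- dplyr::bind_rows(lapply(genes, function(g) {
    out <- compare_models_for_gene(fit, cm, g, new_topics = new_topics)
    out$gene_id <- g
    out
  }))
  long <- tidyr::pivot_longer(df, c("p_theta", "p_delta"),
                              names_to = "model", values_to = "tail_prob")
  ggplot2::ggplot(long, ggplot2::aes(.data$model, .data$tail_prob)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3, colour = "red") +
    ggplot2::facet_wrap(~gene_id) +
    ggplot2::labs(x = NULL, y = "P(X >= x)")
}
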