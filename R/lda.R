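#' Fit a latent Dirichlet allocation topic model on counts
#'
#' Cells play the role of documents and genes the role of words: each cell
#' is a mixture over `K` topics (`theta`, rows of the cell-topic matrix)
#' and each topic is a probability distribution over genes (`phi`). The
#' model is fitted by mean-field variational EM: per-cell Dirichlet
#' variational parameters are updated by coordinate ascent (compiled
#' E-step) and the topic-gene rows by a smoothed M-step
#' `phi ~ sufficient statistics + beta`. With that pairing every step is an
#' exact ascent of the tracked evidence lower bound, so the ELBO trace is
#' non-decreasing up to floating point.
#'
#' Counts may be fractional (non-negative); the variational updates only
#' require non-negativity and reduce to standard LDA on integers.
#'
#' @param cm A [count_matrix()] (cells x genes).
#' @param K Number of topics (`>= 1`, at most the number of cells).
#' @param alpha Symmetric Dirichlet prior on cell-topic weights; scalar or
#'   length-`K` vector. Default `1/K`.
#' @param beta Topic-gene smoothing pseudocount (scalar). Default `0.01`.
#' @param seed Integer seed controlling topic initialization.
#' @param tol Relative ELBO change at which EM stops. Default `1e-6`.
#' @param max_iter Maximum EM iterations. Default `500`.
#' @param n_starts Number of random restarts; the fit with the highest
#'   final ELBO is kept (variational EM only finds local optima, and
#'   restart selection by the bound is the standard remedy). Restart `i`
#'   initializes from `seed + 1000 * (i - 1)`. Default 1.
#' @param inner_tol,inner_max Per-cell E-step convergence controls.
#' @param verbose Print the ELBO each iteration.
#'
#' @return An object of class `topic_fit` with elements `phi` (K x V,
#'   rows sum to 1), `theta` (cells x K, rows sum to 1), `gamma`,
#'   `fixed_mask`, `alpha`, `beta`, `elbo_trace`, `n_iter`, `converged`,
#'   `seed`, plus the cell/gene ids and labels of `cm`.
#' @seealso [fit_lda_fixed()] for the second-stage fit with frozen topics,
#'   [tidy.topic_fit()], [perplexity()].
#' @export
fit_lda <- function(cm, K, alpha = 1 / K, beta = 0.01, seed = 1,
                    tol = 1e-6, max_iter = 500, n_starts = 1,
                    inner_tol = 1e-3, inner_max = 20, verbose = FALSE) {
  stopifnot(inherits(cm, "count_matrix"), K >= 1, n_starts >= 1)
  if (K > nrow(cm$counts))
    abort("`K` cannot exceed the number of cells.")
  V <- ncol(cm$counts)
  fit <- best_of_starts(seed, n_starts, function(s) {
    set.seed(s)
    phi0 <- matrix(rgamma(K * V, 1), K, V)
    phi0 <- phi0 / rowSums(phi0)
    lda_engine(cm, phi0, fixed_mask = rep(FALSE, K), alpha = alpha,
               beta = beta, tol = tol, max_iter = max_iter,
               inner_tol = inner_tol, inner_max = inner_max,
               verbose = verbose)
  })
  rownames(fit$phi) <- sprintf("topic%02d", seq_len(K))
  colnames(fit$theta) <- rownames(fit$phi)
  fit
}

# Run the fitting closure once per restart seed and keep the best ELBO.
best_of_starts <- function(seed, n_starts, fit_one) {
  best <- NULL
  for (i in seq_len(n_starts)) {
    s <- as.integer((as.numeric(seed) + 1000 * (i - 1)) %%
                      .Machine$integer.max)
    fit <- fit_one(s)
    fit$seed <- s
    if (is.null(best) ||
        tail(fit$elbo_trace, 1) > tail(best$elbo_trace, 1))
      best <- fit
  }
  best
}

#' Fit additional topics with reference topic-gene rows frozen
#'
#' The second stage of the two-stage workflow: the topic-gene rows learned
#' on a non-interacting reference population are held fixed (excluded from
#' the M-step) while `K_new` free topics are fitted on an interacting
#' population. Cell-topic weights are estimated over all
#' `K_ref + K_new` topics, so any expression the reference topics cannot
#' explain is pushed into the new topics.
#'
#' Gene axes are aligned first: gene ids are intersected (reference order),
#' the interacting matrix is subset to the shared genes, and the fixed rows
#' are renormalized over the shared vocabulary. When the two gene axes are
#' already identical the reference rows are carried over bit-identically.
#'
#' @param cm A [count_matrix()] of the interacting population.
#' @param reference A `topic_fit` from [fit_lda()] on the reference
#'   population.
#' @param K_new Number of free topics to add. Default 5.
#' @param alpha Dirichlet prior over all `K_ref + K_new` topics; default
#'   `1/(K_ref + K_new)`.
#' @inheritParams fit_lda
#'
#' @return A `topic_fit` over `K_ref + K_new` topics; `fixed_mask` is
#'   `TRUE` for the reference rows, whose names are kept, while new topics
#'   are named `new01`, `new02`, ...
#' @export
fit_lda_fixed <- function(cm, reference, K_new = 5,
                          alpha = 1 / (nrow(reference$phi) + K_new),
                          beta = 0.01, seed = 1, tol = 1e-6, max_iter = 500,
                          n_starts = 1, inner_tol = 1e-3, inner_max = 20,
                          verbose = FALSE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(reference, "topic_fit"),
            K_new >= 1)
  shared <- intersect(reference$gene_ids, cm$gene_ids)
  if (length(shared) < 2)
    abort("Fewer than 2 genes shared between reference and data.",
          class = "pictopics_alignment_error")
  n_dropped <- length(cm$gene_ids) - length(shared)
  if (n_dropped > 0)
    message(sprintf("Dropping %d genes absent from the reference vocabulary.",
                    n_dropped))
  identical_axis <- identical(reference$gene_ids, cm$gene_ids)
  if (!identical_axis)
    cm <- subset_count_matrix(cm, genes = match(shared, cm$gene_ids))
  phi_ref <- reference$phi
  if (!identical_axis) {
    phi_ref <- phi_ref[, match(shared, reference$gene_ids), drop = FALSE]
    phi_ref <- phi_ref / rowSums(phi_ref)
  }
  K_ref <- nrow(phi_ref)
  V <- ncol(cm$counts)
  fit <- best_of_starts(seed, n_starts, function(s) {
    set.seed(s)
    phi_new <- matrix(rgamma(K_new * V, 1), K_new, V)
    phi_new <- phi_new / rowSums(phi_new)
    phi0 <- rbind(phi_ref, phi_new)
    lda_engine(cm, phi0,
               fixed_mask = c(rep(TRUE, K_ref), rep(FALSE, K_new)),
               alpha = alpha, beta = beta, tol = tol,
               max_iter = max_iter, inner_tol = inner_tol,
               inner_max = inner_max, verbose = verbose)
  })
  rownames(fit$phi) <- c(rownames(phi_ref) %||%
                           sprintf("topic%02d", seq_len(K_ref)),
                         sprintf("new%02d", seq_len(K_new)))
  colnames(fit$theta) <- rownames(fit$phi)
  fit$reference_phi <- phi_ref
  fit
}

# Shared variational EM loop; phi rows with fixed_mask TRUE are never
# touched by the M-step.
lda_engine <- function(cm, phi, fixed_mask, alpha, beta, tol, max_iter,
                       inner_tol, inner_max, verbose = FALSE) {
  X <- cm$counts
  if (length(X@x) == 0)
    abort("Count matrix has no nonzero entries.")
  K <- nrow(phi)
  D <- nrow(X)
  alpha <- rep_len(alpha, K)
  if (any(alpha <= 0) || beta <= 0)
    abort("Dirichlet priors must be strictly positive.")
  Xt <- methods::as(Matrix::t(X), "CsparseMatrix") # genes x cells, CSC = per-cell
  doc_tot <- Matrix::rowSums(X)
  gamma <- outer(doc_tot / K, rep(1, K)) + rep(alpha, each = D)
  free <- !fixed_mask
  elbo_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    es <- lda_estep_cpp(Xt@p, Xt@i, Xt@x, phi, gamma, alpha,
                        as.integer(inner_max), inner_tol)
    gamma <- es$gamma
    elbo <- es$token_ll + dirichlet_theta_terms(gamma, alpha) +
      if (any(free)) beta * sum(log(phi[free, , drop = FALSE])) else 0
    elbo_trace <- c(elbo_trace, elbo)
    if (verbose) message(sprintf("iter %d: elbo %.4f", it, elbo))
    # M-step (free rows only)
    if (any(free)) {
      ss <- es$sstats[free, , drop = FALSE] + beta
      phi[free, ] <- ss / rowSums(ss)
    }
    if (it >= 2) {
      prev <- elbo_trace[it - 1]
      if (abs(elbo - prev) / max(abs(prev), 1e-10) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  theta <- gamma / rowSums(gamma)
  rownames(theta) <- cm$cell_ids
  colnames(phi) <- cm$gene_ids
  structure(list(phi = phi, theta = theta, gamma = gamma,
                 fixed_mask = fixed_mask, alpha = alpha, beta = beta,
                 elbo_trace = elbo_trace, n_iter = it, converged = converged,
                 seed = NA_integer_, cell_ids = cm$cell_ids,
                 gene_ids = cm$gene_ids, cell_labels = cm$cell_labels),
            class = "topic_fit")
}

dirichlet_theta_terms <- function(gamma, alpha) {
  D <- nrow(gamma)
  elog <- digamma(gamma) - digamma(rowSums(gamma))
  sum((rep(alpha, each = D) - gamma) * elog) +
    sum(lgamma(gamma)) - sum(lgamma(rowSums(gamma))) +
    D * (lgamma(sum(alpha)) - sum(lgamma(alpha)))
}

#' @export
print.topic_fit <- function(x, ...) {
  cat(sprintf(
    "<topic_fit> %d topics (%d fixed) x %d genes on %d cells\n",
    nrow(x$phi), sum(x$fixed_mask), ncol(x$phi), nrow(x$theta)))
  cat(sprintf("  ELBO %.2f after %d iterations (%s)\n",
              tail(x$elbo_trace, 1), x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Tidy a fitted topic model
#'
#' Mirrors the tidiers for topic models elsewhere in the ecosystem:
#' `matrix = "phi"` returns one row per (topic, gene) with the topic-gene
#' probability; `matrix = "theta"` one row per (cell, topic) with the
#' cell-topic weight.
#'
#' @param x A `topic_fit`.
#' @param matrix `"phi"` (topic-gene) or `"theta"` (cell-topic).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy topic_fit
#' @export
tidy.topic_fit <- function(x, matrix = c("phi", "theta"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "phi") {
    tibble(topic = rep(rownames(x$phi), times = ncol(x$phi)),
           gene_id = rep(colnames(x$phi), each = nrow(x$phi)),
           prob = as.vector(x$phi),
           fixed = rep(x$fixed_mask, times = ncol(x$phi)))
  } else {
    tibble(cell_id = rep(rownames(x$theta), times = ncol(x$theta)),
           topic = rep(colnames(x$theta), each = nrow(x$theta)),
           weight = as.vector(x$theta))
  }
}

#' @rdname tidy.topic_fit
#' @return For `glance()`: a one-row tibble with topic counts, dimensions,
#'   final ELBO and convergence information.
#' @method glance topic_fit
#' @export
glance.topic_fit <- function(x, ...) {
  tibble(k = nrow(x$phi), k_fixed = sum(x$fixed_mask),
         n_cells = nrow(x$theta), n_genes = ncol(x$phi),
         elbo = tail(x$elbo_trace, 1), n_iter = x$n_iter,
         converged = x$converged)
}

new_topics <- function(fit) which(!fit$fixed_mask)

#' Per-token topic posterior
#'
#' For one gene's counts in one cell, the posterior probability over topics
#' of having generated those counts: `r_k` proportional to
#' `theta[cell, k] * phi[k, gene]`. When the normalizer is zero a uniform
#' vector is returned with the `degenerate` column set, so downstream
#' ranking can skip such tokens deterministically.
#'
#' @param fit A `topic_fit`.
#' @param cell,gene Cell and gene, by id or index.
#' @return A tibble with columns `topic`, `posterior`, `degenerate`.
#' @export
token_posterior <- function(fit, cell, gene) {
  d <- if (is.character(cell)) match(cell, fit$cell_ids) else as.integer(cell)
  g <- if (is.character(gene)) match(gene, fit$gene_ids) else as.integer(gene)
  if (is.na(d) || d < 1 || d > nrow(fit$theta)) abort("Unknown cell.")
  if (is.na(g) || g < 1 || g > ncol(fit$phi)) abort("Unknown gene.")
  r <- fit$theta[d, ] * fit$phi[, g]
  s <- sum(r)
  degenerate <- s <= 0
  r <- if (degenerate) rep(1 / length(r), length(r)) else r / s
  tibble(topic = rownames(fit$phi), posterior = unname(r),
         degenerate = degenerate)
}

#' Infer cell-topic weights for new cells under a fitted model
#'
#' Runs the variational E-step with the topic-gene rows held at their
#' fitted values. Used for held-out perplexity.
#'
#' @inheritParams fit_lda
#' @param fit A `topic_fit`.
#' @return A cells x K matrix of topic weights (rows sum to 1).
#' @export
infer_theta <- function(fit, cm, inner_tol = 1e-3, inner_max = 20) {
  cm <- align_to_fit(cm, fit)
  K <- nrow(fit$phi)
  D <- nrow(cm$counts)
  Xt <- methods::as(Matrix::t(cm$counts), "CsparseMatrix")
  gamma <- outer(Matrix::rowSums(cm$counts) / K, rep(1, K)) +
    rep(fit$alpha, each = D)
  for (i in 1:20) {
    es <- lda_estep_cpp(Xt@p, Xt@i, Xt@x, fit$phi, gamma, fit$alpha,
                        as.integer(inner_max), inner_tol)
    if (max(abs(es$gamma - gamma)) < 1e-6 * (1 + max(gamma))) {
      gamma <- es$gamma
      break
    }
    gamma <- es$gamma
  }
  theta <- gamma / rowSums(gamma)
  dimnames(theta) <- list(cm$cell_ids, rownames(fit$phi))
  theta
}

align_to_fit <- function(cm, fit) {
  if (identical(cm$gene_ids, fit$gene_ids)) return(cm)
  shared <- intersect(fit$gene_ids, cm$gene_ids)
  if (!identical(shared, fit$gene_ids))
    abort("Count matrix lacks genes present in the fitted model.")
  subset_count_matrix(cm, genes = match(shared, cm$gene_ids))
}

#' Model perplexity on a count matrix
#'
#' Exponentiated negative per-token log-likelihood,
#' `exp(-sum(x * log(theta %*% phi)) / sum(x))`, using the fitted per-cell
#' topic weights (plug-in token likelihood). Lower is better; under a
#' uniform topic-gene model the perplexity equals the vocabulary size
#' exactly. With `newdata = TRUE` (or when `cm`'s cells differ from the
#' fitted ones) topic weights for `cm` are first inferred with the topics
#' held fixed, giving a held-out variant.
#'
#' @param fit A `topic_fit`.
#' @param cm The [count_matrix()] to score.
#' @param newdata Force re-inference of topic weights for `cm`.
#' @return A positive scalar.
#' @export
perplexity <- function(fit, cm, newdata = !identical(cm$cell_ids, fit$cell_ids)) {
  stopifnot(inherits(fit, "topic_fit"), inherits(cm, "count_matrix"))
  cm <- align_to_fit(cm, fit)
  if (length(cm$counts@x) == 0) abort("Count matrix has no counts.")
  theta <- if (newdata) infer_theta(fit, cm) else fit$theta
  Xt <- methods::as(Matrix::t(cm$counts), "TsparseMatrix")
  i <- Xt@j + 1L   # cells
  j <- Xt@i + 1L   # genes
  p <- rowSums(theta[i, , drop = FALSE] * t(fit$phi)[j, , drop = FALSE])
  exp(-sum(Xt@x * log(p)) / sum(Xt@x))
}
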