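#' Metrics for choosing the number of topics
#'
#' Fits the model over a grid of topic numbers (seed derived as
#' `seed + K` per fit) and records, per `K`: training perplexity, the mean
#' cosine similarity over all unordered pairs of topic-gene rows, and the
#' mean Jensen-Shannon divergence over the same pairs (natural log, so
#' bounded by `log(2)`). Perplexity typically drops steeply and then
#' flattens; the flattening point is the usual choice of `K`. Cosine and JS
#' follow the same pattern and serve as redundancy checks: topics that
#' collapse onto each other push cosine up and JS down.
#'
#' @inheritParams fit_lda
#' @param K_values Ascending integer vector of topic numbers, minimum 2.
#' @param heldout Optional [count_matrix()] on which perplexity is computed
#'   instead of the training data.
#' @return A tibble of class `selection_curve` with columns `K`,
#'   `perplexity`, `mean_cosine`, `mean_js` and `error` (NA unless the fit
#'   for that `K` failed, in which case the message is recorded and the
#'   sweep continues).
#' @export
selection_curve <- function(cm, K_values = 2:15, alpha = NULL, beta = 0.01,
                            seed = 1, tol = 1e-6, max_iter = 500,
                            heldout = NULL) {
  stopifnot(all(diff(K_values) > 0), min(K_values) >= 2)
  rows <- purrr::map(K_values, function(K) {
    res <- tryCatch({
      fit <- fit_lda(cm, K, alpha = alpha %||% (1 / K), beta = beta,
                     seed = seed + K, tol = tol, max_iter = max_iter)
      perp <- if (is.null(heldout)) perplexity(fit, cm, newdata = FALSE)
              else perplexity(fit, heldout, newdata = TRUE)
      tibble(K = K, perplexity = perp,
             mean_cosine = mean_pairwise_cosine(fit$phi),
             mean_js = mean_pairwise_js(fit$phi), error = NA_character_)
    }, error = function(e) {
      tibble(K = K, perplexity = NA_real_, mean_cosine = NA_real_,
             mean_js = NA_real_, error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("selection_curve", class(out))
  out
}

mean_pairwise_cosine <- function(phi) {
  if (nrow(phi) < 2) return(NA_real_)
  nrm <- phi / sqrt(rowSums(phi^2))
  cs <- tcrossprod(nrm)
  mean(cs[upper.tri(cs)])
}

js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

mean_pairwise_js <- function(phi) {
  K <- nrow(phi)
  if (K < 2) return(NA_real_)
  pairs <- utils::combn(K, 2)
  mean(apply(pairs, 2, function(ij) js_divergence(phi[ij[1], ], phi[ij[2], ])))
}

#' Suggest a number of topics from a selection curve
#'
#' Returns the smallest `K` after which the relative perplexity improvement
#' to the next grid point falls below `flatten_frac` — a thresholded
#' version of reading the elbow off the perplexity plot. Invariant to
#' rescaling all perplexities by a positive constant. If the curve never
#' flattens the largest `K` is returned with a warning.
#'
#' @param curve A [selection_curve()] (or any data frame with columns `K`
#'   and `perplexity`), at least 3 points.
#' @param flatten_frac Relative-improvement threshold. Default `0.02`.
#' @return A single integer.
#' @export
suggest_K <- function(curve, flatten_frac = 0.02) {
  ok <- !is.na(curve$perplexity)
  K <- curve$K[ok]
  perp <- curve$perplexity[ok]
  if (length(K) < 3) abort("Need at least 3 successful fits.")
  for (i in seq_len(length(K) - 1)) {
    improvement <- (perp[i] - perp[i + 1]) / perp[i]
    if (improvement < flatten_frac) return(K[i])
  }
  warn("Perplexity never flattens over the tested grid; returning max K.")
  K[length(K)]
}

#' @describeIn selection_curve Line plots of perplexity, mean pairwise
#'   cosine and mean pairwise JS against `K`.
#' @param object A `selection_curve`.
#' @param ... Unused.
#' @method autoplot selection_curve
#' @export
autoplot.selection_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("K", "perplexity", "mean_cosine", "mean_js")],
    -"K", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$K, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "number of topics", y = NULL)
}
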