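#' Recovery (ROC-style) curve for a gene ranking
#'
#' Scores new-topic gene rankings against a ground-truth gene set over a
#' grid of per-topic cutoffs. At cutoff `N` the predicted set is
#' [top_genes()] with `top_n = N`; TPR is the recovered fraction of the
#' truth and FPR the fraction of non-truth universe genes predicted. AUC
#' is the trapezoid over (FPR, TPR) with the curve padded to (0, 0) and
#' (1, 1). Genes on `exclude` are removed from FPR accounting (useful when
#' nominal false positives are plausibly real) without joining the truth.
#'
#' @param rankings A [rank_genes()] tibble.
#' @param truth Ground-truth gene ids (must be a subset of `universe`).
#' @param universe All genes eligible for ranking (typically the genes
#'   surviving preprocessing in the interacting matrix).
#' @param cutoffs Ascending integer grid of per-topic cutoffs. Default
#'   `1:50`.
#' @param exclude Optional gene ids excluded from FPR accounting.
#' @return A tibble of class `recovery_curve` with columns `cutoff`,
#'   `n_predicted`, `tp`, `fp`, `tpr`, `fpr`; attributes `auc`,
#'   `truth_size`, `universe_size`.
#' @export
recovery_curve <- function(rankings, truth, universe, cutoffs = 1:50,
                           exclude = NULL) {
  truth <- unique(truth)
  if (!length(truth)) abort("`truth` must be nonempty.")
  if (length(setdiff(truth, universe)))
    abort("`truth` must be a subset of `universe`.")
  stopifnot(all(diff(cutoffs) > 0))
  negatives <- setdiff(setdiff(universe, truth), exclude)
  rows <- purrr::map(cutoffs, function(N) {
    pred <- top_genes(rankings, N)
    tp <- length(intersect(pred, truth))
    fp <- length(setdiff(setdiff(pred, truth), exclude))
    tibble(cutoff = N, n_predicted = length(pred), tp = tp, fp = fp,
           tpr = tp / length(truth),
           fpr = if (length(negatives)) fp / length(negatives) else 0)
  })
  out <- dplyr::bind_rows(rows)
  auc <- trapezoid_auc(c(0, out$fpr, 1), c(0, out$tpr, 1))
  attr(out, "auc") <- auc
  attr(out, "truth_size") <- length(truth)
  attr(out, "universe_size") <- length(universe)
  class(out) <- c("recovery_curve", class(out))
  out
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  fpr <- fpr[o]
  tpr <- tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' @rdname recovery_curve
#' @param x A `recovery_curve`.
#' @param ... Unused.
#' @method glance recovery_curve
#' @export
glance.recovery_curve <- function(x, ...) {
  tibble(auc = attr(x, "auc"), truth_size = attr(x, "truth_size"),
         universe_size = attr(x, "universe_size"),
         max_tpr = max(x$tpr))
}

#' @rdname recovery_curve
#' @param object A `recovery_curve`.
#' @method autoplot recovery_curve
#' @export
autoplot.recovery_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc")))
}

#' Smallest per-topic cutoff recovering the full truth set
#'
#' Scans cutoffs upward and returns the smallest `N` for which
#' `top_genes(rankings, N)` contains every truth gene, or `Inf` when some
#' truth gene appears in no ranking at all.
#'
#' @inheritParams recovery_curve
#' @return A single integer, or `Inf`.
#' @export
min_cutoff_full_recovery <- function(rankings, truth) {
  truth <- unique(truth)
  if (!length(truth)) abort("`truth` must be nonempty.")
  if (!all(truth %in% rankings$gene_id)) return(Inf)
  hits <- dplyr::filter(rankings, .data$gene_id %in% truth)
  best <- dplyr::summarise(dplyr::group_by(hits, .data$gene_id),
                           best_rank = min(.data$rank), .groups = "drop")
  max(best$best_rank)
}
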