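#' Associate topics with cell types
#'
#' For every (topic, cell-type label) pair, compares the topic's per-cell
#' weights in that label's cells against all other cells with a two-sided
#' Mann-Whitney U test (exact for small untied groups, normal approximation
#' with tie correction otherwise; with exactly two labels this is the plain
#' two-group comparison). All (topic, label) p-values are corrected jointly
#' with Benjamini-Hochberg. The `direction` column marks whether the topic
#' runs higher or lower in the labelled group, so cell-type-specific topics
#' are identifiable directly.
#'
#' @param fit A `topic_fit`, or a cells x topics weight matrix.
#' @param labels Named character vector mapping cell ids to labels; defaults
#'   to the labels carried by the fit.
#' @param alpha Benjamini-Hochberg level. Default 0.05.
#' @return A tibble with columns `topic`, `label`, `n_cells`, `statistic`
#'   (U for the labelled group), `p_value`, `p_adjusted`, `significant`,
#'   `direction` (`"higher"`/`"lower"`) and `untestable` (groups with fewer
#'   than 2 cells are flagged rather than dropped).
#' @export
topic_celltype_association <- function(fit, labels = NULL, alpha = 0.05) {
  theta <- if (inherits(fit, "topic_fit")) fit$theta else as.matrix(fit)
  if (is.null(labels) && inherits(fit, "topic_fit"))
    labels <- fit$cell_labels
  if (is.null(labels)) abort("No cell labels available.")
  labels <- labels[intersect(rownames(theta), names(labels))]
  theta <- theta[names(labels), , drop = FALSE]
  groups <- unique(labels)
  if (length(groups) < 2) abort("Need at least 2 distinct labels.")
  grid <- tidyr::expand_grid(topic = colnames(theta), label = groups)
  rows <- purrr::pmap(grid, function(topic, label) {
    in_grp <- labels == label
    a <- theta[in_grp, topic]
    b <- theta[!in_grp, topic]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(topic = topic, label = label, n_cells = length(a),
                    statistic = NA_real_, p_value = NA_real_,
                    direction = NA_character_, untestable = TRUE))
    }
    if (length(unique(c(a, b))) == 1) {
      # every value tied: U is central and there is no evidence either way
      return(tibble(topic = topic, label = label, n_cells = length(a),
                    statistic = length(a) * length(b) / 2, p_value = 1,
                    direction = "higher", untestable = FALSE))
    }
    exact <- length(a) <= 20 && length(b) <= 20
    wt <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = exact,
                  correct = FALSE))
    tibble(topic = topic, label = label, n_cells = length(a),
           statistic = unname(wt$statistic), p_value = wt$p.value,
           direction = if (unname(wt$statistic) >= length(a) * length(b) / 2)
             "higher" else "lower",
           untestable = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  adj <- bh_adjust(out$p_value[!out$untestable], alpha = alpha)
  out$p_adjusted <- NA_real_
  out$p_adjusted[!out$untestable] <- adj$adjusted
  out$significant <- FALSE
  out$significant[!out$untestable] <- adj$reject
  out[, c("topic", "label", "n_cells", "statistic", "p_value", "p_adjusted",
          "significant", "direction", "untestable")]
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Standard step-up procedure: `adjusted[i] = min over j with rank >= rank(i)
#' of m * p[(j)] / j`, capped at 1; hypotheses with adjusted p at or below
#' `alpha` are rejected.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs allowed and
#'   passed through).
#' @param alpha Rejection level. Default 0.05.
#' @return A list with `adjusted` and logical `reject`.
#' @export
bh_adjust <- function(pvals, alpha = 0.05) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    abort("p-values must lie in [0, 1].",
          class = "pictopics_validation_error")
  adjusted <- p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= alpha)
}

#' Topic-by-label mean weight heatmap
#'
#' Summarises a fit as the mean cell-topic weight per (topic, label) cell
#' group, as a ggplot tile map.
#'
#' @inheritParams topic_celltype_association
#' @export
plot_topic_heatmap <- function(fit, labels = NULL) {
  theta <- if (inherits(fit, "topic_fit")) fit$theta else as.matrix(fit)
  if (is.null(labels) && inherits(fit, "topic_fit"))
    labels <- fit$cell_labels
  if (is.null(labels)) abort("No cell labels available.")
  df <- tidy_theta_labels(theta, labels)
  summ <- dplyr::summarise(dplyr::group_by(df, .data$topic, .data$label),
                           mean_weight = mean(.data$weight), .groups = "drop")
  ggplot2::ggplot(summ,
                  ggplot2::aes(.data$label, .data$topic,
                               fill = .data$mean_weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean weight") +
    ggplot2::labs(x = NULL, y = NULL)
}

tidy_theta_labels <- function(theta, labels) {
  labels <- labels[intersect(rownames(theta), names(labels))]
  theta <- theta[names(labels), , drop = FALSE]
  tibble(cell_id = rep(rownames(theta), times = ncol(theta)),
         topic = rep(colnames(theta), each = nrow(theta)),
         weight = as.vector(theta),
         label = rep(unname(labels), times = ncol(theta)))
}
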