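#' Count how many cells attribute each gene to each new topic
#'
#' For every (cell, gene) pair with nonzero count, the per-token topic
#' posterior (proportional to `theta[cell, ] * phi[, gene]`) is maximized
#' over ALL topics — reference and new. When the argmax lands on a new
#' topic, that (topic, gene) pair gains one supporting cell. Ties are
#' broken toward the lowest topic index, so a tie between a reference and
#' a new topic counts for the reference (conservative). Degenerate tokens
#' (zero posterior mass) are skipped.
#'
#' @param fit A `topic_fit` from [fit_lda_fixed()].
#' @param cm The [count_matrix()] the fit was computed on.
#' @param new_topics See [reference_only_weights()]; defaults to the
#'   non-fixed topics.
#' @param all_topics Count support for every topic, not only new ones
#'   (used by the partition property that per-gene supports over all topics
#'   sum to the number of cells expressing the gene).
#' @return A tibble with columns `topic`, `gene_id`, `support` (number of
#'   supporting cells); only pairs with positive support appear.
#' @export
count_topic_support <- function(fit, cm, new_topics = NULL,
                                all_topics = FALSE) {
  cm <- align_to_fit(cm, fit)
  idx_new <- if (all_topics) seq_len(nrow(fit$phi))
             else resolve_new_topics(fit, new_topics)
  Xt <- methods::as(Matrix::t(cm$counts), "TsparseMatrix")
  i <- Xt@j + 1L  # cells
  j <- Xt@i + 1L  # genes
  scores <- fit$theta[i, , drop = FALSE] *
    t(fit$phi)[j, , drop = FALSE]
  ok <- rowSums(scores) > 0           # skip degenerate tokens
  winner <- max.col(scores[ok, , drop = FALSE], ties.method = "first")
  keep <- winner %in% idx_new
  if (!any(keep)) {
    return(tibble(topic = character(), gene_id = character(),
                  support = integer()))
  }
  tab <- table(topic = rownames(fit$phi)[winner[keep]],
               gene = j[ok][keep])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  tibble(topic = df$topic,
         gene_id = fit$gene_ids[as.integer(df$gene)],
         support = as.integer(df$Freq))
}

#' Rank genes per new topic by supporting-cell count
#'
#' Genes needing a topic in fewer than `min_cells` cells are filtered out;
#' the rest are ordered by support (descending), ties broken
#' lexicographically by gene id.
#'
#' @param support Output of [count_topic_support()].
#' @param min_cells Minimum supporting cells to keep a gene. Default 10.
#' @return A tibble of class `gene_ranking` with columns `topic`, `rank`,
#'   `gene_id`, `supporting_cells`, carrying `min_cells` as an attribute.
#'   Topics whose ranking is empty simply contribute no rows.
#' @export
rank_genes <- function(support, min_cells = 10) {
  stopifnot(min_cells >= 1)
  kept <- dplyr::filter(support, .data$support >= min_cells)
  kept <- dplyr::arrange(kept, .data$topic, dplyr::desc(.data$support),
                         .data$gene_id)
  kept <- dplyr::mutate(dplyr::group_by(kept, .data$topic),
                        rank = dplyr::row_number())
  out <- dplyr::ungroup(dplyr::select(kept, "topic", "rank", "gene_id",
                                      supporting_cells = "support"))
  attr(out, "min_cells") <- min_cells
  class(out) <- c("gene_ranking", class(out))
  out
}

#' Top genes across new topics
#'
#' Takes the first `top_n` genes from each topic's ranking and unions
#' them, de-duplicating while preserving each gene's best support. The
#' result is ordered by best support (descending), ties broken by gene id.
#'
#' @param rankings A [rank_genes()] tibble.
#' @param top_n Genes to take per topic.
#' @return A character vector of gene ids.
#' @export
top_genes <- function(rankings, top_n) {
  stopifnot(top_n >= 1)
  sel <- dplyr::filter(rankings, .data$rank <= top_n)
  best <- dplyr::summarise(dplyr::group_by(sel, .data$gene_id),
                           best_support = max(.data$supporting_cells),
                           .groups = "drop")
  best <- dplyr::arrange(best, dplyr::desc(.data$best_support),
                         .data$gene_id)
  best$gene_id
}

#' @describeIn rank_genes Bar chart of the top genes per new topic.
#' @param object A `gene_ranking`.
#' @param top_n Genes to display per topic. Default 10.
#' @param ... Unused.
#' @method autoplot gene_ranking
#' @export
autoplot.gene_ranking <- function(object, top_n = 10, ...) {
  df <- dplyr::filter(object, .data$rank <= top_n)
  ggplot2::ggplot(df,
                  ggplot2::aes(.data$supporting_cells,
                               stats::reorder(.data$gene_id,
                                              .data$supporting_cells))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~topic, scales = "free_y") +
    ggplot2::labs(x = "supporting cells", y = NULL)
}
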