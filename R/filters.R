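#' Gene and cell filters
#'
#' Plate-based protocols motivate simple count-based filters applied
#' independently of any clustering pipeline: drop genes detected in too few
#' cells, drop cells with too few detected genes, and drop gene families by
#' identifier pattern (ribosomal genes by default). Two threshold
#' conventions appear in practice and both are supported: the inclusive
#' convention keeps a gene detected in at least `min_cells` cells ("fewer
#' than 200 cells were filtered out"), the strict convention keeps only
#' genes detected in strictly more than `min_cells` cells ("expressed in
#' more than 10 cells").
#'
#' @param cm A [count_matrix()].
#' @param min_cells Detection threshold (number of cells with nonzero
#'   count).
#' @param strict If `FALSE` (default) keep genes detected in `>= min_cells`
#'   cells; if `TRUE` keep genes detected in `> min_cells` cells.
#'
#' @return A filtered [count_matrix()].
#' @name filters
NULL

#' @rdname filters
#' @export
filter_genes_min_cells <- function(cm, min_cells, strict = FALSE) {
  stopifnot(is.numeric(min_cells), min_cells >= 1)
  detected <- Matrix::colSums(cm$counts > 0)
  keep <- if (strict) detected > min_cells else detected >= min_cells
  if (!any(keep))
    abort("All genes removed; lower `min_cells`.",
          class = "pictopics_filter_error")
  subset_count_matrix(cm, genes = which(keep))
}

#' @rdname filters
#' @param min_features Keep cells detected in strictly more than
#'   `min_features` genes ("more than 500 features were retained").
#' @export
filter_cells_min_features <- function(cm, min_features) {
  stopifnot(is.numeric(min_features), min_features >= 1)
  nfeat <- Matrix::rowSums(cm$counts > 0)
  keep <- nfeat > min_features
  if (!any(keep))
    abort("All cells removed; lower `min_features`.",
          class = "pictopics_filter_error")
  subset_count_matrix(cm, cells = which(keep))
}

#' Default ribosomal gene id patterns (mouse and human prefixes).
#' @export
ribosomal_patterns <- function() c("^Rps", "^Rpl", "^RPS", "^RPL")

#' @rdname filters
#' @param patterns Character vector of regular expressions; genes whose id
#'   matches any pattern are removed. Matching is case sensitive.
#' @export
exclude_genes_by_pattern <- function(cm, patterns = ribosomal_patterns()) {
  if (!length(patterns)) return(cm)
  hit <- Reduce(`|`, lapply(patterns, function(p) grepl(p, cm$gene_ids)))
  if (!any(hit)) return(cm)
  subset_count_matrix(cm, genes = which(!hit))
}
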