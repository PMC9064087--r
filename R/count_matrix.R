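#' Cells-by-genes count matrix
#'
#' `count_matrix()` wraps a non-negative cells x genes matrix together with
#' unique cell and gene identifiers and optional per-cell labels (cell type,
#' condition, timepoint). Counts are stored sparsely; fractional values are
#' allowed (they arise from count injection in simulations) but negative
#' values are not.
#'
#' @param counts A cells x genes matrix or sparse Matrix of non-negative
#'   counts.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#'   Defaults to the rownames of `counts`.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column. Defaults to the colnames of `counts`.
#' @param cell_labels Optional named character vector (or 2-column data frame
#'   with columns `cell_id`, `label`) mapping cell ids to labels.
#'
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts), cell_labels = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts))
    abort("`cell_ids` length must equal the number of rows of `counts`.")
  if (length(gene_ids) != ncol(counts))
    abort("`gene_ids` length must equal the number of columns of `counts`.")
  if (anyDuplicated(cell_ids)) abort("`cell_ids` must be unique.")
  if (anyDuplicated(gene_ids)) abort("`gene_ids` must be unique.")
  if (length(counts@x) && min(counts@x) < 0)
    abort("Counts must be non-negative.", class = "pictopics_validation_error")
  if (length(counts@x) && any(!is.finite(counts@x)))
    abort("Counts must be finite.", class = "pictopics_validation_error")
  if (is.data.frame(cell_labels)) {
    cell_labels <- setNames(as.character(cell_labels[[2]]),
                            as.character(cell_labels[[1]]))
  }
  if (!is.null(cell_labels)) {
    cell_labels <- cell_labels[intersect(names(cell_labels), cell_ids)]
    if (!length(cell_labels)) cell_labels <- NULL
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 cell_labels = cell_labels),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes (%d nonzero entries)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  if (!is.null(x$cell_labels)) {
    tab <- table(x$cell_labels)
    cat("labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @describeIn count_matrix Long-format view: one row per nonzero entry with
#'   columns `cell_id`, `gene_id`, `count` (and `label` when labels exist).
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @method as_tibble count_matrix
#' @export
as_tibble.count_matrix <- function(x, ...) {
  m <- methods::as(x$counts, "TsparseMatrix")
  out <- tibble(cell_id = x$cell_ids[m@i + 1L],
                gene_id = x$gene_ids[m@j + 1L],
                count = m@x)
  if (!is.null(x$cell_labels))
    out$label <- unname(x$cell_labels[out$cell_id])
  out
}

subset_count_matrix <- function(cm, cells = NULL, genes = NULL) {
  counts <- cm$counts
  if (!is.null(cells)) counts <- counts[cells, , drop = FALSE]
  if (!is.null(genes)) counts <- counts[, genes, drop = FALSE]
  count_matrix(counts, cell_labels = cm$cell_labels)
}

#' Read a count matrix from disk
#'
#' Reads either a 10x-style MatrixMarket directory (`matrix.mtx` plus
#' `genes.tsv` and `barcodes.tsv`, one id per line) or a dense TSV with a
#' gene-id header row and cell ids in the first column. The in-memory
#' orientation is always cells x genes; for MTX input the on-disk orientation
#' is declared with `genes_in_rows` (10x convention stores genes in rows).
#' A `labels.tsv` (cell_id, label; no header) in an MTX directory is picked
#' up automatically.
#'
#' @param path File (dense TSV) or directory (MTX) to read.
#' @param format `"mtx_dir"` or `"dense_tsv"`.
#' @param genes_in_rows For `mtx_dir`: is the on-disk matrix genes x cells?
#'   Default `TRUE`.
#' @param labels Optional path to a 2-column TSV (cell_id, label, no header).
#'
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("mtx_dir", "dense_tsv"),
                        genes_in_rows = TRUE, labels = NULL) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    files <- c(matrix = "matrix.mtx", genes = "genes.tsv",
               barcodes = "barcodes.tsv")
    paths <- file.path(path, files)
    names(paths) <- names(files)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      abort(paste0("Missing file: ", missing[[1]]),
            class = "pictopics_io_error")
    m <- Matrix::readMM(paths[["matrix"]])
    gene_ids <- readLines(paths[["genes"]])
    cell_ids <- readLines(paths[["barcodes"]])
    if (genes_in_rows) m <- Matrix::t(m)
    if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_ids))
      abort(sprintf(
        "Matrix is %d x %d after orientation but ids give %d cells x %d genes.",
        nrow(m), ncol(m), length(cell_ids), length(gene_ids)),
        class = "pictopics_format_error")
    lab_path <- labels %||% file.path(path, "labels.tsv")
    lab <- NULL
    if (file.exists(lab_path)) {
      df <- utils::read.table(lab_path, sep = "\t", header = FALSE,
                              colClasses = "character", quote = "")
      lab <- setNames(df[[2]], df[[1]])
    }
    count_matrix(m, cell_ids, gene_ids, cell_labels = lab)
  } else {
    if (!file.exists(path))
      abort(paste0("Missing file: ", path), class = "pictopics_io_error")
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    lab <- NULL
    if (!is.null(labels) && file.exists(labels)) {
      ldf <- utils::read.table(labels, sep = "\t", header = FALSE,
                               colClasses = "character", quote = "")
      lab <- setNames(ldf[[2]], ldf[[1]])
    }
    count_matrix(m, cell_ids = df[[1]], gene_ids = colnames(df)[-1],
                 cell_labels = lab)
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]: writes either a 10x-style MTX directory
#' (genes in rows) or a dense TSV. Labels, when present, go to `labels.tsv`
#' next to the matrix (MTX) or to `<path>.labels.tsv` (dense).
#'
#' @param cm A [count_matrix()].
#' @param path Output directory (`mtx_dir`) or file (`dense_tsv`).
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("mtx_dir", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::t(cm$counts), file.path(path, "matrix.mtx"))
    writeLines(cm$gene_ids, file.path(path, "genes.tsv"))
    writeLines(cm$cell_ids, file.path(path, "barcodes.tsv"))
    if (!is.null(cm$cell_labels))
      utils::write.table(
        data.frame(names(cm$cell_labels), unname(cm$cell_labels)),
        file.path(path, "labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
  } else {
    df <- as.data.frame(as.matrix(cm$counts))
    df <- cbind(cell_id = cm$cell_ids, df)
    readr::write_tsv(tibble::as_tibble(df), path)
    if (!is.null(cm$cell_labels))
      utils::write.table(
        data.frame(names(cm$cell_labels), unname(cm$cell_labels)),
        paste0(path, ".labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
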