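#' Read a count dataset from an MTX directory
#'
#' Expects `matrix.mtx` (genes x cells), `genes.tsv`, `barcodes.tsv` and
#' `labels.tsv` (tab-separated with header; columns `cell_id`, `batch`,
#' optionally `cell_type`) in `path`.
#'
#' @param path Directory containing the triplet.
#' @return A `SingleCellExperiment` with a sparse `"counts"` assay and
#'   `batch` (and possibly `cell_type`) in `colData`.
#' @export
read_dataset <- function(path) {
  need <- file.path(path, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                            "labels.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing file(s): ", paste(missing, collapse = ", "))
  X <- methods::as(Matrix::readMM(need[1]), "CsparseMatrix")
  genes <- utils::read.table(need[2], sep = "\t",
                             stringsAsFactors = FALSE)[, 1]
  cells <- utils::read.table(need[3], sep = "\t",
                             stringsAsFactors = FALSE)[, 1]
  labels <- utils::read.table(need[4], sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  if (!"batch" %in% names(labels))
    stop("labels.tsv lacks the required 'batch' column")
  if (nrow(labels) != ncol(X) || length(genes) != nrow(X) ||
      length(cells) != ncol(X))
    stop("matrix and annotation dimensions disagree")
  frac <- max(abs(X@x - round(X@x)))
  if (frac > 1e-6) stop("expected integer counts; entries deviate by ", frac)
  if (frac > 0) {
    warning("rounding near-integer counts")
    X@x <- round(X@x)
  }
  cd <- S4Vectors::DataFrame(batch = factor(labels$batch),
                             row.names = cells)
  if ("cell_type" %in% names(labels))
    cd$cell_type <- factor(labels$cell_type)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = X), colData = cd)
  rownames(sce) <- genes
  sce
}

#' Write a count dataset as an MTX directory
#'
#' Inverse of [read_dataset()]; writes the raw `"counts"` assay and the
#' label table.
#'
#' @param sce A `SingleCellExperiment` with `"counts"` and `batch`.
#' @param path Destination directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(sce, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  X <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(X, "CsparseMatrix"),
                  file.path(path, "matrix.mtx"))
  utils::write.table(data.frame(gene = rownames(sce)),
                     file.path(path, "genes.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(cell = colnames(sce)),
                     file.path(path, "barcodes.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  cd <- SummarizedExperiment::colData(sce)
  lab <- data.frame(cell_id = colnames(sce),
                    batch = as.character(cd$batch))
  if (!is.null(cd$cell_type))
    lab$cell_type <- as.character(cd$cell_type)
  utils::write.table(lab, file.path(path, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' PCA baseline embedding
#'
#' Principal-component scores of the log-normalized expression (cells in
#' rows), the unintegrated reference embedding used for comparison.
#'
#' @param sce Preprocessed `SingleCellExperiment` with `"logcounts"`.
#' @param n_comp Number of components (default 64).
#' @return `n_cells x n_comp` score matrix.
#' @export
pca_embed <- function(sce, n_comp = 64) {
  X <- t(as.matrix(SummarizedExperiment::assay(sce, "logcounts")))
  n_comp <- min(n_comp, ncol(X), nrow(X) - 1)
  p <- stats::prcomp(X, rank. = n_comp, center = TRUE, scale. = FALSE)
  unname(p$x[, seq_len(n_comp), drop = FALSE])
}
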