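#' Remove genes expressed in too few cells
#'
#' Keeps genes with nonzero counts in at least `min_cells` cells; the cell
#' set and the relative order of surviving genes are unchanged.
#'
#' @param sce A `SingleCellExperiment` with a `"counts"` assay.
#' @param min_cells Minimum number of expressing cells (default 3).
#' @return The filtered `SingleCellExperiment`.
#' @export
filter_genes <- function(sce, min_cells = 3) {
  X <- SummarizedExperiment::assay(sce, "counts")
  keep <- Matrix::rowSums(X > 0) >= min_cells
  if (!any(keep)) stop("empty gene set: no gene expressed in >= ",
                       min_cells, " cells")
  out <- sce[keep, ]
  S4Vectors::metadata(out)$preprocess <- c(
    S4Vectors::metadata(sce)$preprocess,
    list(filter_genes = list(min_cells = min_cells,
                             n_removed = sum(!keep))))
  out
}

#' Depth-normalize counts and log transform
#'
#' Scales each cell so its total count equals `target_sum` (cells with zero
#' depth are left all-zero), then applies `log1p` (natural log). The result
#' is stored as the `"logcounts"` assay.
#'
#' @param sce A `SingleCellExperiment` with a `"counts"` assay.
#' @param target_sum Per-cell total after scaling (default `1e4`).
#' @return `sce` with a `"logcounts"` assay added.
#' @export
normalize_log <- function(sce, target_sum = 1e4) {
  X <- SummarizedExperiment::assay(sce, "counts")
  if (any(X < 0)) stop("counts must be nonnegative")
  cs <- Matrix::colSums(X)
  sc <- ifelse(cs > 0, target_sum / cs, 0)
  Xn <- X %*% Matrix::Diagonal(ncol(X), sc)
  Xn <- methods::as(Xn, "CsparseMatrix")
  Xn@x <- log1p(Xn@x)
  dimnames(Xn) <- dimnames(X)
  SummarizedExperiment::assay(sce, "logcounts") <- Xn
  S4Vectors::metadata(sce)$preprocess <- c(
    S4Vectors::metadata(sce)$preprocess,
    list(normalize_log = list(target_sum = target_sum)))
  sce
}

# Clipped standardized variance of raw counts (vst criterion): per gene,
# counts are standardized by the loess-predicted sd at that gene's mean and
# clipped at sqrt(N) before taking the variance. Returns a ranking score
# (larger = more variable).
.vst_variance <- function(X) {
  n <- ncol(X)
  m <- Matrix::rowMeans(X)
  v <- Matrix::rowMeans(X^2) * n / max(n - 1, 1) -
    m^2 * n / max(n - 1, 1)
  v <- pmax(v, 0)
  est_sd <- rep(0, length(m))
  use <- v > 0
  if (sum(use) >= 2) {
    lx <- log10(m[use]); ly <- log10(v[use])
    fit <- tryCatch(
      stats::fitted(stats::loess(ly ~ lx, span = 0.3, degree = 2)),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit)))
      fit <- stats::fitted(stats::lm(ly ~ lx))
    est_sd[use] <- sqrt(10^fit)
  } else if (sum(use) == 1) {
    est_sd[use] <- sqrt(v[use])
  }
  clip <- sqrt(n)
  Xd <- as.matrix(X)
  out <- numeric(length(m))
  for (g in which(est_sd > 0)) {
    z <- pmin((Xd[g, ] - m[g]) / est_sd[g], clip)
    out[g] <- sum(z^2) / max(n - 1, 1)
  }
  out
}

#' Select highly variable genes per batch
#'
#' Ranks genes by the clipped standardized variance of raw counts (the
#' "vst"/Seurat-v3 criterion) computed within each batch, flags each
#' batch's top `n_hvg`, and combines batches by sorting genes on (number of
#' batches in which the gene is highly variable, descending; then median
#' within-batch rank, ascending). The returned object is restricted to the
#' selected genes, with the boolean mask stored in
#' `rowData(sce)$hvg` of the input-gene universe recorded in metadata.
#'
#' @param sce A `SingleCellExperiment` with `"counts"` (raw counts drive the
#'   ranking) and a `batch` column in `colData`.
#' @param n_hvg Number of genes to keep (default 2000). If at most `n_hvg`
#'   genes are present, all are kept.
#' @param batch_aware If `FALSE`, ranks on the pooled data instead.
#' @return `sce` subset to the selected genes.
#' @export
select_hvg <- function(sce, n_hvg = 2000, batch_aware = TRUE) {
  if (n_hvg <= 0) stop("n_hvg must be positive")
  X <- SummarizedExperiment::assay(sce, "counts")
  G <- nrow(X)
  if (G <= n_hvg) {
    keep <- rep(TRUE, G)
  } else {
    if (batch_aware) {
      batches <- factor(SummarizedExperiment::colData(sce)$batch)
      ranks <- matrix(NA_real_, G, nlevels(batches))
      for (b in seq_len(nlevels(batches))) {
        sv <- .vst_variance(X[, batches == levels(batches)[b], drop = FALSE])
        ranks[, b] <- rank(-sv, ties.method = "first")
      }
      n_hv_batches <- rowSums(ranks <= n_hvg)
      med_rank <- apply(ranks, 1, stats::median)
      ord <- order(-n_hv_batches, med_rank)
    } else {
      sv <- .vst_variance(X)
      ord <- order(rank(-sv, ties.method = "first"))
    }
    keep <- logical(G)
    keep[ord[seq_len(n_hvg)]] <- TRUE
  }
  out <- sce[keep, ]
  SummarizedExperiment::rowData(out)$hvg <- TRUE
  S4Vectors::metadata(out)$preprocess <- c(
    S4Vectors::metadata(sce)$preprocess,
    list(select_hvg = list(n_hvg = n_hvg, batch_aware = batch_aware,
                           hvg_mask = stats::setNames(keep, rownames(sce)))))
  out
}

#' Run the full preprocessing pipeline
#'
#' `filter_genes()`, then `normalize_log()`, then `select_hvg()`, with the
#' defaults used throughout the package.
#'
#' @inheritParams filter_genes
#' @inheritParams normalize_log
#' @inheritParams select_hvg
#' @return A preprocessed `SingleCellExperiment` with `"logcounts"`.
#' @export
preprocess <- function(sce, min_cells = 3, target_sum = 1e4, n_hvg = 2000,
                       batch_aware = TRUE) {
  sce <- filter_genes(sce, min_cells = min_cells)
  sce <- normalize_log(sce, target_sum = target_sum)
  select_hvg(sce, n_hvg = n_hvg, batch_aware = batch_aware)
}
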