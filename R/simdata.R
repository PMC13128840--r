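#' Configure the multi-batch count simulator
#'
#' Builds a validated configuration for [simulate_counts()]. The generative
#' model is a negative-binomial hierarchy standard for scRNA-seq: baseline
#' gene means are gamma draws, each cell type perturbs a random subset of
#' genes by log-normal fold changes, each batch (domain) multiplies every
#' gene by its own log-normal technical factor, and each cell carries a
#' log-normal library-size factor. Cell types can be made batch-specific by
#' zeroing their entry in a domain's row of `type_proportions`; rare types
#' are just small entries.
#'
#' @param n_domains Number of batches/domains `D` (>= 1).
#' @param cells_per_domain Integer vector of cells per domain; a scalar is
#'   recycled to length `n_domains`.
#' @param n_genes Number of genes.
#' @param n_cell_types Number of cell types.
#' @param type_proportions `D x n_cell_types` matrix of per-domain mixing
#'   proportions (rows must sum to 1); default is uniform over all types.
#' @param de_gene_frac Fraction of genes differentially expressed per type.
#' @param de_logfc_scale Standard deviation of the natural-log fold changes
#'   applied to a type's DE genes (> 0).
#' @param batch_effect_scale Standard deviation (log scale) of the per-batch
#'   multiplicative gene factors; 0 makes all domains identically
#'   distributed.
#' @param libsize_logmean,libsize_logsd Log-normal parameters of the
#'   per-cell library-size factor.
#' @param nb_dispersion Negative-binomial size parameter `r`; the variance
#'   is `mu + mu^2 / r`.
#' @param seed Integer seed; the whole draw is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_domains = 3,
                       cells_per_domain = 1000,
                       n_genes = 500,
                       n_cell_types = 5,
                       type_proportions = NULL,
                       de_gene_frac = 0.1,
                       de_logfc_scale = 1.0,
                       batch_effect_scale = 0.3,
                       libsize_logmean = 0,
                       libsize_logsd = 0.3,
                       nb_dispersion = 2,
                       seed = 1L) {
  stopifnot(n_domains >= 1, n_genes >= 1, n_cell_types >= 1)
  cells_per_domain <- as.integer(rep_len(cells_per_domain, n_domains))
  if (any(cells_per_domain <= 0)) stop("all cell counts must be positive")
  if (is.null(type_proportions)) {
    type_proportions <- matrix(1 / n_cell_types, n_domains, n_cell_types)
  }
  type_proportions <- as.matrix(type_proportions)
  if (!all(dim(type_proportions) == c(n_domains, n_cell_types)))
    stop("type_proportions must be n_domains x n_cell_types")
  if (any(type_proportions < 0))
    stop("type proportions must be nonnegative")
  rs <- rowSums(type_proportions)
  ok <- abs(rs - 1) <= 1e-9 | rs == 0   # all-zero rows caught at simulate time
  if (!all(ok)) stop("each row of type_proportions must sum to 1")
  stopifnot(de_gene_frac >= 0, de_gene_frac <= 1, de_logfc_scale > 0,
            batch_effect_scale >= 0, libsize_logsd >= 0, nb_dispersion > 0)
  structure(list(
    n_domains = as.integer(n_domains),
    cells_per_domain = cells_per_domain,
    n_genes = as.integer(n_genes),
    n_cell_types = as.integer(n_cell_types),
    type_proportions = type_proportions,
    de_gene_frac = de_gene_frac,
    de_logfc_scale = de_logfc_scale,
    batch_effect_scale = batch_effect_scale,
    libsize_logmean = libsize_logmean,
    libsize_logsd = libsize_logsd,
    nb_dispersion = nb_dispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate multi-batch scRNA-seq counts with known structure
#'
#' Draws a cells-in-columns count matrix under the model described in
#' [sim_config()] and returns it as a
#' [SingleCellExperiment::SingleCellExperiment] with assay `"counts"`
#' (sparse), `colData` columns `batch` and `cell_type` (factors), and the
#' true per-type/per-domain model means stored in `metadata(sce)$model`.
#'
#' @param config A `sim_config`.
#' @return A `SingleCellExperiment`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  Tt <- config$n_cell_types
  D <- config$n_domains

  base_mean <- stats::rgamma(G, shape = 0.6, rate = 0.3)
  # per-type multiplicative programs on a random DE subset
  n_de <- floor(config$de_gene_frac * G + 1e-9)
  type_factor <- matrix(1, Tt, G)
  de_genes <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    idx <- sample.int(G, n_de)
    type_factor[t, idx] <- exp(stats::rnorm(n_de, 0, config$de_logfc_scale))
    de_genes[[t]] <- sort(idx)
  }
  batch_factor <- matrix(
    stats::rlnorm(D * G, 0, config$batch_effect_scale), D, G, byrow = TRUE)

  counts <- vector("list", D)
  batch <- integer(0)
  ctype <- integer(0)
  for (d in seq_len(D)) {
    p <- config$type_proportions[d, ]
    if (all(p == 0)) stop("empty domain: domain ", d,
                          " selects zero cells for every type")
    n_d <- config$cells_per_domain[d]
    types_d <- sample.int(Tt, n_d, replace = TRUE, prob = p)
    lib <- stats::rlnorm(n_d, config$libsize_logmean, config$libsize_logsd)
    mu <- (type_factor[types_d, , drop = FALSE] *
             matrix(batch_factor[d, ], n_d, G, byrow = TRUE) *
             matrix(base_mean, n_d, G, byrow = TRUE)) * lib
    cnt <- matrix(stats::rnbinom(n_d * G, size = config$nb_dispersion,
                                 mu = as.numeric(mu)), n_d, G)
    counts[[d]] <- cnt
    batch <- c(batch, rep.int(d, n_d))
    ctype <- c(ctype, types_d)
  }
  X <- do.call(rbind, counts)              # cells x genes
  n <- nrow(X)
  gene_ids <- sprintf("gene%0*d", nchar(G), seq_len(G))
  cell_ids <- sprintf("cell%0*d", nchar(n), seq_len(n))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(t(X), sparse = TRUE),
                                       "CsparseMatrix")),
    colData = S4Vectors::DataFrame(
      batch = factor(batch, levels = seq_len(D)),
      cell_type = factor(ctype, levels = seq_len(Tt)),
      row.names = cell_ids))
  rownames(sce) <- gene_ids
  S4Vectors::metadata(sce)$model <- list(
    base_mean = base_mean, type_factor = type_factor,
    batch_factor = batch_factor, de_genes = de_genes,
    config = config)
  sce
}
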