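# Shared fixture builders; everything is generated in code under fixed
# seeds.

# Small simulated dataset, preprocessed, for fast end-to-end tests.
tiny_prep <- function(n_domains = 2, cells = 80, genes = 60, types = 3,
                      seed = 3, n_hvg = 50, ...) {
  sce <- simulate_counts(sim_config(
    n_domains = n_domains, cells_per_domain = cells, n_genes = genes,
    n_cell_types = types, seed = seed, ...))
  preprocess(sce, n_hvg = n_hvg)
}

# A small network configuration matched to tiny_prep.
tiny_net_cfg <- function(prep, ...) {
  net_config(input_dim = nrow(prep),
             n_domains = nlevels(SummarizedExperiment::colData(prep)$batch),
             encoder_depth = 3, encoder_growth = 16,
             projector_dims = c(32, 32, 32), ...)
}

# Gaussian blobs in d dimensions: one matrix row per cell, labels attached.
make_blobs <- function(n_per, centers, d = 64, sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  Z <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(stats::rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[i, ], n_per, d, byrow = TRUE)))
  list(Z = Z, labels = rep(seq_len(k), each = n_per))
}

# Centers at distance `sep` along distinct axes.
axis_centers <- function(k, sep, d = 64) {
  C <- matrix(0, k, d)
  for (i in seq_len(k)) C[i, i] <- sep
  C
}

# Brute-force adjusted Rand index by enumerating all item pairs.
ari_pairs <- function(a, b) {
  n <- length(a)
  s_ab <- s_a <- s_b <- 0
  np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    s_ab <- s_ab + (same_a && same_b)
    s_a <- s_a + same_a
    s_b <- s_b + same_b
    np <- np + 1
  }
  expct <- s_a * s_b / np
  den <- (s_a + s_b) / 2 - expct
  if (den == 0) return(1)
  (s_ab - expct) / den
}

# Entrywise Pearson cross-correlation of raw embeddings (population
# moments), the definitional oracle for cross_correlation().
crosscorr_oracle <- function(Za, Zb) {
  K <- nrow(Za); P <- ncol(Za)
  W <- matrix(0, P, P)
  for (i in seq_len(P)) for (j in seq_len(P)) {
    mi <- mean(Za[, i]); mj <- mean(Zb[, j])
    si <- sqrt(mean((Za[, i] - mi)^2))
    sj <- sqrt(mean((Zb[, j] - mj)^2))
    W[i, j] <- mean((Za[, i] - mi) * (Zb[, j] - mj)) / (si * sj)
  }
  W
}
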