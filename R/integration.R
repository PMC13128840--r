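#' Leiden clustering sweep over resolutions
#'
#' Clusters the kNN graph of the embedding with the Leiden algorithm
#' (modularity objective) at each resolution, scores every clustering
#' against the true labels, and returns the ARI and NMI at the resolution
#' maximizing their average (ties to the smaller resolution).
#'
#' @param Z Embedding matrix (cells in rows).
#' @param true_labels Ground-truth labels (>= 2 distinct).
#' @param resolutions Resolutions to sweep (default 0.1 to 1.0, step 0.1).
#' @param seed Seed for the Leiden refinement.
#' @param k kNN graph neighbours (default 15).
#' @return List with `ari`, `nmi`, `best_resolution`, `membership` (cluster
#'   labels at the best resolution) and the full `sweep` data frame.
#' @export
leiden_sweep <- function(Z, true_labels, resolutions = seq(0.1, 1, 0.1),
                         seed = 1L, k = 15) {
  if (length(unique(true_labels)) < 2) stop("need >= 2 distinct labels")
  g <- .knn_graph(Z, k)
  memberships <- lapply(resolutions, function(r)
    .with_seed(seed, as.integer(igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = r)))))
  sweep_df <- data.frame(
    resolution = resolutions,
    ari = vapply(memberships, ari, numeric(1), truth = true_labels),
    nmi = vapply(memberships, nmi, numeric(1), truth = true_labels))
  best <- which.max((sweep_df$ari + sweep_df$nmi) / 2)
  list(ari = sweep_df$ari[best], nmi = sweep_df$nmi[best],
       best_resolution = sweep_df$resolution[best],
       membership = memberships[[best]], sweep = sweep_df)
}

#' Score one embedding on the data-integration task
#'
#' Computes the raw integration metrics for a single embedding: Leiden-swept
#' ARI/NMI, cell-type silhouette, batch silhouette, graph connectivity,
#' batch mixing entropy and the overcorrection index.
#'
#' @param Z Embedding matrix.
#' @param batch_labels,cell_type_labels Per-cell labels.
#' @param run Identifier recorded in the report row.
#' @param seed Seed for Leiden and entropy sampling.
#' @param k_graph,k_entropy,k_oc Neighbourhood sizes for the kNN graph
#'   metrics, batch entropy, and overcorrection.
#' @return One-row data frame (an integration report).
#' @export
evaluate_integration <- function(Z, batch_labels, cell_type_labels,
                                 run = "run", seed = 1L, k_graph = 15,
                                 k_entropy = 30, k_oc = 30) {
  sw <- leiden_sweep(Z, cell_type_labels, seed = seed, k = k_graph)
  data.frame(
    run = run,
    ari = sw$ari, nmi = sw$nmi,
    casw = casw(Z, cell_type_labels),
    basw = basw(Z, batch_labels, cell_type_labels),
    graph_connectivity = graph_connectivity(Z, cell_type_labels, k_graph),
    batch_entropy = batch_entropy(Z, batch_labels, cell_type_labels,
                                  k = k_entropy, seed = seed),
    overcorrection = overcorrection(Z, cell_type_labels, k_oc),
    best_resolution = sw$best_resolution,
    stringsAsFactors = FALSE)
}

# Min-max normalize across runs; a degenerate range maps to 0.5.
.minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Aggregate integration reports across runs
#'
#' Min-max normalizes each raw metric across the supplied runs, then forms
#' `s_bio` = mean of normalized (ARI, NMI, cASW), `s_batch` = mean of
#' normalized (bASW, graph connectivity, batch entropy), `s_oc` =
#' normalized overcorrection, and the weighted total
#' `s_integration = 0.6 s_bio + 0.3 s_batch + 0.1 s_oc`.
#'
#' @param reports Data frame of rows from [evaluate_integration()] (one or
#'   more runs).
#' @return `reports` with the four aggregate columns appended.
#' @export
aggregate_integration <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  f <- lapply(reports[c("ari", "nmi", "casw", "basw",
                        "graph_connectivity", "batch_entropy",
                        "overcorrection")], .minmax)
  reports$s_bio <- (f$ari + f$nmi + f$casw) / 3
  reports$s_batch <- (f$basw + f$graph_connectivity + f$batch_entropy) / 3
  reports$s_oc <- f$overcorrection
  reports$s_integration <-
    0.6 * reports$s_bio + 0.3 * reports$s_batch + 0.1 * reports$s_oc
  reports
}
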