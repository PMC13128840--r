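# Exact Euclidean k-nearest-neighbour indices (self excluded), computed in
# row blocks; deterministic, adequate at this package's problem sizes.
.knn_index <- function(Z, k) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n <= k) stop("need more than k = ", k, " cells")
  rn <- rowSums(Z^2)
  out <- matrix(0L, n, k)
  bs <- 512L
  for (start in seq(1L, n, by = bs)) {
    rows <- start:min(start + bs - 1L, n)
    d2 <- outer(rn[rows], rn, "+") - 2 * (Z[rows, , drop = FALSE] %*% t(Z))
    d2[cbind(seq_along(rows), rows)] <- Inf
    out[rows, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

# Undirected union kNN graph as an igraph object.
.knn_graph <- function(Z, k) {
  nn <- .knn_index(Z, k)
  el <- cbind(rep(seq_len(nrow(nn)), k), as.integer(nn))
  igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
}

# Run expr with a temporary RNG seed, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  expr
}

.check_labels <- function(pred, truth) {
  if (length(pred) == 0 || length(truth) == 0) stop("empty label vector")
  if (length(pred) != length(truth)) stop("label vectors differ in length")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings, from the closed-form
#' pair-counting expression on the contingency table. 1 for identical
#' partitions; 0 in expectation for independent ones.
#'
#' @param pred,truth Equal-length label vectors.
#' @return Scalar in `[-1, 1]`.
#' @export
ari <- function(pred, truth) {
  .check_labels(pred, truth)
  tab <- table(pred, truth)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  exp_idx <- sa * sb / choose(n, 2)
  den <- (sa + sb) / 2 - exp_idx
  if (den == 0) return(1)   # both partitions trivial and identical in form
  (sij - exp_idx) / den
}

#' Normalized mutual information
#'
#' Mutual information between two labelings normalized by the arithmetic
#' mean of their entropies. 1 for identical partitions; 0 when either
#' labeling is constant while the other is not.
#'
#' @inheritParams ari
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(pred, truth) {
  .check_labels(pred, truth)
  tab <- table(pred, truth) / length(pred)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  mi / ((ha + hb) / 2)
}

.sil_widths <- function(Z, labels) {
  f <- factor(labels)
  s <- cluster::silhouette(as.integer(f), stats::dist(Z))
  w <- s[, "sil_width"]
  w[!is.finite(w)] <- 0
  w
}

#' Cell-type average silhouette width, rescaled to \[0, 1\]
#'
#' Mean silhouette coefficient of the cells under their cell-type labels
#' (Euclidean distance on the embedding), mapped through `(s + 1) / 2` so
#' 1 means perfectly separated types and 0.5 means no structure.
#'
#' @param Z Embedding matrix (cells in rows).
#' @param cell_type_labels Per-cell labels (>= 2 distinct).
#' @return Scalar in `[0, 1]`.
#' @export
casw <- function(Z, cell_type_labels) {
  if (length(unique(cell_type_labels)) < 2)
    stop("need at least 2 cell types")
  (mean(.sil_widths(Z, cell_type_labels)) + 1) / 2
}

#' Batch average silhouette width (batch-mixing score)
#'
#' For every cell type present in at least two batches, computes the
#' silhouette of its cells under batch labels and scores the type as the
#' mean of `1 - |s|`; the final value is the mean over those shared types.
#' 1 indicates ideal batch mixing within cell types, 0 full separation.
#'
#' @param Z Embedding matrix.
#' @param batch_labels,cell_type_labels Per-cell labels.
#' @return Scalar in `[0, 1]`.
#' @export
basw <- function(Z, batch_labels, cell_type_labels) {
  types <- unique(cell_type_labels)
  scores <- c()
  for (tp in types) {
    sel <- cell_type_labels == tp
    if (length(unique(batch_labels[sel])) < 2) next
    w <- .sil_widths(Z[sel, , drop = FALSE], batch_labels[sel])
    scores <- c(scores, mean(1 - abs(w)))
  }
  if (length(scores) == 0) stop("no shared cell types")
  mean(scores)
}

#' Graph connectivity of cell types in the kNN graph
#'
#' Builds the symmetrized union kNN graph on the embedding; for each cell
#' type, takes the induced subgraph and the fraction of its cells in the
#' largest connected component; returns the mean over types. 1 means every
#' type is fully connected.
#'
#' @param Z Embedding matrix.
#' @param cell_type_labels Per-cell labels.
#' @param k Neighbours per cell (default 15).
#' @return Scalar in `(0, 1]`.
#' @export
graph_connectivity <- function(Z, cell_type_labels, k = 15) {
  g <- .knn_graph(Z, k)
  types <- unique(cell_type_labels)
  fr <- vapply(types, function(tp) {
    sel <- which(cell_type_labels == tp)
    sub <- igraph::induced_subgraph(g, sel)
    max(igraph::components(sub)$csize) / length(sel)
  }, numeric(1))
  mean(fr)
}

#' Batch mixing entropy in local neighbourhoods
#'
#' Restricted to cells of cell types shared across at least two batches:
#' repeatedly samples anchor cells, takes each anchor's `k` nearest
#' neighbours, and computes the Shannon entropy of the neighbourhood's
#' batch composition with each batch's count reweighted by its inverse
#' global frequency, normalized by `log(n_batches)`. 1 means batches are
#' perfectly mixed locally, 0 means single-batch neighbourhoods.
#'
#' @param Z Embedding matrix.
#' @param batch_labels,cell_type_labels Per-cell labels.
#' @param k Neighbourhood size (default 30).
#' @param n_anchors Anchors per repeat (default 100).
#' @param n_repeats Repeats (default 10).
#' @param seed Seed for anchor sampling.
#' @return Scalar in `[0, 1]`.
#' @export
batch_entropy <- function(Z, batch_labels, cell_type_labels, k = 30,
                          n_anchors = 100, n_repeats = 10, seed = 1L) {
  shared <- names(which(vapply(
    split(batch_labels, cell_type_labels),
    function(b) length(unique(b)) >= 2, logical(1))))
  sel <- which(as.character(cell_type_labels) %in% shared)
  if (length(sel) == 0 ||
      length(unique(batch_labels[sel])) < 2)
    stop("need cells of >= 2 batches within shared cell types")
  if (length(sel) <= k) stop("fewer than k + 1 eligible cells")
  Ze <- Z[sel, , drop = FALSE]
  bt <- factor(batch_labels[sel])
  freq <- as.numeric(table(bt)) / length(bt)
  nn <- .knn_index(Ze, k)
  bmat <- matrix(as.integer(bt)[nn], nrow(nn), k)
  ent_of <- function(i) {
    cnt <- tabulate(bmat[i, ], nbins = nlevels(bt))
    w <- cnt / freq
    p <- w / sum(w)
    p <- p[p > 0]
    -sum(p * log(p)) / log(nlevels(bt))
  }
  .with_seed(seed, {
    mean(unlist(lapply(seq_len(n_repeats), function(r) {
      anchors <- sample.int(nrow(Ze), min(n_anchors, nrow(Ze)))
      vapply(anchors, ent_of, numeric(1))
    })))
  })
}

#' Overcorrection score (positive index)
#'
#' Mean, over cells, of the fraction of each cell's `k` nearest neighbours
#' (self excluded) sharing its cell-type label. 1 means no mixing of
#' distinct types (no overcorrection); values near chance indicate that
#' integration has merged distinct types.
#'
#' @param Z Embedding matrix.
#' @param cell_type_labels Per-cell labels (>= 2 distinct).
#' @param k Neighbours (default 30).
#' @return Scalar in `[0, 1]`.
#' @export
overcorrection <- function(Z, cell_type_labels, k = 30) {
  if (length(unique(cell_type_labels)) < 2)
    stop("need at least 2 cell types")
  nn <- .knn_index(Z, k)
  lab <- as.integer(factor(cell_type_labels))
  mean(rowMeans(matrix(lab[nn], nrow(nn), k) == lab))
}
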