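# Labels of each query cell's reference neighbours, ordered by increasing
# Euclidean distance, up to kmax columns. Deterministic.
.knn_rank_labels <- function(ref_Z, ref_labels_int, query_Z, kmax) {
  kmax <- min(kmax, nrow(ref_Z))
  rn <- rowSums(ref_Z^2)
  out <- matrix(0L, nrow(query_Z), kmax)
  bs <- 512L
  for (start in seq(1L, nrow(query_Z), by = bs)) {
    rows <- start:min(start + bs - 1L, nrow(query_Z))
    q <- query_Z[rows, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn, "+") - 2 * (q %*% t(ref_Z))
    out[rows, ] <- t(apply(d2, 1, function(r)
      ref_labels_int[order(r)[seq_len(kmax)]]))
  }
  out
}

# Majority vote over the first k columns; ties broken toward the class
# whose nearest neighbour comes first in distance order (deterministic).
.vote <- function(rank_labels, k, n_classes) {
  k <- min(k, ncol(rank_labels))
  apply(rank_labels[, seq_len(k), drop = FALSE], 1, function(lab) {
    cnt <- tabulate(lab, nbins = n_classes)
    top <- which(cnt == max(cnt))
    if (length(top) == 1) top else lab[lab %in% top][1]
  })
}

.balanced_accuracy <- function(pred, truth) {
  mean(vapply(unique(truth), function(cl)
    mean(pred[truth == cl] == cl), numeric(1)))
}

.macro_f1 <- function(pred, truth, classes) {
  mean(vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1)))
}

#' Cross-validated grid search for the kNN classifier's k
#'
#' 3-fold stratified cross-validation on the reference embedding over the
#' arithmetic grid `5, 11, ..., 197`, choosing the `k` maximizing mean
#' balanced accuracy (ties toward smaller `k`). Classes with fewer than
#' `folds` members are dropped from the cross-validation fitting.
#'
#' @param ref_Z Reference embedding matrix.
#' @param ref_labels Reference labels.
#' @param k_grid Candidate `k` values (default `seq(5, 197, by = 6)`).
#' @param folds Cross-validation folds (default 3).
#' @param seed Seed for the fold assignment.
#' @return List with `chosen_k` and the `scores` data frame
#'   (`k`, `balanced_accuracy`).
#' @export
knn_grid_search <- function(ref_Z, ref_labels, k_grid = seq(5L, 197L, 6L),
                            folds = 3, seed = 1L) {
  if (nrow(ref_Z) < min(k_grid) + 1)
    stop("reference smaller than the smallest k + 1")
  f <- factor(ref_labels)
  keep <- as.character(f) %in% names(which(table(f) >= folds))
  Zc <- ref_Z[keep, , drop = FALSE]
  fc <- droplevels(f[keep])
  fold_id <- integer(length(fc))
  .with_seed(seed, for (cl in levels(fc)) {
    sel <- which(fc == cl)
    fold_id[sel] <- sample(rep_len(seq_len(folds), length(sel)))
  })
  acc <- matrix(NA_real_, length(k_grid), folds)
  for (fd in seq_len(folds)) {
    tr <- fold_id != fd
    rl <- .knn_rank_labels(Zc[tr, , drop = FALSE], as.integer(fc)[tr],
                           Zc[!tr, , drop = FALSE], max(k_grid))
    truth <- as.integer(fc)[!tr]
    for (i in seq_along(k_grid)) {
      pred <- .vote(rl, k_grid[i], nlevels(fc))
      acc[i, fd] <- .balanced_accuracy(pred, truth)
    }
  }
  mean_acc <- rowMeans(acc)
  list(chosen_k = k_grid[which.max(mean_acc)],
       scores = data.frame(k = k_grid, balanced_accuracy = mean_acc))
}

#' Classify query cells from a labelled reference
#'
#' Restricts the reference to cell types shared with the query, predicts
#' each query cell's label by majority vote over its `chosen_k` Euclidean
#' nearest reference neighbours, and scores macro F1 (mean per-class F1
#' over shared classes) and balanced accuracy (mean per-class recall) on
#' the query cells of shared types only.
#'
#' @param ref_Z,ref_labels Reference embedding and labels.
#' @param query_Z,query_labels Query embedding and labels.
#' @param chosen_k Number of neighbours.
#' @return List with `macro_f1`, `balanced_accuracy`, `predictions` (for
#'   scored query cells), `scored` (logical mask of scored query cells)
#'   and `shared_types`.
#' @export
classify_query <- function(ref_Z, ref_labels, query_Z, query_labels,
                           chosen_k) {
  shared <- intersect(unique(as.character(ref_labels)),
                      unique(as.character(query_labels)))
  if (length(shared) == 0) stop("disjoint label sets")
  ref_sel <- as.character(ref_labels) %in% shared
  q_sel <- as.character(query_labels) %in% shared
  lev <- sort(shared)
  ref_int <- match(as.character(ref_labels)[ref_sel], lev)
  truth <- match(as.character(query_labels)[q_sel], lev)
  rl <- .knn_rank_labels(ref_Z[ref_sel, , drop = FALSE], ref_int,
                         query_Z[q_sel, , drop = FALSE], chosen_k)
  pred <- .vote(rl, chosen_k, length(lev))
  list(macro_f1 = .macro_f1(pred, truth, seq_along(lev)),
       balanced_accuracy = .balanced_accuracy(pred, truth),
       predictions = lev[pred], scored = q_sel, shared_types = lev)
}

#' Clustering quality of query cells within the full embedding
#'
#' Leiden-clusters the whole dataset's embedding over the resolution sweep,
#' picks the resolution by the query-restricted (ARI + NMI) / 2, and
#' returns query-cell ARI and NMI plus the query cells' cell-type
#' silhouette (computed on the query embedding alone; `NA` when the query
#' holds a single cell type).
#'
#' @param Z_all Full-dataset embedding.
#' @param true_labels Full-dataset cell-type labels.
#' @param query_mask Logical mask of query cells.
#' @param seed Leiden seed.
#' @param k kNN graph neighbours.
#' @return List with `ari`, `nmi`, `casw`, `best_resolution`.
#' @export
batchwise_bio <- function(Z_all, true_labels, query_mask, seed = 1L,
                          k = 15) {
  if (!any(query_mask)) stop("query is empty")
  g <- .knn_graph(Z_all, k)
  resolutions <- seq(0.1, 1, 0.1)
  memberships <- lapply(resolutions, function(r)
    .with_seed(seed, as.integer(igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = r)))))
  qa <- vapply(memberships, function(m)
    ari(m[query_mask], true_labels[query_mask]), numeric(1))
  qn <- vapply(memberships, function(m)
    nmi(m[query_mask], true_labels[query_mask]), numeric(1))
  best <- which.max((qa + qn) / 2)
  qcasw <- if (length(unique(true_labels[query_mask])) < 2) NA_real_
           else casw(Z_all[query_mask, , drop = FALSE],
                     true_labels[query_mask])
  list(ari = qa[best], nmi = qn[best], casw = qcasw,
       best_resolution = resolutions[best])
}

#' Leave-one-batch-out label-transfer evaluation
#'
#' For each query batch: selects `k` by [knn_grid_search()] on the
#' remaining (reference) cells, classifies the query with
#' [classify_query()], and scores query clustering quality with
#' [batchwise_bio()].
#'
#' @param Z Full-dataset embedding.
#' @param cell_type_labels Per-cell labels.
#' @param query_batch_labels Per-cell query-batch assignment (the batches
#'   looped over as queries).
#' @param run Run identifier.
#' @param seed Seed for CV folds and Leiden.
#' @return Data frame with one row per query batch: `run`, `batch`,
#'   `chosen_k`, `f1`, `acc`, `ari`, `nmi`, `casw`.
#' @export
evaluate_transfer <- function(Z, cell_type_labels, query_batch_labels,
                              run = "run", seed = 1L) {
  batches <- unique(as.character(query_batch_labels))
  rows <- lapply(batches, function(b) {
    q <- as.character(query_batch_labels) == b
    gs <- knn_grid_search(Z[!q, , drop = FALSE], cell_type_labels[!q],
                          seed = seed)
    cl <- classify_query(Z[!q, , drop = FALSE], cell_type_labels[!q],
                         Z[q, , drop = FALSE], cell_type_labels[q],
                         gs$chosen_k)
    bw <- batchwise_bio(Z, cell_type_labels, q, seed = seed)
    data.frame(run = run, batch = b, chosen_k = gs$chosen_k,
               f1 = cl$macro_f1, acc = cl$balanced_accuracy,
               ari = bw$ari, nmi = bw$nmi, casw = bw$casw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate label-transfer reports across runs
#'
#' Within each query batch, min-max normalizes each raw metric across runs
#' (degenerate range maps to 0.5; a missing cASW is excluded from the
#' batchwise-bio mean), forms `s_classify` = mean(f(F1), f(Acc)),
#' `s_bw_bio` = mean(f(ARI), f(NMI), f(cASW)), and
#' `s_label_transfer = 0.5 s_classify + 0.5 s_bw_bio`; dataset-level
#' scores are unweighted means over batches.
#'
#' @param per_batch Data frame of rows from [evaluate_transfer()], possibly
#'   covering several runs.
#' @return List with `per_batch` (normalized per-batch scores appended)
#'   and `overall` (one row per run: `s_classify`, `s_bw_bio`,
#'   `s_label_transfer`).
#' @export
aggregate_transfer <- function(per_batch) {
  stopifnot(nrow(per_batch) >= 1)
  out <- do.call(rbind, lapply(split(per_batch, per_batch$batch),
                               function(d) {
    d$f_f1 <- .minmax(d$f1)
    d$f_acc <- .minmax(d$acc)
    d$f_ari <- .minmax(d$ari)
    d$f_nmi <- .minmax(d$nmi)
    d$f_casw <- if (all(is.na(d$casw))) NA_real_ else .minmax(d$casw)
    d$s_classify <- (d$f_f1 + d$f_acc) / 2
    d$s_bw_bio <- rowMeans(cbind(d$f_ari, d$f_nmi, d$f_casw), na.rm = TRUE)
    d$s_label_transfer <- 0.5 * d$s_classify + 0.5 * d$s_bw_bio
    d
  }))
  rownames(out) <- NULL
  overall <- do.call(rbind, lapply(split(out, out$run), function(d)
    data.frame(run = d$run[1],
               s_classify = mean(d$s_classify),
               s_bw_bio = mean(d$s_bw_bio),
               s_label_transfer = mean(d$s_label_transfer),
               stringsAsFactors = FALSE)))
  rownames(overall) <- NULL
  list(per_batch = out, overall = overall)
}
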