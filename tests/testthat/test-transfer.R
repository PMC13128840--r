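test_that("the k grid is the 33-value arithmetic sequence", {
  grid <- seq(5L, 197L, 6L)
  expect_length(grid, 33)
  expect_true(all(grid <= 200) && max(grid) + 6 > 200)
  bl <- make_blobs(150, axis_centers(2, 50), sd = 1, seed = 26)
  gs <- knn_grid_search(bl$Z, bl$labels, seed = 3)
  expect_equal(nrow(gs$scores), 33)
  expect_equal(gs$scores$k, grid)
  # perfectly separable classes: every small k ties at 1.0 -> smallest wins
  expect_equal(gs$chosen_k, 5L)
  gs2 <- knn_grid_search(bl$Z, bl$labels, seed = 3)
  expect_identical(gs$chosen_k, gs2$chosen_k)
  expect_error(knn_grid_search(bl$Z[1:4, ], bl$labels[1:4]), "smallest k")
})

test_that("classify_query reproduces a hand-built confusion matrix", {
  # reference: class 1 at 0, class 2 at 10 (1-d); query placed so that
  # 1-NN yields TP/FN/FP/TN = (8, 2, 1, 9)
  ref_Z <- matrix(c(rep(0, 20), rep(10, 20)), ncol = 1)
  ref_lab <- rep(c("one", "two"), each = 20)
  q_Z <- matrix(c(rep(0.1, 8), rep(9.9, 2),    # truth one: 8 right, 2 wrong
                  rep(10.1, 9), rep(0.2, 1)),  # truth two: 9 right, 1 wrong
                ncol = 1)
  q_lab <- rep(c("one", "two"), c(10, 10))
  out <- classify_query(ref_Z, ref_lab, q_Z, q_lab, chosen_k = 1)
  expect_equal(out$balanced_accuracy, (0.8 + 0.9) / 2)
  expect_equal(out$macro_f1, 0.5 * (16 / 19 + 18 / 21))
  # self-classification is perfect
  self <- classify_query(ref_Z, ref_lab, ref_Z, ref_lab, chosen_k = 1)
  expect_equal(self$macro_f1, 1)
  expect_equal(self$balanced_accuracy, 1)
})

test_that("non-shared cell types are excluded from fitting and scoring", {
  bl <- make_blobs(40, axis_centers(3, 60), sd = 1, seed = 27)
  ref <- bl$Z[bl$labels != 3, ]
  ref_lab <- bl$labels[bl$labels != 3]
  out <- classify_query(ref, ref_lab, bl$Z, bl$labels, chosen_k = 5)
  expect_equal(sum(out$scored), 80)          # type-3 query cells dropped
  expect_equal(out$shared_types, c("1", "2"))
  base <- classify_query(ref, ref_lab, bl$Z[bl$labels != 3, ],
                         bl$labels[bl$labels != 3], chosen_k = 5)
  expect_equal(out$macro_f1, base$macro_f1)
  expect_error(classify_query(ref, rep("a", nrow(ref)), bl$Z,
                              rep("b", nrow(bl$Z)), 5), "disjoint")
})

test_that("classify_query is invariant to cell order", {
  bl <- make_blobs(50, axis_centers(2, 40), sd = 2, seed = 28)
  q <- make_blobs(30, axis_centers(2, 40), sd = 2, seed = 29)
  a <- classify_query(bl$Z, bl$labels, q$Z, q$labels, chosen_k = 7)
  set.seed(30)
  pr <- sample(nrow(bl$Z)); pq <- sample(nrow(q$Z))
  b <- classify_query(bl$Z[pr, ], bl$labels[pr], q$Z[pq, ],
                      q$labels[pq], chosen_k = 7)
  expect_equal(a$macro_f1, b$macro_f1)
  expect_equal(a$balanced_accuracy, b$balanced_accuracy)
})

test_that("query-restricted clustering matches the full sweep and theory", {
  bl <- make_blobs(80, axis_centers(3, 80), sd = 1, seed = 31)
  # query = whole dataset reduces to the plain sweep
  all_q <- batchwise_bio(bl$Z, bl$labels, rep(TRUE, 240), seed = 2)
  sw <- leiden_sweep(bl$Z, bl$labels, seed = 2)
  expect_equal(all_q$ari, sw$ari)
  expect_equal(all_q$nmi, sw$nmi)
  # a perfectly clustered dataset keeps ARI 1 on any >= 2-type query
  q <- bl$labels %in% c(1, 2) & seq_len(240) %% 2 == 0
  part <- batchwise_bio(bl$Z, bl$labels, q, seed = 2)
  expect_equal(part$ari, 1)
  expect_equal(part$nmi, 1)
  # single-type query: cASW recorded as missing
  q1 <- which(bl$labels == 1)
  m1 <- rep(FALSE, 240); m1[q1] <- TRUE
  expect_true(is.na(batchwise_bio(bl$Z, bl$labels, m1, seed = 2)$casw))
  expect_error(batchwise_bio(bl$Z, bl$labels, rep(FALSE, 240)), "empty")
})

test_that("NMI on a restricted contingency table matches hand arithmetic", {
  # two clusters vs two types on 30 query cells: table [[10,2],[3,15]]
  pred <- rep(c(1, 1, 2, 2), c(10, 2, 3, 15))
  truth <- rep(c("a", "b", "a", "b"), c(10, 2, 3, 15))
  tab <- table(pred, truth) / 30
  pa <- rowSums(tab); pb <- colSums(tab)
  mi <- sum(tab * log(tab / outer(pa, pb)))
  expected <- mi / ((-sum(pa * log(pa)) - sum(pb * log(pb))) / 2)
  expect_equal(nmi(pred, truth), expected)
})

test_that("transfer aggregation applies the equal-weight identities", {
  mk <- function(run, batch, f1, acc, a = 0.5, n = 0.5, cw = 0.5)
    data.frame(run = run, batch = batch, chosen_k = 5, f1 = f1, acc = acc,
               ari = a, nmi = n, casw = cw, stringsAsFactors = FALSE)
  # single run: every normalized score is the degenerate 0.5
  single <- aggregate_transfer(mk("r", "b1", 0.9, 0.8))
  expect_equal(single$per_batch$s_label_transfer, 0.5)
  expect_equal(single$overall$s_label_transfer, 0.5)
  # a run dominating every metric in every batch scores 1
  dom <- rbind(mk("hi", "b1", 1, 1, 1, 1, 1), mk("lo", "b1", 0, 0, 0, 0, 0),
               mk("hi", "b2", 1, 1, 1, 1, 1), mk("lo", "b2", 0, 0, 0, 0, 0))
  agg <- aggregate_transfer(dom)
  expect_equal(agg$overall$s_label_transfer[agg$overall$run == "hi"], 1)
  # f(F1) = 1, f(Acc) = 0.5 -> s_classify = 0.75; with s_bw_bio = 0.5 the
  # equal weighting gives 0.625
  tri <- rbind(mk("x", "b1", 1, 0.5), mk("lo", "b1", 0, 0),
               mk("hi", "b1", 1, 1))
  px <- aggregate_transfer(tri)$per_batch
  x <- px[px$run == "x", ]
  expect_equal(x$s_classify, 0.75)
  expect_equal(x$s_bw_bio, 0.5)
  expect_equal(x$s_label_transfer, 0.625)
})
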