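test_that("ARI and NMI agree with their definitions and oracles", {
  expect_equal(ari(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  expect_equal(ari(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0)
  expect_equal(nmi(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0)
  expect_error(ari(integer(0), integer(0)), "empty")

  # contingency [[2,0],[0,2],[1,1]]: pred has 3 groups, truth 2
  pred <- c(1, 1, 2, 2, 3, 3)
  truth <- c("a", "a", "b", "b", "a", "b")
  expect_equal(ari(pred, truth), ari_pairs(pred, truth))

  # closed form equals brute-force pair counting on small random instances
  set.seed(14)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(ari(a, b), ari_pairs(a, b))
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b))
    if (length(unique(a)) > 1 || length(unique(b)) > 1)
      expect_equal(nmi(a, b), igraph::compare(a, b, method = "nmi"),
                   tolerance = 1e-12)
  }
})

test_that("cell-type silhouette score reflects separation", {
  bl <- make_blobs(50, axis_centers(2, 100), sd = 0.5, seed = 15)
  expect_gt(casw(bl$Z, bl$labels), 0.9)
  set.seed(16)
  one <- matrix(rnorm(1000 * 5), 1000, 5)
  lab <- sample(1:2, 1000, replace = TRUE)
  expect_lt(abs(casw(one, lab) - 0.5), 0.05)
  same <- matrix(1, 20, 3)
  expect_equal(casw(same, rep(1:2, 10)), 0.5)
  expect_error(casw(one, rep(1, 1000)), "2 cell types")
})

test_that("batch silhouette scores batch mixing within cell types", {
  # interleaved batches: same distribution per type in both batches
  set.seed(17)
  n <- 500
  type <- rep(1:2, each = n / 2)
  Z <- matrix(rnorm(n * 10), n, 10) + 10 * (type == 2)
  batch <- rep(1:2, times = n / 2)
  expect_gt(basw(Z, batch, type), 0.85)
  # fully separated batches within each type
  Zs <- Z + 50 * (batch == 2)
  expect_lt(basw(Zs, batch, type), 0.05)
  # a single shared type contributes its own score
  type2 <- type
  batch2 <- batch
  batch2[type == 2] <- 1          # type 2 now single-batch, excluded
  expect_equal(basw(Z, batch2, type2),
               mean(1 - abs(sctwin:::.sil_widths(
                 Z[type == 1, ], batch2[type == 1]))))
  expect_error(basw(Z, rep(1, n), type), "no shared cell types")
})

test_that("graph connectivity detects split cell types", {
  bl <- make_blobs(60, axis_centers(3, 80), sd = 0.5, seed = 18)
  expect_equal(graph_connectivity(bl$Z, bl$labels), 1.0)
  # one type split into two far halves of equal size: contributes 0.5
  Z <- bl$Z
  split_half <- which(bl$labels == 1)[1:30]
  Z[split_half, ] <- Z[split_half, ] + 500
  gc <- graph_connectivity(Z, bl$labels)
  expect_equal(gc, mean(c(0.5, 1, 1)))
  # single cell type equals its own component fraction
  expect_equal(graph_connectivity(Z[bl$labels == 1, ],
                                  rep(1, 60)), 0.5)
  expect_error(graph_connectivity(bl$Z[1:10, ], bl$labels[1:10], k = 15),
               "more than k")
})

test_that("batch entropy separates mixed from disjoint batches", {
  set.seed(19)
  n <- 1000
  Zm <- matrix(rnorm(2 * n * 8), 2 * n, 8)      # i.i.d. mixed batches
  batch <- rep(1:2, each = n)
  type <- rep(1:2, times = n)
  expect_gt(batch_entropy(Zm, batch, type, seed = 1), 0.9)
  Zd <- Zm + 100 * (batch == 2)                 # disjoint supports
  expect_lt(batch_entropy(Zd, batch, type, seed = 1), 0.05)
  # all shared types in one batch only -> error
  expect_error(batch_entropy(Zm[batch == 1, ], batch[batch == 1],
                             type[batch == 1], seed = 1), ">= 2 batches")
  # deterministic given the seed
  expect_identical(batch_entropy(Zm, batch, type, seed = 5),
                   batch_entropy(Zm, batch, type, seed = 5))
})

test_that("overcorrection is 1 for separated types, chance for merged", {
  bl <- make_blobs(100, axis_centers(3, 100), sd = 0.5, seed = 20)
  expect_equal(overcorrection(bl$Z, bl$labels), 1.0)
  set.seed(21)
  Z <- matrix(rnorm(2000 * 6), 2000, 6)
  lab <- rep(1:2, 1000)
  expect_lt(abs(overcorrection(Z, lab) - 0.5), 0.05)
  # k exceeding the smallest type forces cross-type neighbours
  bl2 <- make_blobs(20, axis_centers(2, 100), sd = 0.5, seed = 22)
  expect_lt(overcorrection(bl2$Z, bl2$labels, k = 30), 1)
})

test_that("metrics are invariant to relabeling and cell order", {
  bl <- make_blobs(40, axis_centers(3, 30), sd = 2, seed = 23)
  batch <- rep(1:2, 60)
  set.seed(24)
  perm <- sample(120)
  relab <- c(7, 5, 3)[bl$labels]
  expect_equal(casw(bl$Z[perm, ], bl$labels[perm]), casw(bl$Z, relab))
  expect_equal(graph_connectivity(bl$Z[perm, ], bl$labels[perm]),
               graph_connectivity(bl$Z, relab))
  expect_equal(overcorrection(bl$Z[perm, ], bl$labels[perm]),
               overcorrection(bl$Z, relab))
  expect_equal(basw(bl$Z[perm, ], batch[perm], bl$labels[perm]),
               basw(bl$Z, batch, relab))
  a <- sample(1:3, 50, replace = TRUE)
  b <- sample(1:3, 50, replace = TRUE)
  expect_equal(ari(a, b), ari(c(9, 1, 4)[a], b))
  expect_equal(nmi(a, b), nmi(a, c("x", "z", "y")[b]))
})

test_that("the Leiden sweep evaluates ten resolutions and finds structure", {
  bl <- make_blobs(80, axis_centers(4, 60), sd = 1, seed = 25)
  sw <- leiden_sweep(bl$Z, bl$labels, seed = 2)
  expect_equal(nrow(sw$sweep), 10)
  expect_equal(sw$sweep$resolution, seq(0.1, 1, 0.1))
  expect_gte(sw$ari, 0.99)
  expect_gte(sw$nmi, 0.99)
  expect_error(leiden_sweep(bl$Z, rep(1, 320)), "distinct labels")
})

test_that("aggregation follows the min-max and 0.6/0.3/0.1 weighting", {
  mk <- function(run, v) data.frame(run = run, ari = v[1], nmi = v[2],
    casw = v[3], basw = v[4], graph_connectivity = v[5],
    batch_entropy = v[6], overcorrection = v[7], best_resolution = 0.5)
  # run A holds the maximum of every metric
  r <- aggregate_integration(rbind(mk("A", rep(0.9, 7)),
                                   mk("B", rep(0.1, 7))))
  expect_equal(r$s_integration[r$run == "A"], 1)
  # degenerate ranges collapse to 0.5
  r2 <- aggregate_integration(rbind(mk("A", rep(0.4, 7)),
                                    mk("B", rep(0.4, 7))))
  expect_equal(r2$s_integration, rep(0.5, 2))
  # hand-computed example: f(ARI,NMI,cASW)=(1,.5,.3), f(batch)=1, f(oc)=0
  r3 <- aggregate_integration(rbind(
    mk("x", c(1, 0.5, 0.3, 1, 1, 1, 0)),
    mk("lo", rep(0, 7)),
    mk("hi", rep(1, 7))))
  x <- r3[r3$run == "x", ]
  expect_equal(x$s_bio, 0.6)
  expect_equal(x$s_batch, 1)
  expect_equal(x$s_oc, 0)
  expect_equal(x$s_integration, 0.66)
})
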