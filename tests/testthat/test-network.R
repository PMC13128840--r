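test_that("DSBN normalizes per domain and isolates domain statistics", {
  st <- dsbn_state(4, 2, affine = FALSE)
  set.seed(10)
  h <- matrix(rnorm(40, mean = 3, sd = 2), 10, 4)
  out <- dsbn_forward(st, h, 1, "train")
  expect_true(all(abs(colMeans(out$output)) < 1e-5))
  expect_true(all(abs(apply(out$output, 2, function(c)
    mean(c^2) - mean(c)^2) - 1) < 1e-4))
  # domain 2 untouched
  expect_identical(out$state$rm[, 2], st$rm[, 2])
  expect_identical(out$state$rv[, 2], st$rv[, 2])
  # shift invariance: inputs differing by a constant normalize identically
  o1 <- dsbn_forward(st, h, 1, "train")$output
  o2 <- dsbn_forward(st, h + 5, 2, "train")$output
  expect_equal(o1, o2, tolerance = 1e-10)
  expect_error(dsbn_forward(st, h, 3, "train"), "unregistered domain")
  expect_error(dsbn_forward(st, h[1, , drop = FALSE], 1, "train"),
               "single sample")
})

test_that("DSBN eval mode uses the domain's running statistics", {
  st <- dsbn_state(3, 2, affine = FALSE, momentum = 1)  # adopt batch stats
  set.seed(11)
  h <- matrix(rnorm(30, 2, 3), 10, 3)
  st <- dsbn_forward(st, h, 1, "train")$state
  ev <- dsbn_forward(st, h, 1, "eval")$output
  # domain 2 still has init stats: eval there is a near-identity transform
  ev2 <- dsbn_forward(st, h, 2, "eval")$output
  expect_true(all(abs(colMeans(ev)) < 0.3))   # batch vs unbiased variance
  expect_equal(ev2, h, tolerance = 1e-4)
})

test_that("encoder and projector have the configured shapes", {
  cfgS <- net_config(input_dim = 30, n_domains = 2, profile = "S")
  expect_equal(cfgS$projector_dims, rep(512L, 3))
  expect_equal(cfgS$encoder_depth, 11L)
  cfgL <- net_config(input_dim = 30, n_domains = 2, profile = "L")
  expect_equal(cfgL$projector_dims, rep(1024L, 3))

  cfg <- net_config(input_dim = 20, n_domains = 2, encoder_depth = 4,
                    encoder_growth = 8, projector_dims = c(16, 16, 16))
  net <- net_init(cfg, seed = 1)
  x <- matrix(rnorm(5 * 20), 5, 20)
  Z <- encode(net, x, 1)
  expect_equal(dim(Z), c(5L, 64L))
  Y <- project(net, Z, 1)
  expect_equal(dim(Y), c(5L, 16L))
  expect_identical(encode(net, x, 1), Z)   # eval determinism
  expect_error(encode(net, x[, 1:5], 1), "expected")
  expect_error(project(net, Z[, 1:5], 1), "expected")
  expect_error(encode(net, x, 5), "unregistered domain")
})

test_that("the projector's final linear layer has no activation", {
  cfg <- net_config(input_dim = 6, n_domains = 1, encoder_depth = 2,
                    encoder_growth = 4, projector_dims = c(8, 8, 8))
  net <- net_init(cfg, seed = 2)
  net$params$proj_b[[3]] <- rep(-100, 8)   # force negative pre-activations
  Z <- encode(net, matrix(rnorm(18), 3, 6), 1)
  Y <- project(net, Z, 1)
  expect_true(all(Y < 0))                  # survive: no ReLU/normalization
})

test_that("parameter count is domain-independent except DSBN terms", {
  n_scalars <- function(tree) if (is.list(tree))
    sum(vapply(tree, n_scalars, numeric(1))) else length(tree)
  strip_affine <- function(p) p[setdiff(names(p),
    c("enc_gamma", "enc_beta", "proj_gamma", "proj_beta"))]
  cfg2 <- net_config(input_dim = 15, n_domains = 2, encoder_depth = 3,
                     encoder_growth = 8, projector_dims = c(8, 8, 8))
  cfg5 <- net_config(input_dim = 15, n_domains = 5, encoder_depth = 3,
                     encoder_growth = 8, projector_dims = c(8, 8, 8))
  p2 <- net_init(cfg2, seed = 1)$params
  p5 <- net_init(cfg5, seed = 1)$params
  expect_equal(n_scalars(strip_affine(p2)), n_scalars(strip_affine(p5)))
  expect_equal(n_scalars(p5$proj_gamma) / n_scalars(p2$proj_gamma), 2.5)
})

test_that("network gradients match finite differences", {
  set.seed(12)
  cfg <- net_config(input_dim = 10, n_domains = 2, encoder_depth = 3,
                    encoder_growth = 5, projector_dims = c(7, 7, 7))
  net <- net_init(cfg, seed = 5)
  Xa <- matrix(abs(rnorm(80)), 8, 10)
  Xb <- matrix(abs(rnorm(80)), 8, 10)
  loss_of <- function(net) {
    fa <- sctwin:::.net_forward(net, Xa, 1, "val", keep_cache = TRUE)
    fb <- sctwin:::.net_forward(fa$net, Xb, 1, "val", keep_cache = TRUE)
    lg <- sctwin:::.domain_loss_grad(fa$Y, fb$Y, 0.005)
    list(loss = lg$loss, fa = fa, fb = fb, lg = lg)
  }
  r <- loss_of(net)
  ga <- sctwin:::.net_backward(net, r$fa$cache, r$lg$dYa)
  gb <- sctwin:::.net_backward(net, r$fb$cache, r$lg$dYb)
  g <- sctwin:::.tree_map2(`+`, ga, gb)
  h <- 1e-5
  cases <- list(list("enc_W", 1L, 7L), list("enc_W", 2L, 13L),
                list("enc_gamma", 1L, 3L), list("proj_W", 1L, 9L),
                list("proj_W", 3L, 20L), list("proj_gamma", 2L, 5L))
  for (cs in cases) {
    n2 <- net
    n2$params[[cs[[1]]]][[cs[[2]]]][cs[[3]]] <-
      n2$params[[cs[[1]]]][[cs[[2]]]][cs[[3]]] + h
    lp <- loss_of(n2)$loss
    n2$params[[cs[[1]]]][[cs[[2]]]][cs[[3]]] <-
      n2$params[[cs[[1]]]][[cs[[2]]]][cs[[3]]] - 2 * h
    lm <- loss_of(n2)$loss
    fd <- (lp - lm) / (2 * h)
    an <- g[[cs[[1]]]][[cs[[2]]]][cs[[3]]]
    expect_equal(an, fd, tolerance = 1e-3)
  }
  # encoder receives gradient at all
  expect_gt(max(abs(g$enc_W[[1]])), 0)
})

test_that("checkpoints reload to bit-identical eval outputs", {
  prep <- tiny_prep()
  nc <- tiny_net_cfg(prep)
  tc <- train_config(K = 16, epochs = 3, warmup_epochs = 1, seed = 5)
  ck <- fit_sctwin(prep, nc, tc)
  f <- tempfile(fileext = ".rds")
  write_checkpoint(ck, f)
  expect_true(file.exists(paste0(f, ".json")))
  ck2 <- read_checkpoint(f)
  expect_identical(embed_cells(prep, ck), embed_cells(prep, ck2))
})
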