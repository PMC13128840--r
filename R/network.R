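#' Network architecture configuration
#'
#' Describes the Siamese encoder-projector. The encoder is a densely
#' connected MLP: `encoder_depth - 1` fully connected layers of width
#' `encoder_growth`, layer `l` consuming the concatenation of the input and
#' all previous layers' outputs, each followed by domain-specific batch
#' normalization (DSBN) and ReLU; a final linear layer maps the full
#' concatenation to `repr_dim`. The projector is 3 linear layers, the first
#' two each followed by ReLU and DSBN. `encoder_depth` counts linear
#' layers, so the standard small profile ("S": depth 11, projector
#' 512-512-512) and large profile ("L": depth 21, projector 1024-1024-1024)
#' match their nominal layer counts.
#'
#' @param input_dim Number of input genes (post-HVG).
#' @param repr_dim Encoder output dimension (default 64).
#' @param encoder_depth Number of linear layers in the encoder.
#' @param encoder_growth Width of each dense layer (default 64).
#' @param projector_dims Integer vector of the 3 projector layer widths.
#' @param n_domains Number of batches/domains `D`.
#' @param profile Convenience: `"S"` or `"L"` fills in depth/projector
#'   defaults; explicit arguments override.
#' @return A `net_config` list.
#' @export
net_config <- function(input_dim, n_domains, repr_dim = 64,
                       encoder_depth = NULL, encoder_growth = 64,
                       projector_dims = NULL, profile = c("S", "L")) {
  profile <- match.arg(profile)
  if (is.null(encoder_depth))
    encoder_depth <- if (profile == "S") 11L else 21L
  if (is.null(projector_dims))
    projector_dims <- if (profile == "S") c(512L, 512L, 512L)
                      else c(1024L, 1024L, 1024L)
  stopifnot(length(projector_dims) == 3, encoder_depth >= 2,
            input_dim >= 1, n_domains >= 1, repr_dim >= 1,
            encoder_growth >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 repr_dim = as.integer(repr_dim),
                 encoder_depth = as.integer(encoder_depth),
                 encoder_growth = as.integer(encoder_growth),
                 projector_dims = as.integer(projector_dims),
                 n_domains = as.integer(n_domains),
                 profile = profile),
            class = "net_config")
}

.kaiming <- function(fan_in, fan_out) {
  b <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out)
}

#' Initialize network weights and DSBN state
#'
#' Kaiming-uniform linear weights, zero biases, unit/zero DSBN affine
#' parameters and zero-mean/unit-variance running statistics for every
#' domain. Fully reproducible from `seed`.
#'
#' @param config A [net_config()].
#' @param seed Integer seed.
#' @return A `sctwin_net` list with elements `config`, `params`, `state`.
#' @export
net_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  set.seed(seed)
  D <- config$n_domains
  gr <- config$encoder_growth
  nd <- config$encoder_depth - 1L
  p <- config$projector_dims
  params <- list(enc_W = list(), enc_b = list(),
                 enc_gamma = list(), enc_beta = list())
  for (l in seq_len(nd)) {
    fi <- config$input_dim + (l - 1L) * gr
    params$enc_W[[l]] <- .kaiming(fi, gr)
    params$enc_b[[l]] <- numeric(gr)
    params$enc_gamma[[l]] <- matrix(1, gr, D)
    params$enc_beta[[l]] <- matrix(0, gr, D)
  }
  fi <- config$input_dim + nd * gr
  params$enc_Wout <- .kaiming(fi, config$repr_dim)
  params$enc_bout <- numeric(config$repr_dim)
  pin <- c(config$repr_dim, p[1], p[2])
  params$proj_W <- lapply(1:3, function(l) .kaiming(pin[l], p[l]))
  params$proj_b <- lapply(1:3, function(l) numeric(p[l]))
  params$proj_gamma <- lapply(1:2, function(l) matrix(1, p[l], D))
  params$proj_beta <- lapply(1:2, function(l) matrix(0, p[l], D))
  state <- list(
    enc_rm = lapply(seq_len(nd), function(l) matrix(0, gr, D)),
    enc_rv = lapply(seq_len(nd), function(l) matrix(1, gr, D)),
    proj_rm = lapply(1:2, function(l) matrix(0, p[l], D)),
    proj_rv = lapply(1:2, function(l) matrix(1, p[l], D)))
  structure(list(config = config, params = params, state = state,
                 seed = as.integer(seed)),
            class = "sctwin_net")
}

# Core batch-normalization forward for one domain's statistics column.
# mode: "train" = batch stats + running update; "val" = batch stats, no
# update; "eval" = running stats. Returns out, cache and updated stats.
.bn_forward <- function(a, gamma, beta, rm, rv, mode,
                        momentum = 0.1, eps = 1e-5) {
  K <- nrow(a)
  if (mode == "eval") {
    invstd <- 1 / sqrt(rv + eps)
    xhat <- sweep(sweep(a, 2, rm), 2, invstd, "*")
  } else {
    if (K < 2) stop("batch normalization undefined for a single sample")
    mu <- colMeans(a)
    v <- colMeans(a^2) - mu^2
    v <- pmax(v, 0)
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(a, 2, mu), 2, invstd, "*")
    if (mode == "train") {
      rm <- (1 - momentum) * rm + momentum * mu
      rv <- (1 - momentum) * rv + momentum * v * K / (K - 1)
    }
  }
  out <- if (is.null(gamma)) xhat
         else sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, invstd = invstd, rm = rm, rv = rv)
}

# Backward through batch-stats normalization (train/val modes).
.bn_backward <- function(g, cache, gamma) {
  gh <- if (is.null(gamma)) g else sweep(g, 2, gamma, "*")
  dgamma <- if (is.null(gamma)) NULL else colSums(g * cache$xhat)
  dbeta <- if (is.null(gamma)) NULL else colSums(g)
  t1 <- sweep(gh, 2, colMeans(gh))
  t2 <- sweep(cache$xhat, 2, colMeans(gh * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2, cache$invstd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Create a standalone domain-specific batch-normalization state
#'
#' Holds separate running statistics (and, when `affine`, separate
#' learnable scale/shift) for each of `n_domains` domains over `n_features`
#' features. Feeding one domain never touches another domain's state.
#'
#' @param n_features Number of features normalized.
#' @param n_domains Number of registered domains.
#' @param affine Carry per-domain scale/shift parameters?
#' @param momentum Running-statistics momentum (default 0.1).
#' @param eps Variance guard (default 1e-5).
#' @return A `dsbn_state` list.
#' @export
dsbn_state <- function(n_features, n_domains, affine = TRUE,
                       momentum = 0.1, eps = 1e-5) {
  structure(list(
    n_features = as.integer(n_features),
    n_domains = as.integer(n_domains),
    affine = affine, momentum = momentum, eps = eps,
    gamma = if (affine) matrix(1, n_features, n_domains),
    beta = if (affine) matrix(0, n_features, n_domains),
    rm = matrix(0, n_features, n_domains),
    rv = matrix(1, n_features, n_domains)), class = "dsbn_state")
}

#' Apply domain-specific batch normalization
#'
#' In `"train"` mode, normalizes with the current mini-batch's statistics
#' of the given domain (columnwise mean 0 / variance 1 before affine) and
#' updates that domain's running statistics; in `"eval"` mode, normalizes
#' with the stored running statistics. Other domains' state is untouched.
#'
#' @param st A [dsbn_state()].
#' @param h K x F activation matrix.
#' @param domain_id Domain index in `1..n_domains`.
#' @param mode `"train"` or `"eval"`.
#' @return List with `output` (K x F) and the updated `state`.
#' @export
dsbn_forward <- function(st, h, domain_id, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  stopifnot(inherits(st, "dsbn_state"))
  if (!(domain_id %in% seq_len(st$n_domains)))
    stop("unregistered domain: ", domain_id)
  h <- as.matrix(h)
  if (ncol(h) != st$n_features) stop("feature dimension mismatch")
  d <- domain_id
  bn <- .bn_forward(h,
                    if (st$affine) st$gamma[, d],
                    if (st$affine) st$beta[, d],
                    st$rm[, d], st$rv[, d], mode,
                    momentum = st$momentum, eps = st$eps)
  st$rm[, d] <- bn$rm
  st$rv[, d] <- bn$rv
  list(output = bn$out, state = st)
}

# Full forward pass through encoder (+ optionally projector) for one
# domain's mini-batch. Returns Z, Y, updated net (running stats), and a
# cache for backprop when keep_cache.
.net_forward <- function(net, x, domain, mode, with_projector = TRUE,
                         keep_cache = FALSE) {
  cfg <- net$config
  if (!(domain %in% seq_len(cfg$n_domains)))
    stop("unregistered domain: ", domain)
  x <- as.matrix(x)
  if (ncol(x) != cfg$input_dim)
    stop("input has ", ncol(x), " features; expected ", cfg$input_dim)
  P <- net$params; S <- net$state
  nd <- cfg$encoder_depth - 1L
  feats <- x
  enc_cache <- vector("list", nd)
  for (l in seq_len(nd)) {
    a <- feats %*% P$enc_W[[l]] + rep(P$enc_b[[l]], each = nrow(x))
    bn <- .bn_forward(a, P$enc_gamma[[l]][, domain],
                      P$enc_beta[[l]][, domain],
                      S$enc_rm[[l]][, domain], S$enc_rv[[l]][, domain],
                      mode)
    S$enc_rm[[l]][, domain] <- bn$rm
    S$enc_rv[[l]][, domain] <- bn$rv
    h <- pmax(bn$out, 0)
    if (keep_cache)
      enc_cache[[l]] <- list(in_dim = ncol(feats), bn = bn,
                             mask = bn$out > 0)
    feats <- cbind(feats, h)
  }
  Z <- feats %*% P$enc_Wout + rep(P$enc_bout, each = nrow(x))
  Y <- NULL
  proj_cache <- NULL
  if (with_projector) {
    proj_cache <- vector("list", 2)
    inp <- Z
    for (l in 1:2) {
      pre <- inp %*% P$proj_W[[l]] + rep(P$proj_b[[l]], each = nrow(x))
      r <- pmax(pre, 0)
      bn <- .bn_forward(r, P$proj_gamma[[l]][, domain],
                        P$proj_beta[[l]][, domain],
                        S$proj_rm[[l]][, domain], S$proj_rv[[l]][, domain],
                        mode)
      S$proj_rm[[l]][, domain] <- bn$rm
      S$proj_rv[[l]][, domain] <- bn$rv
      if (keep_cache)
        proj_cache[[l]] <- list(input = inp, mask = pre > 0, bn = bn)
      inp <- bn$out
    }
    Y <- inp %*% P$proj_W[[3]] + rep(P$proj_b[[3]], each = nrow(x))
    if (keep_cache) proj_cache$top_input <- inp
  }
  net$state <- S
  cache <- if (keep_cache) list(x = x, feats = feats, Z = Z,
                                enc = enc_cache, proj = proj_cache,
                                domain = domain)
  list(Z = Z, Y = Y, net = net, cache = cache)
}

# Backprop dL/dY through projector and encoder for one domain. Returns a
# gradient tree matching net$params (zeros for other domains' affine
# columns).
.net_backward <- function(net, cache, dY) {
  cfg <- net$config
  P <- net$params
  d <- cache$domain
  D <- cfg$n_domains
  gr <- .zero_like(P)
  # projector layer 3
  inp3 <- cache$proj$top_input
  gr$proj_W[[3]] <- crossprod(inp3, dY)
  gr$proj_b[[3]] <- colSums(dY)
  g <- dY %*% t(P$proj_W[[3]])
  for (l in 2:1) {
    pc <- cache$proj[[l]]
    bb <- .bn_backward(g, pc$bn, P$proj_gamma[[l]][, d])
    gr$proj_gamma[[l]][, d] <- bb$dgamma
    gr$proj_beta[[l]][, d] <- bb$dbeta
    dpre <- bb$dx * pc$mask
    gr$proj_W[[l]] <- crossprod(pc$input, dpre)
    gr$proj_b[[l]] <- colSums(dpre)
    g <- dpre %*% t(P$proj_W[[l]])
  }
  dZ <- g
  # final encoder linear over the full concatenation
  gr$enc_Wout <- crossprod(cache$feats, dZ)
  gr$enc_bout <- colSums(dZ)
  dfeats <- dZ %*% t(P$enc_Wout)
  nd <- cfg$encoder_depth - 1L
  grw <- cfg$encoder_growth
  for (l in nd:1) {
    ec <- cache$enc[[l]]
    off <- ec$in_dim
    dh <- dfeats[, off + seq_len(grw), drop = FALSE]
    dn <- dh * ec$mask
    bb <- .bn_backward(dn, ec$bn, P$enc_gamma[[l]][, d])
    gr$enc_gamma[[l]][, d] <- bb$dgamma
    gr$enc_beta[[l]][, d] <- bb$dbeta
    inp <- cache$feats[, seq_len(off), drop = FALSE]
    gr$enc_W[[l]] <- crossprod(inp, bb$dx)
    gr$enc_b[[l]] <- colSums(bb$dx)
    dfeats <- dfeats[, seq_len(off), drop = FALSE] + bb$dx %*% t(P$enc_W[[l]])
  }
  gr
}

# Tree utilities over nested lists of numeric arrays.
.zero_like <- function(tree) {
  if (is.list(tree)) lapply(tree, .zero_like)
  else tree * 0
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) Map(function(x, y) .tree_map2(f, x, y), a, b)
  else f(a, b)
}

#' Encode expression profiles to 64-dimensional representations
#'
#' Applies the encoder branch (weights shared across the two Siamese
#' branches) for one domain. In `"eval"` mode normalization uses the
#' domain's stored running statistics and the call is deterministic.
#'
#' @param net A `sctwin_net`.
#' @param x K x `input_dim` matrix.
#' @param domain Domain index.
#' @param mode `"eval"` (default) or `"train"`.
#' @return K x `repr_dim` matrix `Z`.
#' @export
encode <- function(net, x, domain, mode = "eval") {
  .net_forward(net, x, domain, mode, with_projector = FALSE)$Z
}

#' Project representations to the embedding space
#'
#' Applies the 3-layer projector for one domain. The third linear layer's
#' output receives no activation or normalization inside this function.
#'
#' @param net A `sctwin_net`.
#' @param Z K x `repr_dim` matrix of representations.
#' @param domain Domain index.
#' @param mode `"eval"` (default) or `"train"`.
#' @return K x P embedding matrix, P = last projector width.
#' @export
project <- function(net, Z, domain, mode = "eval") {
  cfg <- net$config
  if (!(domain %in% seq_len(cfg$n_domains)))
    stop("unregistered domain: ", domain)
  Z <- as.matrix(Z)
  if (ncol(Z) != cfg$repr_dim)
    stop("representation has ", ncol(Z), " dims; expected ", cfg$repr_dim)
  P <- net$params; S <- net$state
  inp <- Z
  for (l in 1:2) {
    pre <- inp %*% P$proj_W[[l]] + rep(P$proj_b[[l]], each = nrow(Z))
    r <- pmax(pre, 0)
    bn <- .bn_forward(r, P$proj_gamma[[l]][, domain],
                      P$proj_beta[[l]][, domain],
                      S$proj_rm[[l]][, domain], S$proj_rv[[l]][, domain],
                      mode)
    inp <- bn$out
  }
  inp %*% P$proj_W[[3]] + rep(P$proj_b[[3]], each = nrow(Z))
}
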