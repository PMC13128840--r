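#' Training configuration
#'
#' @param profile `"S"` (mini-batch K = 512) or `"L"` (K = 2048); K may be
#'   overridden directly. Pick S for datasets below 50k cells.
#' @param K Per-domain mini-batch size.
#' @param epochs Maximum epochs (default 1000).
#' @param base_lr Adam base learning rate (default 3e-4).
#' @param warmup_epochs Linear warmup length (default 10).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 50); 0 stops at the first non-improving epoch.
#' @param lam Loss trade-off `lambda` (default 0.005).
#' @param seed Global seed driving init, sampling and augmentation.
#' @param val_fraction Per-domain fraction of cells held out for the
#'   validation loss (default 0.1).
#' @param mask_fraction,shuffle_fraction,p_apply Augmentation settings.
#' @return A `train_config` list.
#' @export
train_config <- function(profile = c("S", "L"), K = NULL, epochs = 1000,
                         base_lr = 3e-4, warmup_epochs = 10, patience = 50,
                         lam = 0.005, seed = 1L, val_fraction = 0.1,
                         mask_fraction = 0.2, shuffle_fraction = 0.1,
                         p_apply = 0.5) {
  profile <- match.arg(profile)
  if (is.null(K)) K <- if (profile == "S") 512L else 2048L
  stopifnot(K >= 2, val_fraction > 0, val_fraction < 1, epochs >= 1,
            warmup_epochs >= 0, patience >= 0, lam > 0, base_lr > 0)
  structure(list(profile = profile, K = as.integer(K),
                 epochs = as.integer(epochs), base_lr = base_lr,
                 warmup_epochs = as.integer(warmup_epochs),
                 patience = as.integer(patience), lam = lam,
                 seed = as.integer(seed), val_fraction = val_fraction,
                 mask_fraction = mask_fraction,
                 shuffle_fraction = shuffle_fraction, p_apply = p_apply),
            class = "train_config")
}

#' Warmup + cosine-annealing learning-rate schedule
#'
#' Linear ramp from 0 to `base_lr` over `warmup_steps`, then
#' `base_lr * 0.5 * (1 + cos(pi * (step - warmup) / (total - warmup)))`.
#'
#' @param step Current step (0 to `total_steps`).
#' @param total_steps Total schedule length.
#' @param warmup_steps Warmup length.
#' @param base_lr Peak learning rate.
#' @return Learning rate at `step`.
#' @export
lr_schedule <- function(step, total_steps, warmup_steps, base_lr) {
  stopifnot(step >= 0, step <= total_steps)
  if (warmup_steps > 0 && step < warmup_steps)
    return(base_lr * step / warmup_steps)
  if (total_steps == warmup_steps) return(base_lr)
  base_lr * 0.5 * (1 + cos(pi * (step - warmup_steps) /
                             (total_steps - warmup_steps)))
}

# Stateful per-domain index sampler: without replacement within a shuffled
# epoch-cycle; domains smaller than K are resampled with replacement.
.sampler_new <- function(domain_indices, K) {
  lapply(domain_indices, function(idx) {
    if (length(idx) < 2) stop("every domain needs at least 2 cells")
    list(idx = idx, queue = integer(0), K = K)
  })
}

.sampler_draw <- function(state) {
  draws <- vector("list", length(state))
  for (d in seq_along(state)) {
    s <- state[[d]]
    if (length(s$idx) < s$K) {
      draws[[d]] <- sample(s$idx, s$K, replace = TRUE)
    } else {
      if (length(s$queue) < s$K) s$queue <- c(s$queue, sample(s$idx))
      draws[[d]] <- s$queue[seq_len(s$K)]
      s$queue <- s$queue[-seq_len(s$K)]
      state[[d]] <- s
    }
  }
  list(draws = draws, state = state)
}

#' Draw one per-domain mini-batch
#'
#' Samples `K` cells from each domain of a preprocessed dataset (without
#' replacement when the domain has at least `K` cells, with replacement
#' otherwise) and returns the per-domain `K x G` expression matrices.
#' Uses R's RNG stream.
#'
#' @param sce A `SingleCellExperiment` with `"logcounts"` and `batch`.
#' @param K Cells per domain.
#' @return Named list of `K x G` matrices, one per batch level.
#' @export
build_minibatch <- function(sce, K) {
  batches <- factor(SummarizedExperiment::colData(sce)$batch)
  Xt <- t(as.matrix(SummarizedExperiment::assay(sce, "logcounts")))
  st <- .sampler_new(split(seq_len(ncol(sce)), batches), K)
  draws <- .sampler_draw(st)$draws
  stats::setNames(lapply(draws, function(i) Xt[i, , drop = FALSE]),
                  levels(batches))
}

.adam_step <- function(params, grads, opt, lr,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  opt$m <- .tree_map2(function(m, g) b1 * m + (1 - b1) * g, opt$m, grads)
  opt$v <- .tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, opt$v, grads)
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  upd <- .tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                    opt$m, opt$v)
  list(params = .tree_map2(`-`, params, upd), opt = opt)
}

# Augmented domain-averaged loss (and optionally gradients) for a set of
# per-domain matrices; shared by the train step and the validation pass.
.loss_pass <- function(net, mats, cfg, mode, with_grads = FALSE) {
  D <- length(mats)
  total <- 0
  grads <- if (with_grads) .zero_like(net$params)
  for (d in seq_len(D)) {
    vp <- make_views(mats[[d]], p_apply = cfg$p_apply,
                     mask_fraction = cfg$mask_fraction,
                     shuffle_fraction = cfg$shuffle_fraction)
    fa <- .net_forward(net, vp$view_a, d, mode, keep_cache = with_grads)
    net <- fa$net
    fb <- .net_forward(net, vp$view_b, d, mode, keep_cache = with_grads)
    net <- fb$net
    lg <- .domain_loss_grad(fa$Y, fb$Y, cfg$lam)
    total <- total + lg$loss / D
    if (with_grads) {
      ga <- .net_backward(net, fa$cache, lg$dYa / D)
      gb <- .net_backward(net, fb$cache, lg$dYb / D)
      grads <- .tree_map2(`+`, grads, .tree_map2(`+`, ga, gb))
    }
  }
  list(loss = total, grads = grads, net = net)
}

#' Train the twin-view decorrelation model
#'
#' Optimizes the domain-averaged invariance + decorrelation objective with
#' Adam, warmup + cosine learning-rate annealing and early stopping on a
#' held-out per-domain validation split. The checkpoint with the best
#' validation loss is returned.
#'
#' @param sce Preprocessed `SingleCellExperiment` (`"logcounts"` assay,
#'   `batch` column).
#' @param net_cfg A [net_config()]; its `n_domains` must match the data.
#' @param cfg A [train_config()].
#' @param verbose Print a line every 25 epochs?
#' @return A `sctwin_checkpoint`: the best network plus configs, gene ids,
#'   domain levels and the per-epoch history
#'   (`epoch`, `train_loss`, `val_loss`, `lr`).
#' @export
fit_sctwin <- function(sce, net_cfg, cfg, verbose = FALSE) {
  stopifnot(inherits(net_cfg, "net_config"), inherits(cfg, "train_config"))
  batches <- factor(SummarizedExperiment::colData(sce)$batch)
  D <- nlevels(batches)
  if (net_cfg$n_domains != D)
    stop("net_config declares ", net_cfg$n_domains,
         " domains but data has ", D)
  Xt <- t(as.matrix(SummarizedExperiment::assay(sce, "logcounts")))
  if (ncol(Xt) != net_cfg$input_dim)
    stop("input_dim mismatch: data has ", ncol(Xt), " genes")
  net <- net_init(net_cfg, seed = cfg$seed)   # also seeds the global stream
  val_seed <- (cfg$seed %% 1000000L) + 777771L

  dom_idx <- split(seq_len(nrow(Xt)), batches)
  val_idx <- train_idx <- vector("list", D)
  for (d in seq_len(D)) {
    n_d <- length(dom_idx[[d]])
    if (n_d < 4) stop("domain ", levels(batches)[d], " has too few cells")
    nv <- max(2L, floor(n_d * cfg$val_fraction))
    v <- sample(dom_idx[[d]], nv)
    val_idx[[d]] <- v
    train_idx[[d]] <- setdiff(dom_idx[[d]], v)
  }
  val_mats <- lapply(val_idx, function(i) Xt[i, , drop = FALSE])
  steps <- ceiling(max(lengths(train_idx)) / cfg$K)
  sampler <- .sampler_new(train_idx, cfg$K)
  opt <- list(m = .zero_like(net$params), v = .zero_like(net$params), t = 0)

  best_val <- Inf; best_net <- NULL; best_epoch <- 0L; no_improve <- 0L
  hist <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(epoch, cfg$epochs, cfg$warmup_epochs, cfg$base_lr)
    ep_loss <- 0
    for (s in seq_len(steps)) {
      dr <- .sampler_draw(sampler)
      sampler <- dr$state
      mats <- lapply(dr$draws, function(i) Xt[i, , drop = FALSE])
      pass <- .loss_pass(net, mats, cfg, "train", with_grads = TRUE)
      if (!is.finite(pass$loss))
        stop("non-finite training loss at epoch ", epoch, " step ", s)
      net <- pass$net
      ep_loss <- ep_loss + pass$loss / steps
      ad <- .adam_step(net$params, pass$grads, opt, lr)
      net$params <- ad$params
      opt <- ad$opt
    }
    # validation under a fixed augmentation seed, main RNG stream untouched
    rng <- get(".Random.seed", envir = globalenv())
    set.seed(val_seed)
    val_loss <- .loss_pass(net, val_mats, cfg, "val")$loss
    assign(".Random.seed", rng, envir = globalenv())
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                val_loss = val_loss, lr = lr)
    if (verbose && epoch %% 25 == 0)
      message(sprintf("epoch %d  train %.4f  val %.4f", epoch,
                      ep_loss, val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_net <- net
      best_epoch <- epoch
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
      if (no_improve > cfg$patience) break
    }
  }
  structure(list(net = best_net, net_config = net_cfg, train_config = cfg,
                 gene_ids = rownames(sce), domain_levels = levels(batches),
                 history = do.call(rbind, hist), best_epoch = best_epoch,
                 best_val = best_val, seed = cfg$seed),
            class = "sctwin_checkpoint")
}

#' Extract integrated representations for all cells
#'
#' Runs the eval-mode encoder per domain with that domain's stored
#' normalization statistics (no augmentation; projector unused) and
#' restores the input cell order.
#'
#' @param sce Preprocessed dataset whose gene set matches the checkpoint.
#' @param ckpt A `sctwin_checkpoint` from [fit_sctwin()].
#' @return `n_cells x repr_dim` matrix with cell ids as rownames.
#' @export
embed_cells <- function(sce, ckpt) {
  stopifnot(inherits(ckpt, "sctwin_checkpoint"))
  if (!identical(rownames(sce), ckpt$gene_ids))
    stop("gene set does not match the checkpoint")
  batches <- as.character(SummarizedExperiment::colData(sce)$batch)
  unseen <- setdiff(unique(batches), ckpt$domain_levels)
  if (length(unseen))
    stop("unregistered domain: ", paste(unseen, collapse = ", "))
  Xt <- t(as.matrix(SummarizedExperiment::assay(sce, "logcounts")))
  Z <- matrix(NA_real_, nrow(Xt), ckpt$net_config$repr_dim,
              dimnames = list(colnames(sce), NULL))
  for (d in seq_along(ckpt$domain_levels)) {
    sel <- which(batches == ckpt$domain_levels[d])
    if (length(sel))
      Z[sel, ] <- encode(ckpt$net, Xt[sel, , drop = FALSE], d, "eval")
  }
  Z
}

#' Save / load a checkpoint
#'
#' The checkpoint is a single binary archive (RDS) with a JSON sidecar
#' (`<path>.json`) recording the architecture, training configuration and
#' seed for inspection without loading the weights.
#'
#' @param ckpt A `sctwin_checkpoint`.
#' @param path Destination file.
#' @return `path`, invisibly (`write_checkpoint`); the checkpoint
#'   (`read_checkpoint`).
#' @export
write_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "sctwin_checkpoint"))
  saveRDS(ckpt, path)
  side <- list(net_config = unclass(ckpt$net_config),
               train_config = unclass(ckpt$train_config),
               best_epoch = ckpt$best_epoch, seed = ckpt$seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "sctwin_checkpoint"))
  ckpt
}
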