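#' Zero out a random fraction of genes
#'
#' Sets exactly `floor(fraction * G)` positions, drawn uniformly without
#' replacement, to zero. Uses R's RNG stream.
#'
#' @param x Numeric vector (one cell's expression profile) or a cells-by-
#'   genes matrix; for a matrix the masked index set is drawn independently
#'   per row.
#' @param fraction Fraction of genes to mask, in `[0, 1]` (default 0.2).
#' @return Object of the same shape with masked entries set to 0.
#' @export
mask_genes <- function(x, fraction = 0.2) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (is.matrix(x)) {
    for (i in seq_len(nrow(x))) x[i, ] <- mask_genes(x[i, ], fraction)
    return(x)
  }
  m <- floor(fraction * length(x) + 1e-9)
  if (m > 0) x[sample.int(length(x), m)] <- 0
  x
}

#' Shuffle a random fraction of gene expression values
#'
#' Draws `floor(fraction * G)` positions without replacement and randomly
#' permutes the values sitting at those positions among themselves; the
#' global multiset of values is preserved.
#'
#' @inheritParams mask_genes
#' @param fraction Fraction of positions to permute (default 0.1).
#' @return Object of the same shape, a within-profile permutation of `x`.
#' @export
shuffle_genes <- function(x, fraction = 0.1) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (is.matrix(x)) {
    for (i in seq_len(nrow(x))) x[i, ] <- shuffle_genes(x[i, ], fraction)
    return(x)
  }
  m <- floor(fraction * length(x) + 1e-9)
  if (m > 1) {
    idx <- sample.int(length(x), m)
    x[idx] <- x[idx][sample.int(m)]
  }
  x
}

#' Create two distorted views of a mini-batch
#'
#' For each view independently, each transform (`mask_genes`, then
#' `shuffle_genes` when both fire) is applied with probability `p_apply`;
#' the fire/no-fire decision is made once per transform per view per
#' mini-batch, while masked/shuffled index sets are drawn independently per
#' cell.
#'
#' @param batch K x G numeric matrix (cells in rows).
#' @param p_apply Probability that each transform fires (default 0.5).
#' @param mask_fraction,shuffle_fraction Passed to the transforms.
#' @return A list of class `view_pair` with elements `view_a`, `view_b`
#'   (same shape as `batch`) and `applied_ops`, a 2 x 2 logical matrix of
#'   which transforms fired per view.
#' @export
make_views <- function(batch, p_apply = 0.5, mask_fraction = 0.2,
                       shuffle_fraction = 0.1) {
  if (!is.matrix(batch) || nrow(batch) == 0) stop("batch must be nonempty")
  views <- vector("list", 2)
  fired <- matrix(FALSE, 2, 2,
                  dimnames = list(c("view_a", "view_b"),
                                  c("mask", "shuffle")))
  for (v in 1:2) {
    out <- batch
    do_mask <- stats::runif(1) < p_apply
    do_shuf <- stats::runif(1) < p_apply
    if (do_mask) out <- mask_genes(out, mask_fraction)
    if (do_shuf) out <- shuffle_genes(out, shuffle_fraction)
    fired[v, ] <- c(do_mask, do_shuf)
    views[[v]] <- out
  }
  structure(list(view_a = views[[1]], view_b = views[[2]],
                 applied_ops = fired), class = "view_pair")
}
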