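#' Standardize embedding columns over a mini-batch
#'
#' Centers each column and divides by its population standard deviation
#' (denominator `K`) plus `epsilon`. This is the affine-free per-domain
#' standardization applied to projector outputs before the
#' cross-correlation; a constant column maps to all zeros.
#'
#' @param Y K x P numeric matrix, K >= 2.
#' @param epsilon Guard added to the standard deviation (default 1e-8).
#' @return K x P matrix with columnwise mean 0 and variance ~1.
#' @export
znorm_columns <- function(Y, epsilon = 1e-8) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2) stop("need at least 2 rows to standardize")
  mu <- colMeans(Y)
  U <- sweep(Y, 2, mu)
  s <- sqrt(colMeans(U^2))
  sweep(U, 2, s + epsilon, "/")
}

# Backward through znorm_columns: given upstream gradient g (K x P) and the
# forward input Y, returns dL/dY. Derivation with u = y - mean(y),
# t = s + eps, s = sqrt(mean(u^2)): dL/du = g/t - (sum(g*u)/ (t^2 K s)) u,
# then subtract the column mean (centering).
.znorm_backward <- function(Y, g, epsilon = 1e-8) {
  K <- nrow(Y)
  mu <- colMeans(Y)
  U <- sweep(Y, 2, mu)
  s <- sqrt(colMeans(U^2))
  t <- s + epsilon
  gu <- colSums(g * U)
  coef <- ifelse(s > 1e-12, gu / (t^2 * K * s), 0)
  du <- sweep(g, 2, t, "/") - sweep(U, 2, coef, "*")
  sweep(du, 2, colMeans(du))
}

#' Cross-correlation matrix of two standardized embedding batches
#'
#' `W = t(Ya_hat) %*% Yb_hat / K`. When both inputs are standardized per
#' [znorm_columns()], entry `W[i, j]` is the Pearson correlation between
#' embedding dimension `i` of view A and dimension `j` of view B over the
#' mini-batch.
#'
#' @param Ya_hat,Yb_hat K x P standardized matrices of identical shape.
#' @return P x P matrix of class `cross_corr` with attribute `K`.
#' @export
cross_correlation <- function(Ya_hat, Yb_hat) {
  if (!all(dim(Ya_hat) == dim(Yb_hat))) stop("shape mismatch")
  W <- crossprod(Ya_hat, Yb_hat) / nrow(Ya_hat)
  structure(W, K = nrow(Ya_hat), class = c("cross_corr", "matrix"))
}

#' Single-domain invariance + decorrelation loss
#'
#' `sum((1 - diag(W))^2) + lam * sum(offdiag(W)^2)`: the invariance term
#' drives same-dimension correlations between the two views to 1, the
#' decorrelation term drives distinct-dimension correlations to 0.
#'
#' @param W Square cross-correlation matrix.
#' @param lam Trade-off factor `lambda` (default 0.005).
#' @return Nonnegative scalar loss.
#' @export
domain_loss <- function(W, lam = 0.005) {
  W <- unclass(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  d <- diag(W)
  sum((1 - d)^2) + lam * (sum(W^2) - sum(d^2))
}

# dL/dW for domain_loss.
.domain_loss_backward <- function(W, lam) {
  W <- unclass(W)
  G <- 2 * lam * W
  diag(G) <- -2 * (1 - diag(W))
  G
}

#' Domain-averaged decorrelation loss over view pairs
#'
#' For each domain, standardizes both views' embeddings with
#' [znorm_columns()], forms the cross-correlation, and evaluates
#' [domain_loss()]; the total is the mean over domains.
#'
#' @param per_domain_pairs List with one element per domain, each a list
#'   `(Ya, Yb)` of raw K x P embedding matrices (the per-domain mini-batch
#'   size K may differ between domains).
#' @param lam Trade-off factor `lambda`.
#' @param epsilon Standardization guard.
#' @return A list of class `loss_breakdown` with `total` (mean of domain
#'   losses), `per_domain`, `invar` and `decorr` (summed over domains),
#'   and `lam`.
#' @export
total_loss <- function(per_domain_pairs, lam = 0.005, epsilon = 1e-8) {
  D <- length(per_domain_pairs)
  if (D == 0) stop("need at least one domain")
  per <- numeric(D)
  invar <- 0
  decorr <- 0
  for (d in seq_len(D)) {
    pair <- per_domain_pairs[[d]]
    W <- cross_correlation(znorm_columns(pair[[1]], epsilon),
                           znorm_columns(pair[[2]], epsilon))
    dg <- diag(unclass(W))
    iv <- sum((1 - dg)^2)
    dc <- sum(unclass(W)^2) - sum(dg^2)
    invar <- invar + iv
    decorr <- decorr + dc
    per[d] <- iv + lam * dc
  }
  structure(list(total = mean(per), per_domain = per,
                 invar = invar, decorr = decorr, lam = lam),
            class = "loss_breakdown")
}

# Loss + gradients w.r.t. the raw (pre-standardization) embeddings of one
# domain. Returns list(loss, dYa, dYb). The 1/D averaging over domains is
# applied by the caller.
.domain_loss_grad <- function(Ya, Yb, lam, epsilon = 1e-8) {
  Ah <- znorm_columns(Ya, epsilon)
  Bh <- znorm_columns(Yb, epsilon)
  K <- nrow(Ya)
  W <- crossprod(Ah, Bh) / K
  d <- diag(W)
  loss <- sum((1 - d)^2) + lam * (sum(W^2) - sum(d^2))
  G <- 2 * lam * W
  diag(G) <- -2 * (1 - d)
  dAh <- Bh %*% t(G) / K
  dBh <- Ah %*% G / K
  list(loss = loss,
       dYa = .znorm_backward(Ya, dAh, epsilon),
       dYb = .znorm_backward(Yb, dBh, epsilon))
}
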