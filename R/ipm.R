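#' Integral probability metric between two arms' representations
#'
#' Measures the imbalance between the encoded feature distributions of the
#' two treatment arms. Two estimators are provided:
#' \describe{
#'   \item{\code{"wasserstein-sinkhorn"}}{square root of the debiased
#'     entropic 2-Wasserstein (Sinkhorn) divergence
#'     \eqn{W_\epsilon(P,Q) - \tfrac12 W_\epsilon(P,P) - \tfrac12
#'     W_\epsilon(Q,Q)} with squared Euclidean cost and uniform marginals;
#'     debiasing makes the value exactly 0 for identical point sets, and the
#'     square root puts it on the scale of a distance (two point masses a
#'     distance \eqn{d} apart give \eqn{d}).}
#'   \item{\code{"mmd-rbf"}}{the (biased) maximum mean discrepancy under an
#'     RBF kernel, with the bandwidth set by the median heuristic on the
#'     pooled pairwise distances.}
#' }
#' Both are non-negative and symmetric in arm order, and vanish when the two
#' point sets coincide.
#'
#' Used as an additive penalty \eqn{\alpha \cdot \mathrm{IPM}} in the
#' balanced T-learner's loss, shrinking the representation imbalance between
#' arms. Gradients with respect to the representations are computed with the
#' Sinkhorn transport plans held fixed (envelope approximation).
#'
#' @param z0,z1 numeric matrices of representations (rows = subjects) for arm
#'   0 and arm 1.
#' @param kind \code{"wasserstein-sinkhorn"} or \code{"mmd-rbf"}.
#' @param epsilon entropic regularization for the Sinkhorn estimator.
#' @param n_iter maximum Sinkhorn iterations (the solver exits early on
#'   convergence).
#' @param gradient logical; attach gradients with respect to \code{z0},
#'   \code{z1} as attributes \code{"grad0"}, \code{"grad1"}.
#' @return scalar penalty >= 0.
#' @export
ipm_penalty <- function(z0, z1, kind = c("wasserstein-sinkhorn", "mmd-rbf"),
                        epsilon = 0.1, gradient = FALSE, n_iter = 500L) {
  kind <- match.arg(kind)
  if (is.null(dim(z0))) z0 <- matrix(z0, ncol = 1L)
  if (is.null(dim(z1))) z1 <- matrix(z1, ncol = 1L)
  if (nrow(z0) == 0L || nrow(z1) == 0L) {
    warning("one treatment arm is empty in this batch; IPM penalty set to 0")
    out <- 0
    if (gradient) {
      attr(out, "grad0") <- matrix(0, nrow(z0), ncol(z0))
      attr(out, "grad1") <- matrix(0, nrow(z1), ncol(z1))
    }
    return(out)
  }
  switch(kind,
         "wasserstein-sinkhorn" = sinkhorn_divergence(z0, z1, epsilon, gradient, n_iter),
         "mmd-rbf" = mmd_rbf(z0, z1, gradient))
}

sq_dists <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

# entropic OT with uniform marginals; returns <P, C> and the plan.
# Fast path: scaling iterations on K = exp(-C/eps) computed once; falls back
# to log-domain iterations when K underflows.
sinkhorn_cost <- function(C, epsilon, n_iter = 500, tol = 1e-9) {
  n <- nrow(C); m <- ncol(C)
  a <- rep(1 / n, n); b <- rep(1 / m, m)
  K <- exp(-C / epsilon)
  if (all(rowSums(K) > 1e-280) && all(colSums(K) > 1e-280)) {
    u <- rep(1, n); v <- rep(1, m)
    for (it in seq_len(n_iter)) {
      u_old <- u
      u <- a / drop(K %*% v)
      v <- b / drop(crossprod(K, u))
      if (!all(is.finite(u)) || !all(is.finite(v))) break
      if (max(abs(u - u_old) / pmax(abs(u_old), 1e-12)) < tol) break
    }
    if (all(is.finite(u)) && all(is.finite(v))) {
      P <- K * outer(u, v)
      return(list(cost = sum(P * C), plan = P))
    }
  }
  # log-domain fallback
  la <- -log(n); lb <- -log(m)
  f <- numeric(n); g <- numeric(m)
  lse_rows <- function(M) {
    mx <- apply(M, 1L, max)
    mx + log(rowSums(exp(M - mx)))
  }
  for (it in seq_len(n_iter)) {
    f_old <- f
    f <- -epsilon * lse_rows(sweep(-C, 2L, g, "+") / epsilon + lb)
    g <- -epsilon * lse_rows(t(sweep(-C, 1L, f, "+")) / epsilon + la)
    if (max(abs(f - f_old)) < tol) break
  }
  logP <- (outer(f, g, "+") - C) / epsilon + la + lb
  P <- exp(logP)
  list(cost = sum(P * C), plan = P)
}

sinkhorn_divergence <- function(z0, z1, epsilon, gradient, n_iter = 500L) {
  Cxy <- sq_dists(z0, z1)
  Cxx <- sq_dists(z0, z0)
  Cyy <- sq_dists(z1, z1)
  sxy <- sinkhorn_cost(Cxy, epsilon, n_iter)
  sxx <- sinkhorn_cost(Cxx, epsilon, n_iter)
  syy <- sinkhorn_cost(Cyy, epsilon, n_iter)
  div <- max(sxy$cost - 0.5 * sxx$cost - 0.5 * syy$cost, 0)
  val <- sqrt(div)
  if (!gradient) return(val)

  # d<P,C>/dX with the plan fixed; C_ij = ||x_i - y_j||^2
  grad_cross <- function(P, X, Y) {
    rs <- rowSums(P)
    2 * (X * rs - P %*% Y)
  }
  grad_self <- function(P, X) {
    # both margins of the self plan touch X
    rs <- rowSums(P); cs <- colSums(P)
    2 * (X * (rs + cs) - (P + t(P)) %*% X)
  }
  d0 <- grad_cross(sxy$plan, z0, z1) - 0.5 * grad_self(sxx$plan, z0)
  d1 <- grad_cross(t(sxy$plan), z1, z0) - 0.5 * grad_self(syy$plan, z1)
  scale <- if (val > 1e-8) 1 / (2 * val) else 0
  attr(val, "grad0") <- d0 * scale
  attr(val, "grad1") <- d1 * scale
  val
}

mmd_rbf <- function(z0, z1, gradient) {
  Dxx <- sq_dists(z0, z0); Dyy <- sq_dists(z1, z1); Dxy <- sq_dists(z0, z1)
  pooled <- c(Dxx[upper.tri(Dxx)], Dyy[upper.tri(Dyy)], as.vector(Dxy))
  med <- stats::median(pooled[pooled > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  gamma <- 1 / med                       # k(u,v) = exp(-||u-v||^2 / median)
  Kxx <- exp(-gamma * Dxx); Kyy <- exp(-gamma * Dyy); Kxy <- exp(-gamma * Dxy)
  mmd2 <- mean(Kxx) + mean(Kyy) - 2 * mean(Kxy)
  val <- sqrt(max(mmd2, 0))
  if (!gradient) return(val)
  n <- nrow(z0); m <- nrow(z1)
  # d mmd2 / dx_i, bandwidth treated as fixed
  gKxx <- -gamma * Kxx; gKxy <- -gamma * Kxy; gKyy <- -gamma * Kyy
  d0 <- (2 / n^2) * 2 * (z0 * rowSums(gKxx) - gKxx %*% z0) -
    (2 / (n * m)) * 2 * (z0 * rowSums(gKxy) - gKxy %*% z1)
  d1 <- (2 / m^2) * 2 * (z1 * rowSums(gKyy) - gKyy %*% z1) -
    (2 / (n * m)) * 2 * (z1 * rowSums(t(gKxy)) - t(gKxy) %*% z0)
  scale <- if (val > 1e-8) 1 / (2 * val) else 0
  attr(val, "grad0") <- d0 * scale
  attr(val, "grad1") <- d1 * scale
  val
}
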