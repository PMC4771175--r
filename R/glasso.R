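# Graphical lasso: l1-penalized Gaussian precision estimation by the
# classic block coordinate descent over columns of the covariance estimate
# W, each column update solving a lasso subproblem by coordinate descent.
# The estimate maximizes log det(Theta) - tr(S Theta) - rho * ||Theta||_1
# (off-diagonal penalty applied to all entries, diagonal of W fixed at
# S_ii + rho as in the standard algorithm).

soft_threshold <- function(z, t) {
  sign(z) * pmax(abs(z) - t, 0)
}

#' Graphical lasso precision estimate
#'
#' @param s sample covariance matrix.
#' @param rho nonnegative l1 penalty.
#' @param maxit maximum outer sweeps over columns.
#' @param tol relative convergence tolerance on the working covariance.
#' @return list with `w` (estimated covariance), `theta` (precision
#'   estimate) and `iterations`.
#' @export
graphical_lasso <- function(s, rho, maxit = 200L, tol = 1e-5) {
  assert_symmetric(s, what = "covariance")
  if (rho < 0) stop("`rho` must be nonnegative", call. = FALSE)
  p <- ncol(s)
  w <- s
  diag(w) <- diag(s) + rho
  betas <- matrix(0, p - 1L, p)
  off <- mean(abs(s[upper.tri(s)]))
  thr <- tol * max(off, 1e-12)
  it <- 0L
  repeat {
    it <- it + 1L
    w_old <- w
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      w11 <- w[idx, idx, drop = FALSE]
      s12 <- s[idx, j]
      b <- betas[, j]
      # lasso coordinate descent on 0.5 b'W11 b - s12'b + rho|b|_1
      for (inner in 1:100) {
        delta <- 0
        for (k in seq_len(p - 1L)) {
          grad <- s12[k] - sum(w11[k, ] * b) + w11[k, k] * b[k]
          bk <- soft_threshold(grad, rho) / w11[k, k]
          delta <- max(delta, abs(bk - b[k]))
          b[k] <- bk
        }
        if (delta < thr) break
      }
      betas[, j] <- b
      w12 <- drop(w11 %*% b)
      w[idx, j] <- w12
      w[j, idx] <- w12
    }
    if (max(abs(w - w_old)) < thr || it >= maxit) break
  }
  if (it >= maxit && max(abs(w - w_old)) >= thr) {
    stop("graphical lasso did not converge in ", maxit,
         " iterations at rho = ", rho, call. = FALSE)
  }
  theta <- matrix(0, p, p, dimnames = dimnames(s))
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    b <- betas[, j]
    t22 <- 1 / (w[j, j] - sum(w[idx, j] * b))
    theta[j, j] <- t22
    theta[idx, j] <- -b * t22
  }
  theta <- (theta + t(theta)) / 2
  list(w = w, theta = theta, iterations = it)
}
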