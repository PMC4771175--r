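# Regression route to partial correlation: regress each antibody on all
# others under the variant's penalty, then symmetrize the coefficient
# matrix B into partial correlations by
#   pc_ij = sign(B_ij) * sqrt(max(0, B_ij * B_ji)),
# which is exact for ordinary least squares on standardized data and zero
# when the two directed coefficients disagree in sign.

default_penalty_grid <- function() {
  10^seq(-4, 2, length.out = 10L)
}

default_mixing_grid <- function() c(0.25, 0.5, 0.75)

default_ncomp_grid <- function() 1:8

parcor_regression <- function(x, method, params, seed) {
  n <- nrow(x)
  p <- ncol(x)
  cv_folds <- params$cv_folds %||% 5L
  if (n < max(5L, cv_folds)) {
    stop("need at least max(5, cv_folds) samples", call. = FALSE)
  }
  xs <- scale(x)
  b <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  chosen <- vector("list", p)

  if (method == "plsnet") {
    grid <- params$ncomp_grid %||% default_ncomp_grid()
    if (length(grid) == 0L) stop("empty component grid", call. = FALSE)
    grid <- grid[grid <= p - 1L & grid < n]
    foldid <- cv_foldid(n, cv_folds, seed)
    for (j in seq_len(p)) {
      z <- xs[, -j, drop = FALSE]
      y <- xs[, j]
      ncomp <- params$ncomp %||% cv_ncomp(z, y, grid, foldid)
      fit <- simpls_coef(z, y, max(ncomp))
      b[j, -j] <- fit[, ncomp]
      chosen[[j]] <- ncomp
    }
    params$ncomp_selected <- unlist(chosen)
  } else {
    alpha_grid <- switch(method,
      ridgenet = 0,
      lassonet = 1,
      elasticnet = params$mixing %||% default_mixing_grid()
    )
    grid <- params$penalties %||% default_penalty_grid()
    if (length(grid) == 0L) stop("empty penalty grid", call. = FALSE)
    lambda_path <- sort(unique(c(grid, params$penalty)), decreasing = TRUE)
    foldid <- cv_foldid(n, cv_folds, seed)
    for (j in seq_len(p)) {
      z <- xs[, -j, drop = FALSE]
      y <- xs[, j]
      if (!is.null(params$penalty)) {
        alpha <- if (method == "elasticnet") {
          params$mixing %||% 0.5
        } else {
          alpha_grid[1L]
        }
        fit <- glmnet::glmnet(z, y, alpha = alpha, lambda = lambda_path,
                              standardize = FALSE, intercept = FALSE)
        beta <- as.numeric(stats::coef(fit, s = params$penalty))[-1L]
        sel <- c(penalty = params$penalty, mixing = alpha)
      } else {
        best <- NULL
        for (alpha in alpha_grid) {
          cvf <- glmnet::cv.glmnet(z, y, alpha = alpha,
                                   lambda = lambda_path, foldid = foldid,
                                   standardize = FALSE, intercept = FALSE)
          cand <- list(alpha = alpha, lambda = cvf$lambda.min,
                       cvm = min(cvf$cvm), fit = cvf)
          if (is.null(best) || cand$cvm < best$cvm) best <- cand
        }
        beta <- as.numeric(stats::coef(best$fit, s = best$lambda))[-1L]
        sel <- c(penalty = best$lambda, mixing = best$alpha)
      }
      b[j, -j] <- beta
      chosen[[j]] <- sel
    }
    params$penalty_selected <- vapply(chosen, `[[`, 0, "penalty")
    if (method == "elasticnet") {
      params$mixing_selected <- vapply(chosen, `[[`, 0, "mixing")
    }
  }

  list(w = symmetrize_coefficients(b), params = params)
}

# pc_ij = sign(B_ij) * sqrt(max(0, B_ij * B_ji)): zero whenever the two
# directed coefficients disagree in sign.
symmetrize_coefficients <- function(b) {
  sign(b) * sqrt(pmax(0, b * t(b)))
}

# Deterministic cross-validation fold assignment.
cv_foldid <- function(n, nfolds, seed) {
  with_seed(derive_seed(seed, "cvfold"), sample(rep_len(seq_len(nfolds), n)))
}

# SIMPLS partial least squares for a single response; returns the
# regression coefficient vectors for 1..ncomp latent components as columns
# (cumulative, so column a is the a-component fit).
simpls_coef <- function(z, y, ncomp) {
  p <- ncol(z)
  ncomp <- min(ncomp, p, nrow(z) - 1L)
  s <- drop(crossprod(z, y))
  v_basis <- matrix(0, p, 0L)
  coefs <- matrix(0, p, ncomp)
  b <- numeric(p)
  for (a in seq_len(ncomp)) {
    r <- s
    t_vec <- drop(z %*% r)
    nt <- sqrt(sum(t_vec^2))
    if (nt < 1e-12) {
      # response fully explained; pad remaining columns
      if (a <= ncomp) coefs[, a:ncomp] <- b
      break
    }
    t_vec <- t_vec / nt
    r <- r / nt
    p_load <- drop(crossprod(z, t_vec))
    q_load <- sum(y * t_vec)
    v <- p_load
    if (ncol(v_basis)) v <- v - v_basis %*% crossprod(v_basis, p_load)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) {
      v <- v / nv
      v_basis <- cbind(v_basis, v)
      s <- s - v * drop(crossprod(v, s))
    } else {
      s <- s * 0
    }
    b <- b + r * q_load
    coefs[, a] <- b
  }
  coefs
}

# Cross-validated choice of the PLS component count by prediction error.
cv_ncomp <- function(z, y, grid, foldid) {
  press <- numeric(length(grid))
  for (f in sort(unique(foldid))) {
    test <- foldid == f
    zt <- z[!test, , drop = FALSE]
    yt <- y[!test]
    mu_z <- colMeans(zt)
    mu_y <- mean(yt)
    fit <- simpls_coef(sweep(zt, 2L, mu_z), yt - mu_y, max(grid))
    pred <- sweep(z[test, , drop = FALSE], 2L, mu_z) %*%
      fit[, pmin(grid, ncol(fit)), drop = FALSE] + mu_y
    press <- press + colSums((pred - y[test])^2)
  }
  grid[which.min(press)]
}
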