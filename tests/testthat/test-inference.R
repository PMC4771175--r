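test_that("correlation estimators match direct formulas and invariances", {
  x <- matrix(c(1, 2, 3, 4, 5,
                2, 1, 4, 3, 6,
                5, 3, 1, 2, 4), 5, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  net <- infer_network(x, "pearsoncor")
  # one-line independent oracle for the sample correlation
  oracle <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(net$weights["A", "B"], oracle(x[, 1], x[, 2]))
  expect_equal(net$weights["A", "C"], oracle(x[, 1], x[, 3]))

  # exact linear dependence
  y <- cbind(A = x[, 1], B = 2 * x[, 1], C = x[, 3])
  expect_equal(infer_network(y, "pearsoncor")$weights["A", "B"], 1)

  # monotone nonlinear: spearman saturates, pearson does not
  z <- cbind(A = x[, 1], B = x[, 1]^3, C = x[, 3])
  expect_equal(infer_network(z, "spearmancor")$weights["A", "B"], 1)
  expect_lt(infer_network(z, "pearsoncor")$weights["A", "B"], 1)

  # affine / monotone per-column invariance
  set.seed(42)
  r <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("A", "B", "C")))
  r2 <- r
  r2[, 2] <- 3 * r[, 2] + 7
  expect_equal(infer_network(r, "pearsoncor")$weights,
               infer_network(r2, "pearsoncor")$weights)
  r3 <- r
  r3[, 2] <- exp(r[, 2])
  expect_equal(infer_network(r, "spearmancor")$weights,
               infer_network(r3, "spearmancor")$weights)

  expect_error(infer_network(cbind(r[, 1:2], D = 1), "pearsoncor"), "D")
})

test_that("partial correlation removes the transitive edge of a chain", {
  gt <- make_chain_gt(3, w = 0.5)
  # closed form: chain precision gives parcor(A,C) = 0 while cor(A,C) != 0
  st <- sample_cohorts(gt, c(X = 4000), noise_sd = 0, seed = 5)
  x <- st$cohorts$X
  for (variant in c("simpleparcor", "genenet")) {
    w <- coef(infer_network(x, variant))
    expect_lt(abs(w["AB001", "AB003"]), 0.05)
    expect_gt(abs(w["AB001", "AB002"]), 0.3)
  }
  expect_gt(abs(cor(x[, 1], x[, 3])), 0.1)
})

test_that("shrinkage estimate approaches the simple estimate for n >> p", {
  gt <- make_chain_gt(6, w = 0.5)
  st <- sample_cohorts(gt, c(X = 15000), noise_sd = 0, seed = 8)
  simple <- coef(infer_network(st$cohorts$X, "simpleparcor"))
  shrunk <- coef(infer_network(st$cohorts$X, "genenet"))
  expect_lt(max(abs(simple - shrunk)), 1e-3)
})

test_that("graphical lasso satisfies its optimality conditions and limits", {
  gt <- make_chain_gt(6, w = 0.5)
  st <- sample_cohorts(gt, c(X = 500), noise_sd = 0, seed = 3)
  s <- cov(st$cohorts$X)
  rho <- 0.05
  fit <- graphical_lasso(s, rho = rho)
  # KKT: |W - S| <= rho off-diagonal, equality with matching sign on the
  # support of Theta
  resid <- fit$w - s
  diag(resid) <- 0
  expect_lte(max(abs(resid)), rho + 1e-4)
  supp <- which(abs(fit$theta) > 1e-8 & row(fit$theta) != col(fit$theta))
  expect_equal(resid[supp], rho * sign(fit$theta)[supp], tolerance = 1e-3)
  expect_lt(max(abs(fit$w %*% fit$theta - diag(6))), 1e-2)

  # heavy penalization empties the network
  net <- infer_network(st$cohorts$X, "glasso", params = list(rho = 10))
  expect_equal(max(abs(net$weights)), 0)
  expect_error(graphical_lasso(s, rho = -1), "nonnegative")
})

test_that("ridge regression at vanishing penalty matches inverse covariance", {
  gt <- generate_ground_truth(10, density = 0.2, seed = 13)
  st <- sample_cohorts(gt, c(X = 2000), noise_sd = 0, seed = 14)
  x <- st$cohorts$X
  simple <- coef(infer_network(x, "simpleparcor"))
  ridge <- coef(infer_network(x, "ridgenet", params = list(penalty = 1e-4)))
  expect_lt(max(abs(simple - ridge)), 1e-2)
})

test_that("lasso at heavy penalty gives the empty network", {
  gt <- make_chain_gt(5)
  st <- sample_cohorts(gt, c(X = 100), seed = 4)
  net <- infer_network(st$cohorts$X, "lassonet", params = list(penalty = 100))
  expect_equal(max(abs(net$weights)), 0)
  expect_error(
    infer_network(st$cohorts$X, "lassonet", params = list(penalties = numeric(0))),
    "empty penalty grid"
  )
})

test_that("coefficient symmetrization zeroes sign conflicts", {
  b <- matrix(c(0, 0.5, 0.2,
                -0.4, 0, 0.1,
                0.3, 0.2, 0), 3, 3, byrow = TRUE)
  w <- ppinet:::symmetrize_coefficients(b)
  # hand-applied formula: sign conflict (0.5, -0.4) -> 0;
  # agreeing (0.2, 0.3) -> sqrt(0.06); (0.1, 0.2) -> sqrt(0.02)
  expect_equal(w[1, 2], 0)
  expect_equal(w[2, 1], 0)
  expect_equal(w[1, 3], sqrt(0.2 * 0.3))
  expect_equal(w[2, 3], sqrt(0.1 * 0.2))
})

test_that("partial least squares approximates the full regression route", {
  gt <- generate_ground_truth(8, density = 0.25, seed = 31)
  st <- sample_cohorts(gt, c(X = 3000), noise_sd = 0, seed = 32)
  x <- st$cohorts$X
  simple <- coef(infer_network(x, "simpleparcor"))
  pls <- coef(infer_network(x, "plsnet", params = list(ncomp = 7L)))
  expect_lt(max(abs(simple - pls)), 5e-2)
})

test_that("k-NN mutual information behaves on known distributions", {
  set.seed(9)
  n <- 2000
  x <- cbind(A = rnorm(n), B = rnorm(n), C = runif(n))
  mi <- estimate_mi(x, k_neighbors = 3)
  expect_lt(mean(mi[upper.tri(mi)]), 0.05)  # independents: MI ~ 0

  # bivariate normal, rho = 0.9: MI = -0.5 log(1 - rho^2)
  rho <- 0.9
  n2 <- 5000
  z1 <- rnorm(n2)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n2)
  mi2 <- estimate_mi(cbind(A = z1, B = z2, C = rnorm(n2)))
  truth <- -0.5 * log(1 - rho^2)
  expect_lt(abs(mi2["A", "B"] - truth) / truth, 0.25)

  # exact duplication maximizes MI
  y <- cbind(A = rnorm(300), C = rnorm(300))
  y <- cbind(y, B = y[, "A"])
  mi3 <- estimate_mi(y)
  expect_equal(max(mi3), mi3["A", "B"])

  expect_error(estimate_mi(cbind(A = rnorm(10), B = rep(1, 10))), "B")
  expect_error(estimate_mi(x, k_neighbors = n), "k_neighbors")
})

test_that("ARACNE prunes the weakest edge of a triangle", {
  mi <- matrix(c(0, 0.9, 0.3,
                 0.9, 0, 0.8,
                 0.3, 0.8, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  net <- infer_network(matrix(rnorm(30), 10, 3,
                              dimnames = list(NULL, c("A", "B", "C"))),
                       "aracne.a", params = list(eps = 0, mi = mi))
  expect_equal(net$weights["A", "C"], 0)
  expect_equal(net$weights["A", "B"], 0.9)
  expect_equal(net$weights["B", "C"], 0.8)
  expect_error(ppinet:::aracne_prune(mi, eps = -1), "nonnegative")
})

test_that("ARACNE pruning is monotone in its tolerance", {
  set.seed(15)
  x <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(NULL, sprintf("AB%03d", 1:8)))
  mi <- estimate_mi(x)
  prev_a <- NULL
  prev_m <- NULL
  for (tol in c(0.2, 0.1, 0.05, 0)) {
    wa <- ppinet:::aracne_prune(mi, eps = tol)
    wm <- ppinet:::aracne_prune(mi, tau = tol, multiplicative = TRUE)
    if (!is.null(prev_a)) {
      # shrinking the tolerance can only remove edges
      expect_true(all(wa[prev_a == 0] == 0))
      expect_true(all(wm[prev_m == 0] == 0))
    }
    prev_a <- wa
    prev_m <- wm
  }
})

test_that("CLR vanishes on a flat MI landscape", {
  mi <- matrix(0.4, 4, 4)
  diag(mi) <- 0
  w <- ppinet:::clr_scores(mi)
  expect_equal(max(abs(w)), 0)
})

test_that("MRNET scores equal exhaustive forward selection on 4 variables", {
  set.seed(77)
  mi <- matrix(runif(16, 0, 1), 4)
  mi <- (mi + t(mi)) / 2
  diag(mi) <- 0
  got <- ppinet:::mrnet_scores(mi)
  # independent plain-loop oracle
  oracle_dir <- matrix(0, 4, 4)
  for (t in 1:4) {
    cand <- setdiff(1:4, t)
    sel <- integer(0)
    repeat {
      if (!length(cand)) break
      u <- numeric(length(cand))
      for (ci in seq_along(cand)) {
        j <- cand[ci]
        red <- 0
        if (length(sel)) {
          for (s in sel) red <- red + mi[j, s]
          red <- red / length(sel)
        }
        u[ci] <- mi[j, t] - red
      }
      if (max(u) <= 0) break
      j <- cand[which.max(u)]
      oracle_dir[j, t] <- max(u)
      sel <- c(sel, j)
      cand <- setdiff(cand, j)
    }
  }
  expect_equal(got, pmax(oracle_dir, t(oracle_dir)), ignore_attr = TRUE)
})

test_that("edge ranking averages ties and conserves rank mass", {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- 0.9; w["B", "A"] <- 0.9
  w["A", "C"] <- -0.9; w["C", "A"] <- -0.9
  w["B", "C"] <- 0.1; w["C", "B"] <- 0.1
  rk <- rank_edges(make_net(w))
  ranks <- setNames(rk$edges$rank, pkey(rk$edges$a, rk$edges$b))
  expect_equal(unname(ranks[pkey("A", "B")]), 1.5)
  expect_equal(unname(ranks[pkey("A", "C")]), 1.5)
  expect_equal(unname(ranks[pkey("B", "C")]), 3)

  # all-zero network: every pair shares the average rank (m+1)/2
  rk0 <- rank_edges(make_net(matrix(0, 4, 4)))
  expect_true(all(rk0$edges$rank == (6 + 1) / 2))

  # rank sums are conserved for any network
  set.seed(3)
  m <- matrix(rnorm(49), 7)
  rkr <- rank_edges(make_net((m + t(m)) / 2))
  expect_equal(sum(rkr$edges$rank), 21 * 22 / 2)
})

test_that("every estimator emits a valid symmetric network", {
  set.seed(99)
  x <- matrix(rnorm(60 * 6), 60, 6,
              dimnames = list(NULL, sprintf("AB%03d", 1:6)))
  for (method in ppi_methods()) {
    net <- infer_network(x, method)
    expect_equal(net$weights, t(net$weights))
    expect_equal(unname(diag(net$weights)), rep(0, 6))
    if (!net$signed) expect_true(all(net$weights >= 0))
    expect_identical(net$antibody_ids, colnames(x))
  }
})

test_that("inference rejects degenerate inputs", {
  x <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_error(infer_network(x[1:2, ], "pearsoncor"), "3 samples")
  expect_error(infer_network(x[, 1:2], "pearsoncor"), "3 antibodies")
  expect_error(infer_network(x, "ridgenet"), "max\\(5, cv_folds\\)")
})
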