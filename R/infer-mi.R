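#' Pairwise k-nearest-neighbour mutual information
#'
#' Kraskov-Stoegbauer-Grassberger (first algorithm) estimate of mutual
#' information in nats for every antibody pair, clamped at zero. The
#' estimator is nonparametric: for each sample the Chebyshev distance to
#' its k-th joint-space neighbour defines a box whose marginal neighbour
#' counts enter the digamma correction.
#'
#' @param x numeric samples x antibodies matrix.
#' @param k_neighbors neighbour count (default 3; must be below the sample
#'   count).
#' @return symmetric nonnegative matrix with zero diagonal.
#' @export
estimate_mi <- function(x, k_neighbors = 3L) {
  if (inherits(x, "expression_dataset")) x <- x$matrix
  if (k_neighbors < 1L || k_neighbors >= nrow(x)) {
    stop("`k_neighbors` must be in [1, n_samples)", call. = FALSE)
  }
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop("constant antibody column: ", colnames(x)[which(sds == 0)[1L]],
         call. = FALSE)
  }
  mi <- knn_mi_matrix(x, as.integer(k_neighbors))
  dimnames(mi) <- list(colnames(x), colnames(x))
  mi
}

# Dispatch a mutual-information matrix to the requested network scheme.
mi_network <- function(mi, method, params) {
  assert_symmetric(mi, what = "MI matrix")
  if (any(mi < 0)) stop("MI matrix must be nonnegative", call. = FALSE)
  switch(method,
    aracne.a = aracne_prune(mi, eps = params$eps %||% 0, multiplicative = FALSE),
    aracne.m = aracne_prune(mi, tau = params$tau %||% 0, multiplicative = TRUE),
    clr = clr_scores(mi),
    mrnet = mrnet_scores(mi)
  )
}

# Data-processing-inequality pruning: in every triangle (i, j, k) the edge
# (i, j) is removed when its MI falls below the weaker of the two other
# sides, minus an additive tolerance eps or scaled by (1 - tau). All
# removals are evaluated on the original matrix (simultaneous pruning).
aracne_prune <- function(mi, eps = 0, tau = 0, multiplicative = FALSE) {
  if (eps < 0 || tau < 0) {
    stop("`eps` and `tau` must be nonnegative", call. = FALSE)
  }
  p <- ncol(mi)
  out <- mi
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      others <- setdiff(seq_len(p), c(i, j))
      if (!length(others)) next
      bound <- max(pmin(mi[i, others], mi[j, others]))
      cut <- if (multiplicative) bound * (1 - tau) else bound - eps
      if (mi[i, j] < cut) {
        out[i, j] <- 0
        out[j, i] <- 0
      }
    }
  }
  out
}

# Context likelihood of relatedness: each MI value is standardized against
# the mean and sd of its row background (diagonal excluded, z clamped at
# zero) and the two z-scores are combined in quadrature.
clr_scores <- function(mi) {
  p <- ncol(mi)
  z <- matrix(0, p, p)
  for (i in seq_len(p)) {
    row <- mi[i, -i]
    mu <- mean(row)
    s <- sd(row)
    zi <- if (is.na(s) || s == 0) rep(0, p) else (mi[i, ] - mu) / s
    z[i, ] <- pmax(zi, 0)
  }
  w <- sqrt(z^2 + t(z)^2)
  diag(w) <- 0
  dimnames(w) <- dimnames(mi)
  w
}

# Maximum-relevance / minimum-redundancy network scores: for each target,
# greedy forward selection over the remaining variables maximizing
# relevance MI(x_j, y) minus mean redundancy with the selected set; a
# variable's directed score is its criterion value when selected
# (selection stops when the best criterion is nonpositive). The undirected
# score is the maximum of the two directed scores.
mrnet_scores <- function(mi) {
  p <- ncol(mi)
  s_dir <- matrix(0, p, p)
  for (t in seq_len(p)) {
    candidates <- setdiff(seq_len(p), t)
    selected <- integer(0)
    while (length(candidates)) {
      u <- vapply(candidates, function(j) {
        red <- if (length(selected)) mean(mi[j, selected]) else 0
        mi[j, t] - red
      }, 0)
      best <- which.max(u)
      if (u[best] <= 0) break
      jstar <- candidates[best]
      s_dir[jstar, t] <- u[best]
      selected <- c(selected, jstar)
      candidates <- candidates[-best]
    }
  }
  w <- pmax(s_dir, t(s_dir))
  diag(w) <- 0
  dimnames(w) <- dimnames(mi)
  w
}
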