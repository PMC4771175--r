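#' The thirteen supported network-inference methods
#'
#' Four algorithm families are covered: sample correlation
#' (`pearsoncor`, `spearmancor`), partial correlation from the
#' (pseudo-)inverse covariance (`simpleparcor`, `genenet`, `glasso`),
#' partial correlation from penalized node-wise regression (`ridgenet`,
#' `lassonet`, `elasticnet`, `plsnet`), and k-nearest-neighbour mutual
#' information networks (`aracne.a`, `aracne.m`, `clr`, `mrnet`).
#'
#' @return character vector of method names.
#' @export
ppi_methods <- function() {
  c("pearsoncor", "spearmancor",
    "simpleparcor", "genenet", "glasso",
    "ridgenet", "lassonet", "elasticnet", "plsnet",
    "aracne.a", "aracne.m", "clr", "mrnet")
}

mi_family <- function() c("aracne.a", "aracne.m", "clr", "mrnet")

#' Infer a weighted interaction network from an expression matrix
#'
#' Central estimator of the package: maps a samples x antibodies matrix to
#' a symmetric weighted network (zero diagonal) carrying a significance
#' interpretation of |weight|. Correlation and partial-correlation families
#' return signed weights in [-1, 1]; the mutual-information family returns
#' nonnegative weights in nats.
#'
#' Method parameters are passed through `params`:
#' \describe{
#'   \item{glasso}{`rho`: the l1 penalty (default 0.1).}
#'   \item{ridgenet / lassonet / elasticnet}{`penalty` (and `mixing` for
#'     the elastic net) fix the penalty; when absent, the penalty is chosen
#'     per node by `cv_folds`-fold cross-validated prediction error over
#'     `penalties` (default log-spaced 1e-4 to 1e2).}
#'   \item{plsnet}{`ncomp` fixes the number of latent components; when
#'     absent it is cross-validated over `ncomp_grid` (default 1 to 8).}
#'   \item{aracne.a / aracne.m}{`eps` / `tau`: the additive /
#'     multiplicative tolerance of the data-processing-inequality pruning
#'     (default 0); `k_neighbors` for the MI estimator (default 3).}
#'   \item{clr / mrnet}{`k_neighbors` (default 3).}
#' }
#' The MI family also accepts a precomputed `mi` matrix to avoid repeated
#' estimation during grid searches.
#'
#' @param x numeric samples x antibodies matrix (or an
#'   [expression_dataset()], whose full matrix is used).
#' @param method one of [ppi_methods()].
#' @param params named list of method parameters (see Details).
#' @param seed integer seed for the method's internal randomness
#'   (cross-validation fold assignment); fixed by default so repeated calls
#'   agree.
#' @return An object of class `ppi_network`: `weights` (symmetric matrix,
#'   zero diagonal), `antibody_ids`, `method`, `params` (as resolved,
#'   including selected penalties), and `signed`.
#' @export
#' @examples
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("AB", 1:4)))
#' net <- infer_network(x, "pearsoncor")
#' coef(net)[1:2, 1:2]
infer_network <- function(x, method = ppi_methods(), params = list(),
                          seed = 1L) {
  method <- match.arg(method)
  if (inherits(x, "expression_dataset")) x <- x$matrix
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("AB%03d", seq_len(ncol(x)))
  }
  if (nrow(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (ncol(x) < 3L) stop("need at least 3 antibodies", call. = FALSE)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop("zero-variance antibody: ", colnames(x)[which(sds == 0)[1L]],
         call. = FALSE)
  }

  signed <- !(method %in% mi_family())
  w <- switch(
    method,
    pearsoncor = cor(x, method = "pearson"),
    spearmancor = cor(x, method = "spearman"),
    simpleparcor = parcor_from_precision(precision_pseudoinverse(cov(x))),
    genenet = parcor_shrinkage(x),
    glasso = {
      params$rho <- params$rho %||% 0.1
      fit <- graphical_lasso(cov(x), rho = params$rho)
      parcor_from_precision(fit$theta)
    },
    ridgenet = ,
    lassonet = ,
    elasticnet = ,
    plsnet = {
      res <- parcor_regression(x, method, params, seed)
      params <- res$params
      res$w
    },
    aracne.a = ,
    aracne.m = ,
    clr = ,
    mrnet = {
      params$k_neighbors <- params$k_neighbors %||% 3L
      mi <- params$mi %||% estimate_mi(x, params$k_neighbors)
      params$mi <- NULL
      mi_network(mi, method, params)
    }
  )
  diag(w) <- 0
  dimnames(w) <- list(colnames(x), colnames(x))
  structure(
    list(weights = (w + t(w)) / 2, antibody_ids = colnames(x),
         method = method, params = params, signed = signed),
    class = "ppi_network"
  )
}

# Partial correlations from a precision matrix:
# w_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj).
parcor_from_precision <- function(theta) {
  d <- sqrt(abs(diag(theta)))
  w <- -theta / tcrossprod(d)
  diag(w) <- 0
  w
}

# Inverse covariance, falling back to the Moore-Penrose pseudo-inverse when
# the sample covariance is singular (the route the unregularized estimator
# takes when n < p).
precision_pseudoinverse <- function(s) {
  out <- tryCatch(chol2inv(chol(s)), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out))) out <- MASS::ginv(s)
  dimnames(out) <- dimnames(s)
  out
}

# Schaefer-Strimmer analytic shrinkage of the correlation matrix toward the
# identity, then partial correlation from its inverse (corpcor's estimator,
# the engine behind the shrunken-covariance method).
parcor_shrinkage <- function(x) {
  w <- suppressWarnings(corpcor::pcor.shrink(x, verbose = FALSE))
  lambda <- attr(w, "lambda")
  w <- as.matrix(w[seq_len(ncol(x)), seq_len(ncol(x))])
  attr(w, "lambda") <- lambda
  w
}

#' Rank the edges of an inferred network
#'
#' Orders all C(n,2) antibody pairs by decreasing |weight|. Tied pairs
#' receive their average rank (used for consensus aggregation) and are
#' traversed in deterministic lexicographic pair order when a total order
#' is needed (precision-recall curves, serialization).
#'
#' @param net a `ppi_network`.
#' @return An object of class `edge_ranking`: `edges` (data frame `a`,
#'   `b`, `weight`, `rank`, ordered most significant first),
#'   `antibody_ids`, `method`, `signed`.
#' @export
rank_edges <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  edges <- pair_table(net$antibody_ids)
  edges$weight <- upper_values(net$weights)
  edges$rank <- rank(-abs(edges$weight), ties.method = "average")
  ord <- order(-abs(edges$weight), edges$a, edges$b)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(edges = edges, antibody_ids = net$antibody_ids,
         method = net$method, signed = net$signed),
    class = "edge_ranking"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  w <- upper_values(x$weights)
  cat("Inferred network (", x$method, "): ",
      length(x$antibody_ids), " antibodies, ",
      sum(w != 0), "/", length(w), " nonzero pairs, ",
      if (x$signed) "signed" else "unsigned", " weights\n", sep = "")
  invisible(x)
}

#' @export
summary.ppi_network <- function(object, ...) {
  w <- upper_values(object$weights)
  out <- list(
    method = object$method,
    n_antibodies = length(object$antibody_ids),
    n_pairs = length(w),
    n_nonzero = sum(w != 0),
    signed = object$signed,
    weight_range = range(w),
    n_negative = sum(w < 0),
    params = object$params
  )
  class(out) <- "summary.ppi_network"
  out
}

#' @export
print.summary.ppi_network <- function(x, ...) {
  cat("Method:", x$method, "\n")
  cat("Antibodies:", x$n_antibodies, " Pairs:", x$n_pairs,
      " Nonzero:", x$n_nonzero, "\n")
  cat("Weights:", if (x$signed) "signed" else "unsigned",
      sprintf(" range [%.3g, %.3g], %d negative\n",
              x$weight_range[1], x$weight_range[2], x$n_negative))
  if (length(x$params)) {
    scal <- Filter(function(p) is.atomic(p) && length(p) == 1L, x$params)
    if (length(scal)) {
      cat("Parameters:",
          paste(names(scal), vapply(scal, format, ""), sep = "=",
                collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @export
coef.ppi_network <- function(object, ...) {
  object$weights
}

#' @export
plot.ppi_network <- function(x, ...) {
  w <- x$weights
  n <- ncol(w)
  graphics::image(seq_len(n), seq_len(n), t(w[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste("weights:", x$method), ...)
  invisible(x)
}

#' @export
print.edge_ranking <- function(x, ...) {
  cat("Edge ranking (", x$method, "): ", nrow(x$edges),
      " pairs, most significant first\n", sep = "")
  print(head(x$edges, 5L))
  invisible(x)
}
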