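#' Consensus edge ranks and weights over a method set, per cohort
#'
#' For each cohort, the consensus rank of a pair is the mean of its
#' tie-averaged ranks over the selected methods, and the consensus weight
#' is the mean of per-method weights after each method's |weight| has been
#' min-max scaled to [0, 1] (so mutual-information magnitudes cannot
#' dominate correlation-scale methods). The consensus sign is the majority
#' sign among the signed methods; ties and all-unsigned sets default to
#' positive.
#'
#' @param networks_by_cohort named list (cohorts) of named lists (methods)
#'   of `ppi_network` objects sharing one antibody universe.
#' @param method_set methods to aggregate (default: all methods present).
#' @return An object of class `ppi_consensus`: `cohorts` (named list of
#'   data frames `a`, `b`, `rank`, `weight` in lexicographic pair order),
#'   `antibody_ids`, `method_set`, `n_pairs`.
#' @export
build_consensus <- function(networks_by_cohort, method_set = NULL) {
  stopifnot(length(networks_by_cohort) >= 1L)
  first <- networks_by_cohort[[1L]]
  if (is.null(method_set)) method_set <- names(first)
  if (length(method_set) == 0L) stop("empty method set", call. = FALSE)
  ab <- first[[1L]]$antibody_ids
  cohorts <- lapply(networks_by_cohort, function(nets) {
    missing <- setdiff(method_set, names(nets))
    if (length(missing)) {
      stop("cohort lacks method(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    consensus_edges(nets[method_set], ab)
  })
  structure(
    list(cohorts = cohorts, antibody_ids = ab, method_set = method_set,
         n_pairs = choose(length(ab), 2L)),
    class = "ppi_consensus"
  )
}

consensus_edges <- function(nets, ab) {
  pairs <- pair_table(ab)
  m <- nrow(pairs)
  rank_mat <- matrix(NA_real_, m, length(nets))
  wgt_mat <- matrix(NA_real_, m, length(nets))
  sign_mat <- matrix(0, m, length(nets))
  for (k in seq_along(nets)) {
    net <- nets[[k]]
    if (!identical(net$antibody_ids, ab)) {
      stop("all methods must share the antibody universe", call. = FALSE)
    }
    w <- upper_values(net$weights)
    rank_mat[, k] <- rank(-abs(w), ties.method = "average")
    aw <- abs(w)
    rng <- range(aw)
    wgt_mat[, k] <- if (rng[2L] > rng[1L]) {
      (aw - rng[1L]) / (rng[2L] - rng[1L])
    } else {
      rep(0, m)
    }
    if (net$signed) sign_mat[, k] <- sign(w)
  }
  sgn <- sign(rowSums(sign_mat))
  sgn[sgn == 0] <- 1
  data.frame(
    a = pairs$a, b = pairs$b,
    rank = rowMeans(rank_mat),
    weight = sgn * rowMeans(wgt_mat),
    stringsAsFactors = FALSE
  )
}

#' Inflection point of a series by smoothed second differences
#'
#' Smooths the series with a window-3 moving average and returns the index
#' of the interior point with the largest magnitude of the discrete second
#' difference. Returns `NA` when the series is degenerate (constant or
#' linear, so every second difference vanishes).
#'
#' @param values numeric series (length >= 3).
#' @return integer index of the inflection, or `NA_integer_`.
#' @export
detect_inflection <- function(values) {
  n <- length(values)
  if (n < 3L) return(NA_integer_)
  sm <- values
  ok <- !is.na(values)
  interior <- which(ok[-c(1L, n)] & ok[-c(n - 1L, n)] & ok[-c(1L, 2L)]) + 1L
  sm[interior] <- (values[interior - 1L] + values[interior] +
                     values[interior + 1L]) / 3
  d2 <- abs(sm[interior + 1L] - 2 * sm[interior] + sm[interior - 1L])
  d2[is.na(d2)] <- 0
  if (!length(d2) || max(d2) < 1e-9) return(NA_integer_)
  interior[which.max(d2)]
}

#' Select the consensus rank threshold from PCA variance behavior
#'
#' For every candidate threshold T, collects the union over cohorts of
#' pairs with consensus rank below T, forms the union-pairs x cohorts
#' consensus-weight matrix, and records the variance percentage explained
#' jointly by the first three principal components of the cohort vectors.
#' The returned threshold sits at the inflection of that series
#' ([detect_inflection()]); a degenerate series falls back to the median
#' candidate with a warning.
#'
#' @param consensus a [build_consensus()] result with at least 2 cohorts.
#' @param candidates candidate rank thresholds (default 25 to 2000 by 25).
#' @return list with `threshold` and the diagnostic `series` data frame
#'   (`candidate`, `n_union`, `pc123_variance_pct`).
#' @export
select_rank_threshold <- function(consensus,
                                  candidates = seq(25L, 2000L, by = 25L)) {
  stopifnot(inherits(consensus, "ppi_consensus"))
  if (length(consensus$cohorts) < 2L) {
    stop("need at least 2 cohorts", call. = FALSE)
  }
  rank_mat <- vapply(consensus$cohorts, function(df) df$rank,
                     numeric(consensus$n_pairs))
  wgt_mat <- vapply(consensus$cohorts, function(df) df$weight,
                    numeric(consensus$n_pairs))
  series <- data.frame(candidate = candidates, n_union = NA_integer_,
                       pc123_variance_pct = NA_real_)
  for (i in seq_along(candidates)) {
    sig <- rank_mat < candidates[i]
    union_rows <- rowSums(sig) > 0L
    series$n_union[i] <- sum(union_rows)
    if (sum(union_rows) < 3L) next
    sub <- wgt_mat[union_rows, , drop = FALSE]
    pca <- tryCatch(prcomp(sub, center = TRUE), error = function(e) NULL)
    if (is.null(pca)) next
    tot <- sum(pca$sdev^2)
    if (tot <= 0) next
    k <- min(3L, length(pca$sdev))
    series$pc123_variance_pct[i] <- 100 * sum(pca$sdev[seq_len(k)]^2) / tot
  }
  idx <- detect_inflection(series$pc123_variance_pct)
  if (is.na(idx)) {
    warning("degenerate variance series; returning the median candidate",
            call. = FALSE)
    idx <- ceiling(length(candidates) / 2)
  }
  list(threshold = candidates[idx], series = series)
}

#' Build the discovery set of significant consensus edges
#'
#' A pair is significant in a cohort when its consensus rank is below the
#' threshold. The discovery set is the union of significant pairs over
#' cohorts; each member carries its consensus-weight vector across all
#' cohorts (weights are kept even where the pair misses significance, for
#' clustering), its recurrence (number of cohorts where it is significant)
#' and its pan-cancer mean weight.
#'
#' @param consensus a [build_consensus()] result.
#' @param threshold consensus rank threshold.
#' @return An object of class `ppi_discovery`: `pairs`, `weights`
#'   (pairs x cohorts), `significant` (logical, same shape), `recurrence`,
#'   `pan_weight`, `threshold`, `antibody_ids`.
#' @export
build_discovery_set <- function(consensus, threshold) {
  stopifnot(inherits(consensus, "ppi_consensus"))
  rank_mat <- vapply(consensus$cohorts, function(df) df$rank,
                     numeric(consensus$n_pairs))
  wgt_mat <- vapply(consensus$cohorts, function(df) df$weight,
                    numeric(consensus$n_pairs))
  sig <- rank_mat < threshold
  keep <- rowSums(sig) > 0L
  if (!any(keep)) {
    stop("no pair is significant at threshold ", threshold, call. = FALSE)
  }
  pairs <- consensus$cohorts[[1L]][keep, c("a", "b")]
  rownames(pairs) <- NULL
  weights <- wgt_mat[keep, , drop = FALSE]
  signif_mat <- sig[keep, , drop = FALSE]
  dimnames(weights) <- list(pair_key(pairs$a, pairs$b),
                            names(consensus$cohorts))
  dimnames(signif_mat) <- dimnames(weights)
  structure(
    list(pairs = pairs, weights = weights, significant = signif_mat,
         recurrence = rowSums(signif_mat),
         pan_weight = rowMeans(weights),
         threshold = threshold,
         antibody_ids = consensus$antibody_ids),
    class = "ppi_discovery"
  )
}

#' Cohort similarity from the discovery set
#'
#' Jaccard index (intersection over union of significant pair sets) for
#' every cohort pair, principal components of the cohorts-as-vectors
#' consensus-weight matrix, and Ward-linkage hierarchical clustering on
#' Euclidean distances between cohort weight vectors.
#'
#' @param discovery a [build_discovery_set()] result.
#' @return list with `jaccard`, `pca` (`scores`, `explained_variance`),
#'   `hclust` and `order` (cohort labels in dendrogram order).
#' @export
cohort_similarity <- function(discovery) {
  stopifnot(inherits(discovery, "ppi_discovery"))
  sig <- discovery$significant
  nc <- ncol(sig)
  if (nc < 2L) stop("need at least 2 cohorts", call. = FALSE)
  jac <- matrix(1, nc, nc, dimnames = list(colnames(sig), colnames(sig)))
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      inter <- sum(sig[, i] & sig[, j])
      uni <- sum(sig[, i] | sig[, j])
      jac[i, j] <- jac[j, i] <- if (uni == 0L) 0 else inter / uni
    }
  }
  cohort_vectors <- t(discovery$weights)
  pca <- prcomp(cohort_vectors, center = TRUE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  hc <- hclust(dist(cohort_vectors), method = "ward.D2")
  list(jaccard = jac,
       pca = list(scores = pca$x, explained_variance = ev),
       hclust = hc,
       order = rownames(cohort_vectors)[hc$order])
}

#' @export
print.ppi_consensus <- function(x, ...) {
  cat("Consensus over methods {", paste(x$method_set, collapse = ", "),
      "}: ", length(x$cohorts), " cohort(s), ", x$n_pairs, " pairs\n",
      sep = "")
  invisible(x)
}

#' @export
print.ppi_discovery <- function(x, ...) {
  cat("Discovery set:", nrow(x$pairs), "pairs over",
      length(unique(c(x$pairs$a, x$pairs$b))), "antibodies; threshold",
      x$threshold, "\n")
  cat("  recurrence: ", paste(range(x$recurrence), collapse = "-"),
      " cohorts; mean pan-cancer weight ",
      sprintf("%.3f", mean(x$pan_weight)), "\n", sep = "")
  invisible(x)
}
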