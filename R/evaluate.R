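#' Precision-recall curve of an edge ranking against a gold standard
#'
#' The ranking is first restricted to pairs whose both endpoints belong to
#' the gold-standard universe (pairs involving antibodies with no curated
#' interaction are not evaluable). Traversing the restricted ranking from
#' most to least significant (ties broken in lexicographic pair order),
#' point t has precision TP(t)/t and recall TP(t)/|gold pairs|.
#'
#' @param ranking an [rank_edges()] result.
#' @param gold a [gold_standard()] object.
#' @return An object of class `pr_curve`: data frame `points`
#'   (`recall`, `precision`, `tp`, `n_predicted`), plus `method`, `params`
#'   and `n_gold`.
#' @export
pr_curve <- function(ranking, gold, params = NULL) {
  stopifnot(inherits(ranking, "edge_ranking"), inherits(gold, "gold_standard"))
  if (nrow(gold$pairs) == 0L) stop("empty gold standard", call. = FALSE)
  edges <- ranking$edges
  keep <- edges$a %in% gold$universe & edges$b %in% gold$universe
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) {
    stop("no ranked pairs fall inside the gold universe", call. = FALSE)
  }
  gold_keys <- pair_key(gold$pairs$a, gold$pairs$b)
  hit <- pair_key(edges$a, edges$b) %in% gold_keys
  tp <- cumsum(hit)
  t_idx <- seq_along(tp)
  points <- data.frame(
    recall = tp / nrow(gold$pairs),
    precision = tp / t_idx,
    tp = tp,
    n_predicted = t_idx
  )
  structure(
    list(points = points, method = ranking$method, params = params,
         n_gold = nrow(gold$pairs)),
    class = "pr_curve"
  )
}

#' Area under the precision-recall curve on a limited recall window
#'
#' Trapezoidal integral of precision over recall on `[0, recall_max]`. The
#' curve is treated as piecewise linear through its points, starting from
#' recall 0 at the first point's precision, and linearly interpolated at
#' the window edge. The result is bounded above by `recall_max`.
#'
#' @param curve a [pr_curve()] result.
#' @param recall_max upper recall bound in (0, 1]; the default restricts
#'   the comparison to the 0-10% recall range where methods differ and
#'   precision is meaningfully above noise.
#' @return nonnegative scalar area.
#' @export
aupr <- function(curve, recall_max = 0.1) {
  stopifnot(inherits(curve, "pr_curve"))
  if (recall_max <= 0 || recall_max > 1) {
    stop("`recall_max` must lie in (0, 1]", call. = FALSE)
  }
  pts <- curve$points
  r <- c(0, pts$recall)
  p <- c(pts$precision[1L], pts$precision)
  if (max(r) < recall_max) {
    # curve ends before the window edge; integrate what exists
    recall_max <- max(r)
    if (recall_max == 0) return(0)
  } else {
    # precision at the window edge: the first point attaining that recall,
    # or a linear interpolation inside the enclosing segment
    idx <- which(r >= recall_max)[1L]
    p_end <- if (r[idx] == recall_max) {
      p[idx]
    } else {
      p[idx - 1L] + (p[idx] - p[idx - 1L]) *
        (recall_max - r[idx - 1L]) / (r[idx] - r[idx - 1L])
    }
    keep <- r < recall_max
    r <- c(r[keep], recall_max)
    p <- c(p[keep], p_end)
  }
  sum(diff(r) * (head(p, -1L) + p[-1L]) / 2)
}

#' Grid search for a method's optimal parameters by limited-recall AUPR
#'
#' Evaluates every grid cell exhaustively: infer the network at those
#' parameters, rank its edges, and score the limited-recall AUPR against
#' the gold standard. Ties break to the first cell in grid order. Methods
#' without user-specified parameters use the single empty cell.
#'
#' @param x cohort expression matrix.
#' @param method one of [ppi_methods()].
#' @param gold a [gold_standard()].
#' @param grid list of parameter lists; `NULL` uses
#'   [default_param_grid()].
#' @param recall_max AUPR recall window.
#' @param seed passed to [infer_network()].
#' @return list with `best_params`, `best_aupr`, `best_network`, and
#'   `table` (one row per cell with its AUPR or failure message).
#' @export
optimize_params <- function(x, method, gold, grid = NULL,
                            recall_max = 0.1, seed = 1L) {
  if (is.null(grid)) grid <- default_param_grid(method)
  if (length(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  shared <- NULL
  if (method %in% mi_family()) {
    # the MI matrix does not depend on eps/tau; estimate once per grid
    k <- grid[[1L]]$k_neighbors %||% 3L
    shared <- estimate_mi(x, k)
  }
  best <- NULL
  rows <- vector("list", length(grid))
  errors <- character(0)
  for (ci in seq_along(grid)) {
    cell <- grid[[ci]]
    if (!is.null(shared)) cell$mi <- shared
    res <- tryCatch({
      net <- infer_network(x, method, params = cell, seed = seed)
      a <- aupr(pr_curve(rank_edges(net), gold, params = cell), recall_max)
      list(aupr = a, net = net)
    }, error = function(e) conditionMessage(e))
    cell$mi <- NULL
    label <- if (length(cell)) {
      paste(names(cell), vapply(cell, function(v) paste(format(v), collapse = "/"), ""),
            sep = "=", collapse = ",")
    } else {
      "(none)"
    }
    if (is.character(res)) {
      rows[[ci]] <- data.frame(cell = label, aupr = NA_real_,
                               error = res, stringsAsFactors = FALSE)
      errors <- c(errors, paste0(label, ": ", res))
    } else {
      rows[[ci]] <- data.frame(cell = label, aupr = res$aupr,
                               error = "", stringsAsFactors = FALSE)
      if (is.null(best) || res$aupr > best$aupr) {
        best <- list(params = cell, aupr = res$aupr, net = res$net)
      }
    }
  }
  if (is.null(best)) {
    stop("all grid cells failed:\n", paste(errors, collapse = "\n"),
         call. = FALSE)
  }
  list(best_params = best$params, best_aupr = best$aupr,
       best_network = best$net, table = do.call(rbind, rows))
}

#' Default parameter grid per method
#'
#' Penalized methods get one- or two-dimensional grids spanning the under-
#' to over-regularization regimes; parameterless methods (and methods whose
#' selection is internally cross-validated) get the single empty cell.
#'
#' @param method one of [ppi_methods()].
#' @return list of parameter lists.
#' @export
default_param_grid <- function(method) {
  switch(method,
    glasso = lapply(10^seq(-2, 0, length.out = 8L), function(r) list(rho = r)),
    ridgenet = ,
    lassonet = lapply(default_penalty_grid(), function(l) list(penalty = l)),
    elasticnet = {
      cells <- expand.grid(penalty = default_penalty_grid(),
                           mixing = default_mixing_grid())
      lapply(seq_len(nrow(cells)), function(i) {
        list(penalty = cells$penalty[i], mixing = cells$mixing[i])
      })
    },
    plsnet = lapply(default_ncomp_grid(), function(k) list(ncomp = k)),
    aracne.a = lapply(c(0, 0.05, 0.1, 0.15, 0.2), function(e) list(eps = e)),
    aracne.m = lapply(c(0, 0.05, 0.1, 0.15, 0.2), function(t) list(tau = t)),
    list(list())
  )
}

#' Rank methods across cohorts by overall AUPR and overall AUPR rank
#'
#' Given a complete methods x cohorts table of limited-recall AUPRs,
#' computes per-cohort ranks (1 = best AUPR, ties averaged), the overall
#' AUPR (sum across cohorts) and the overall AUPR rank (sum of per-cohort
#' ranks; smaller is better).
#'
#' @param aupr_table numeric matrix, methods in rows, cohorts in columns.
#' @return An object of class `method_scores`: `scores` data frame (one
#'   row per method with `overall_aupr`, `overall_rank` and both
#'   orderings), `aupr` and `ranks` matrices.
#' @export
rank_methods <- function(aupr_table) {
  if (anyNA(aupr_table)) stop("AUPR table must be complete", call. = FALSE)
  ranks <- apply(aupr_table, 2L, function(col) {
    rank(-col, ties.method = "average")
  })
  overall_aupr <- rowSums(aupr_table)
  overall_rank <- rowSums(ranks)
  scores <- data.frame(
    method = rownames(aupr_table),
    overall_aupr = overall_aupr,
    overall_rank = overall_rank,
    aupr_position = rank(-overall_aupr, ties.method = "average"),
    rank_position = rank(overall_rank, ties.method = "average"),
    stringsAsFactors = FALSE
  )
  scores <- scores[order(scores$rank_position, scores$aupr_position), ]
  rownames(scores) <- NULL
  structure(list(scores = scores, aupr = aupr_table, ranks = ranks),
            class = "method_scores")
}

#' Methods ranking in the top k by both criteria
#'
#' The intersection of the top-k methods by overall AUPR and the top-k by
#' overall AUPR rank; the high-performer set used for consensus
#' aggregation.
#'
#' @param scores a [rank_methods()] result.
#' @param k cutoff (default 6).
#' @return character vector of method names.
#' @export
top_methods <- function(scores, k = 6L) {
  stopifnot(inherits(scores, "method_scores"))
  s <- scores$scores
  by_aupr <- s$method[order(s$aupr_position)][seq_len(min(k, nrow(s)))]
  by_rank <- s$method[order(s$rank_position)][seq_len(min(k, nrow(s)))]
  intersect(by_rank, by_aupr)
}

#' Similarity of methods from their stacked edge-weight vectors
#'
#' Each method is represented by the vector of its edge weights stacked
#' across cohorts (mutual-information weights used as-is, unsigned).
#' Computes the pairwise Spearman correlation matrix, principal components
#' of the centered stacked matrix (methods as observations) and a
#' complete-linkage hierarchical clustering on Euclidean distances between
#' the correlation profiles.
#'
#' @param weight_matrix methods x stacked-edges numeric matrix.
#' @return list with `correlation`, `pca` (`scores`,
#'   `explained_variance`), and `hclust`.
#' @export
method_similarity <- function(weight_matrix) {
  if (is.null(rownames(weight_matrix))) {
    rownames(weight_matrix) <- sprintf("method%02d", seq_len(nrow(weight_matrix)))
  }
  const <- apply(weight_matrix, 1L, sd) == 0
  cmat <- suppressWarnings(
    cor(t(weight_matrix), method = "spearman")
  )
  if (any(const)) {
    warning("constant weight vector(s): ",
            paste(rownames(weight_matrix)[const], collapse = ", "),
            "; their correlations set to 0", call. = FALSE)
    cmat[const, ] <- 0
    cmat[, const] <- 0
    diag(cmat) <- 1
  }
  pca <- prcomp(weight_matrix, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  hc <- hclust(dist(cmat), method = "complete")
  list(correlation = cmat,
       pca = list(scores = pca$x, explained_variance = ev),
       hclust = hc)
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("PR curve (", x$method %||% "?", "): ", nrow(x$points),
      " points, ", x$n_gold, " gold pairs\n", sep = "")
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, recall_max = NULL, ...) {
  graphics::plot(x$points$recall, x$points$precision, type = "l",
                 xlab = "recall", ylab = "precision",
                 main = x$method %||% "", ylim = c(0, 1), ...)
  if (!is.null(recall_max)) graphics::abline(v = recall_max, lty = 2)
  invisible(x)
}

#' @export
print.method_scores <- function(x, ...) {
  cat("Method ranking over", ncol(x$aupr), "cohort(s):\n")
  print(x$scores, digits = 4)
  invisible(x)
}
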