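#' Classify discovery-set edges into weight-profile groups
#'
#' Ward-linkage hierarchical clustering (Euclidean distance) of the
#' edges x cohorts consensus-weight vectors, cut at `n_groups`. Clusters
#' are labelled by their mean pan-cancer weight: the highest-mean cluster
#' is `positive_dominant`, the lowest is `negative_dominant`, and any
#' remaining clusters are `heterogeneous`. Recurrence is carried as
#' annotation, not as a clustering feature.
#'
#' @param discovery a [build_discovery_set()] result.
#' @param n_groups number of clusters (default 3).
#' @return An object of class `edge_groups`: `group` (factor per discovery
#'   pair), `cluster` (raw cluster id) and `stats` (per-group size, mean
#'   pan-cancer weight, mean recurrence).
#' @export
classify_edge_groups <- function(discovery, n_groups = 3L) {
  stopifnot(inherits(discovery, "ppi_discovery"))
  m <- nrow(discovery$pairs)
  if (n_groups > m) {
    stop("`n_groups` exceeds the discovery-set size", call. = FALSE)
  }
  cl <- if (m == 1L) {
    1L
  } else {
    cutree(hclust(dist(discovery$weights), method = "ward.D2"),
           k = n_groups)
  }
  means <- tapply(discovery$pan_weight, cl, mean)
  ord <- order(means, decreasing = TRUE)
  labels <- rep("heterogeneous", length(means))
  labels[ord[1L]] <- "positive_dominant"
  if (length(means) > 1L) labels[ord[length(ord)]] <- "negative_dominant"
  group <- factor(labels[cl],
                  levels = c("positive_dominant", "negative_dominant",
                             "heterogeneous"))
  stats <- data.frame(
    group = levels(group),
    size = as.integer(table(group)[levels(group)]),
    mean_pan_weight = vapply(levels(group), function(g) {
      if (any(group == g)) mean(discovery$pan_weight[group == g]) else NA_real_
    }, 0),
    mean_recurrence = vapply(levels(group), function(g) {
      if (any(group == g)) mean(discovery$recurrence[group == g]) else NA_real_
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(group = group, cluster = cl, stats = stats),
            class = "edge_groups")
}

#' Discovery-set graph
#'
#' @param discovery a [build_discovery_set()] result.
#' @param weighted use |pan-cancer weight| as edge weight (default
#'   unweighted).
#' @return an igraph graph whose vertices are the antibodies incident to
#'   at least one discovery pair.
#' @export
discovery_graph <- function(discovery, weighted = FALSE) {
  el <- as.matrix(discovery$pairs[, c("a", "b")])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (weighted) {
    igraph::E(g)$weight <- abs(discovery$pan_weight)
  }
  g
}

#' Five-algorithm community-detection consensus
#'
#' Runs fast-greedy modularity optimization, the simulated-annealing
#' spin-glass model, multi-level (Louvain) modularity optimization, the
#' information-theoretic random-walk description-length approach (Infomap)
#' and Walktrap on the discovery-set graph, records each partition and its
#' Newman modularity, and forms the consensus frequency matrix whose
#' (i, j) entry is the fraction of algorithms co-assigning antibodies i
#' and j to one module. The spin-glass model requires a connected graph
#' and is run per connected component with offset module ids. A failing
#' algorithm is dropped with a warning and the frequency denominator
#' adjusted.
#'
#' @param graph an igraph graph (see [discovery_graph()]).
#' @param algorithms subset of the five algorithm names.
#' @param seed integer seed covering the stochastic algorithms.
#' @return An object of class `module_consensus`: `frequency` (symmetric
#'   matrix with unit diagonal, entries in multiples of 1/n_algorithms),
#'   `memberships`, `modularity`, `n_algorithms`.
#' @export
detect_communities <- function(graph,
                               algorithms = c("fast_greedy", "spinglass",
                                              "louvain", "infomap",
                                              "walktrap"),
                               seed = 1L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  vnames <- igraph::V(graph)$name
  memberships <- list()
  modularity <- numeric(0)
  for (alg in algorithms) {
    memb <- tryCatch(
      with_seed(derive_seed(seed, alg), run_community(graph, alg)),
      error = function(e) {
        warning("community algorithm '", alg, "' failed: ",
                conditionMessage(e), "; dropped", call. = FALSE)
        NULL
      }
    )
    if (is.null(memb)) next
    memberships[[alg]] <- memb
    modularity[[alg]] <- igraph::modularity(graph, memb)
  }
  if (!length(memberships)) {
    stop("all community-detection algorithms failed", call. = FALSE)
  }
  n <- length(vnames)
  freq <- matrix(0, n, n, dimnames = list(vnames, vnames))
  for (memb in memberships) {
    freq <- freq + outer(memb, memb, `==`)
  }
  freq <- freq / length(memberships)
  diag(freq) <- 1
  structure(
    list(frequency = freq, memberships = memberships,
         modularity = modularity, n_algorithms = length(memberships)),
    class = "module_consensus"
  )
}

run_community <- function(graph, alg) {
  comm <- switch(alg,
    fast_greedy = igraph::cluster_fast_greedy(graph),
    louvain = igraph::cluster_louvain(graph),
    infomap = igraph::cluster_infomap(graph),
    walktrap = igraph::cluster_walktrap(graph),
    spinglass = return(spinglass_components(graph))
  )
  memb <- igraph::membership(comm)
  as.integer(memb[igraph::V(graph)$name])
}

# Spin-glass cannot handle disconnected graphs: run it per connected
# component and offset module ids so modules from different components
# stay distinct.
spinglass_components <- function(graph) {
  comp <- igraph::components(graph)
  memb <- integer(igraph::vcount(graph))
  offset <- 0L
  for (c_id in seq_len(comp$no)) {
    vs <- which(comp$membership == c_id)
    sub <- igraph::induced_subgraph(graph, vs)
    if (igraph::vcount(sub) == 1L) {
      memb[vs] <- offset + 1L
      offset <- offset + 1L
    } else {
      cm <- igraph::membership(igraph::cluster_spinglass(sub))
      memb[vs] <- offset + as.integer(cm)
      offset <- offset + max(as.integer(cm))
    }
  }
  memb
}

#' Cut the consensus frequency matrix into modules
#'
#' Ward-linkage hierarchical clustering (Euclidean distance) of the rows
#' of the co-assignment frequency matrix, cut at `n_modules`; module ids
#' are relabelled in decreasing size order (module 1 is the largest).
#'
#' @param consensus a [detect_communities()] result.
#' @param n_modules number of modules (default 6).
#' @return named integer vector: antibody -> module id.
#' @export
cut_consensus_modules <- function(consensus, n_modules = 6L) {
  stopifnot(inherits(consensus, "module_consensus"))
  freq <- consensus$frequency
  if (n_modules > nrow(freq)) {
    stop("`n_modules` exceeds the antibody count", call. = FALSE)
  }
  cl <- cutree(hclust(dist(freq), method = "ward.D2"), k = n_modules)
  sizes <- table(cl)
  relabel <- setNames(rank(-as.numeric(sizes), ties.method = "first"),
                      names(sizes))
  out <- as.integer(relabel[as.character(cl)])
  names(out) <- rownames(freq)
  out
}

#' Per-module network statistics
#'
#' Considers intra-module interactions only and reports, per module, the
#' five statistics of the consensus-module summary: edge counts split by
#' edge group, antibody counts split by phosphospecificity, the average
#' degree 2 * E_intra / N_antibodies, and the top intra-module hubs with
#' their per-group edge counts.
#'
#' @param assignment named antibody -> module vector
#'   ([cut_consensus_modules()]).
#' @param discovery a [build_discovery_set()] result.
#' @param groups an [classify_edge_groups()] result (optional; without it
#'   the group split is omitted).
#' @param annotation antibody annotation data frame with `antibody` and
#'   `phosphospecific` columns (optional).
#' @param n_hubs number of hubs to report per module (default 3).
#' @return An object of class `module_stats`: `table` (one row per module)
#'   and `hubs` (per module, data frame of hub antibodies with total and
#'   per-group intra-module degrees).
#' @export
module_statistics <- function(assignment, discovery, groups = NULL,
                              annotation = NULL, n_hubs = 3L) {
  pairs <- discovery$pairs
  mod_a <- assignment[pairs$a]
  mod_b <- assignment[pairs$b]
  intra <- !is.na(mod_a) & !is.na(mod_b) & mod_a == mod_b
  grp <- if (!is.null(groups)) as.character(groups$group) else
    rep(NA_character_, nrow(pairs))
  module_ids <- sort(unique(assignment))
  glevels <- c("positive_dominant", "negative_dominant", "heterogeneous")

  rows <- lapply(module_ids, function(m) {
    in_m <- intra & mod_a == m
    abs_m <- names(assignment)[assignment == m]
    n_edges <- sum(in_m)
    gcounts <- if (!is.null(groups)) {
      vapply(glevels, function(g) sum(in_m & grp == g), 0L)
    } else {
      setNames(rep(NA_integer_, 3L), glevels)
    }
    if (!is.null(annotation)) {
      ph <- annotation$phosphospecific[match(abs_m, annotation$antibody)]
      n_phospho <- sum(ph, na.rm = TRUE)
      n_total <- sum(!ph, na.rm = TRUE)
    } else {
      n_phospho <- NA_integer_
      n_total <- NA_integer_
    }
    data.frame(
      module = m,
      n_edges = n_edges,
      n_positive = gcounts[[1L]],
      n_negative = gcounts[[2L]],
      n_heterogeneous = gcounts[[3L]],
      n_antibodies = length(abs_m),
      n_nonphospho = n_total,
      n_phospho = n_phospho,
      average_degree = if (length(abs_m)) 2 * n_edges / length(abs_m) else 0,
      stringsAsFactors = FALSE
    )
  })

  hubs <- lapply(module_ids, function(m) {
    in_m <- which(intra & mod_a == m)
    abs_m <- names(assignment)[assignment == m]
    deg <- setNames(integer(length(abs_m)), abs_m)
    for (i in in_m) {
      deg[pairs$a[i]] <- deg[pairs$a[i]] + 1L
      deg[pairs$b[i]] <- deg[pairs$b[i]] + 1L
    }
    top <- names(sort(deg, decreasing = TRUE))[seq_len(min(n_hubs, length(deg)))]
    do.call(rbind, lapply(top, function(ab) {
      touching <- in_m[pairs$a[in_m] == ab | pairs$b[in_m] == ab]
      data.frame(
        antibody = ab,
        degree = deg[[ab]],
        n_positive = if (!is.null(groups)) sum(grp[touching] == glevels[1L]) else NA_integer_,
        n_negative = if (!is.null(groups)) sum(grp[touching] == glevels[2L]) else NA_integer_,
        n_heterogeneous = if (!is.null(groups)) sum(grp[touching] == glevels[3L]) else NA_integer_,
        stringsAsFactors = FALSE
      )
    }))
  })
  names(hubs) <- as.character(module_ids)
  structure(
    list(table = do.call(rbind, rows), hubs = hubs,
         n_intra = sum(intra), n_inter = sum(!intra)),
    class = "module_stats"
  )
}

#' @export
print.module_consensus <- function(x, ...) {
  cat("Community-detection consensus:", x$n_algorithms, "algorithm(s),",
      nrow(x$frequency), "antibodies\n")
  cat("  modularity:",
      paste(sprintf("%s=%.3f", names(x$modularity), x$modularity),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.module_stats <- function(x, ...) {
  cat("Module statistics (", x$n_intra, " intra-module, ", x$n_inter,
      " inter-module edges)\n", sep = "")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
print.edge_groups <- function(x, ...) {
  cat("Edge groups:\n")
  print(x$stats, digits = 3, row.names = FALSE)
  invisible(x)
}
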