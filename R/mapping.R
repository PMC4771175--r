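#' Index a gene-list hierarchy
#'
#' Builds the parent relation over gene-list ids, identifies top-level
#' lists (those with no parent) and computes each list's depth (shortest
#' distance to a root). Multiple parents are allowed (the hierarchy is a
#' DAG); a cycle is rejected naming one of its members.
#'
#' @param collection a gene-list collection
#'   ([read_gene_lists()] / [generate_genelist_hierarchy()]).
#' @return An object of class `hierarchy_index`: `parents` (named list
#'   id -> character vector of parent ids), `top_level`, `depth`.
#' @export
hierarchy_index <- function(collection) {
  ids <- names(collection$gene_lists)
  rel <- collection$relations
  parents <- setNames(vector("list", length(ids)), ids)
  if (nrow(rel)) {
    for (i in seq_len(nrow(rel))) {
      ch <- rel$child[i]
      parents[[ch]] <- unique(c(parents[[ch]], rel$parent[i]))
    }
  }
  top <- ids[vapply(parents, length, 0L) == 0L]
  # depth by BFS from roots; a node never reached lies on a cycle
  depth <- setNames(rep(NA_integer_, length(ids)), ids)
  depth[top] <- 0L
  children <- split(rel$child, rel$parent)
  frontier <- top
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt)]
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- d
    frontier <- nxt
  }
  if (anyNA(depth)) {
    bad <- names(depth)[is.na(depth)][1L]
    stop("cycle detected in hierarchy involving: ", bad, call. = FALSE)
  }
  structure(list(parents = parents, top_level = top, depth = depth),
            class = "hierarchy_index")
}

#' Trace a gene list to its top-level ancestors
#'
#' Follows parent links transitively; with multiple parents a list can
#' trace to several roots. A root traces to itself.
#'
#' @param list_id gene-list id.
#' @param hierarchy a [hierarchy_index()].
#' @return character vector of top-level ids.
#' @export
trace_top_level <- function(list_id, hierarchy) {
  stopifnot(inherits(hierarchy, "hierarchy_index"))
  if (!list_id %in% names(hierarchy$parents)) {
    stop("unknown gene-list id: ", list_id, call. = FALSE)
  }
  roots <- character(0)
  seen <- character(0)
  frontier <- list_id
  while (length(frontier)) {
    cur <- frontier[[1L]]
    frontier <- frontier[-1L]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    p <- hierarchy$parents[[cur]]
    if (length(p) == 0L) {
      roots <- union(roots, cur)
    } else {
      frontier <- c(frontier, p)
    }
  }
  sort(roots)
}

#' Map discovery-set interactions to gene lists
#'
#' Implements the average-interaction-strength mapping: for each cohort,
#' iterate its significant pairs, reduce each pair to the two gene sets of
#' its antibodies, skip pairs whose gene sets intersect (a gene-level self
#' interaction), and match gene list k when both sets hit k. A match
#' contributes |consensus weight| divided by the gene-list size; each
#' cell of the result is the mean contribution over that cohort's matched
#' interactions, and stays missing (`NA`) when nothing matched.
#'
#' @param discovery a [build_discovery_set()] result.
#' @param annotation antibody annotation with `antibody` and
#'   `gene_symbols` (semicolon-separated) columns; every discovery
#'   antibody must be annotated.
#' @param collection a gene-list collection.
#' @param use_absolute take |weight| (default, matching the
#'   strength-averaging definition); `FALSE` keeps the signed weight.
#' @return An object of class `interaction_strength`: `strength`
#'   (gene-lists x cohorts matrix, NA where unmatched), `counts` (match
#'   counts, same shape), `matches` (long data frame `cohort`, `list_id`,
#'   `a`, `b`, `contribution`), `n_skipped_self`.
#' @export
map_interactions <- function(discovery, annotation, collection,
                             use_absolute = TRUE) {
  stopifnot(inherits(discovery, "ppi_discovery"))
  ab_used <- unique(c(discovery$pairs$a, discovery$pairs$b))
  miss <- setdiff(ab_used, annotation$antibody)
  if (length(miss)) {
    stop("antibody without annotation: ", miss[1L], call. = FALSE)
  }
  gene_sets <- strsplit(annotation$gene_symbols, ";", fixed = TRUE)
  names(gene_sets) <- annotation$antibody
  lists <- collection$gene_lists
  list_ids <- names(lists)
  list_sizes <- lengths(lists)
  cohorts <- colnames(discovery$weights)
  strength <- matrix(NA_real_, length(list_ids), length(cohorts),
                     dimnames = list(list_ids, cohorts))
  counts <- matrix(0L, length(list_ids), length(cohorts),
                   dimnames = list(list_ids, cohorts))
  match_rows <- list()
  n_self <- 0L

  # which lists each gene belongs to, computed once
  gene2lists <- list()
  for (k in seq_along(lists)) {
    for (g in lists[[k]]) gene2lists[[g]] <- c(gene2lists[[g]], k)
  }

  for (ci in seq_along(cohorts)) {
    sig_idx <- which(discovery$significant[, ci])
    sums <- numeric(length(list_ids))
    ns <- integer(length(list_ids))
    for (ei in sig_idx) {
      set1 <- gene_sets[[discovery$pairs$a[ei]]]
      set2 <- gene_sets[[discovery$pairs$b[ei]]]
      if (length(intersect(set1, set2))) {
        n_self <- n_self + 1L
        next
      }
      k1 <- unique(unlist(gene2lists[set1], use.names = FALSE))
      k2 <- unique(unlist(gene2lists[set2], use.names = FALSE))
      hits <- intersect(k1, k2)
      if (!length(hits)) next
      w <- discovery$weights[ei, ci]
      if (use_absolute) w <- abs(w)
      contrib <- w / list_sizes[hits]
      sums[hits] <- sums[hits] + contrib
      ns[hits] <- ns[hits] + 1L
      match_rows[[length(match_rows) + 1L]] <- data.frame(
        cohort = cohorts[ci], list_id = list_ids[hits],
        a = discovery$pairs$a[ei], b = discovery$pairs$b[ei],
        contribution = contrib, stringsAsFactors = FALSE
      )
    }
    matched <- ns > 0L
    strength[matched, ci] <- sums[matched] / ns[matched]
    counts[, ci] <- ns
  }
  matches <- if (length(match_rows)) {
    do.call(rbind, match_rows)
  } else {
    data.frame(cohort = character(), list_id = character(),
               a = character(), b = character(),
               contribution = numeric(), stringsAsFactors = FALSE)
  }
  rownames(matches) <- NULL
  structure(
    list(strength = strength, counts = counts, matches = matches,
         n_skipped_self = n_self),
    class = "interaction_strength"
  )
}

#' Matched-interaction counts per gene list, split by edge group and module
#'
#' For each gene list, the number of matched significant interactions is
#' averaged over cohorts, broken down by edge group and by consensus
#' module. Module tracks count intra-module edges only, so they may be
#' zero when the matching interactions link two modules.
#'
#' @param ism a [map_interactions()] result.
#' @param discovery the [build_discovery_set()] used for the mapping.
#' @param groups an [classify_edge_groups()] result.
#' @param assignment named antibody -> module vector.
#' @return data frame with one row per gene list with a match: mean match
#'   count overall, per group (`group_*`) and per module (`module_*`).
#' @export
matches_by_module_group <- function(ism, discovery, groups, assignment) {
  stopifnot(inherits(ism, "interaction_strength"))
  matches <- ism$matches
  n_cohorts <- ncol(ism$strength)
  if (nrow(matches) == 0L) {
    return(data.frame(list_id = character(), mean_matches = numeric(),
                      stringsAsFactors = FALSE))
  }
  keys <- pair_key(discovery$pairs$a, discovery$pairs$b)
  midx <- match(pair_key(matches$a, matches$b), keys)
  matches$group <- as.character(groups$group)[midx]
  mod_a <- assignment[matches$a]
  mod_b <- assignment[matches$b]
  matches$module <- ifelse(!is.na(mod_a) & !is.na(mod_b) & mod_a == mod_b,
                           mod_a, NA_integer_)

  glevels <- levels(groups$group)
  module_ids <- sort(unique(assignment))
  by_list <- split(matches, matches$list_id)
  out <- lapply(names(by_list), function(lid) {
    mm <- by_list[[lid]]
    row <- data.frame(list_id = lid,
                      mean_matches = nrow(mm) / n_cohorts,
                      stringsAsFactors = FALSE)
    for (g in glevels) {
      row[[paste0("group_", g)]] <- sum(mm$group == g) / n_cohorts
    }
    for (m in module_ids) {
      row[[paste0("module_", m)]] <-
        sum(!is.na(mm$module) & mm$module == m) / n_cohorts
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.interaction_strength <- function(x, ...) {
  matched <- rowSums(!is.na(x$strength)) > 0L
  cat("Interaction-strength matrix:", nrow(x$strength), "gene lists x",
      ncol(x$strength), "cohorts;", sum(matched),
      "lists with at least one match;", x$n_skipped_self,
      "gene-level self interaction(s) skipped\n")
  invisible(x)
}
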