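#' Generate a sparse ground-truth interaction network
#'
#' Builds a random sparse undirected network over a set of synthetic
#' antibodies together with a symmetric positive-definite precision matrix
#' whose off-diagonal support equals the edge set exactly. Samples drawn
#' from the corresponding Gaussian graphical model (see [sample_cohorts()])
#' therefore exhibit direct dependence along true edges and transitive
#' (fan-in / fan-out / cascade) correlations elsewhere, the main
#' false-positive source that partial-correlation and mutual-information
#' estimators are designed to remove.
#'
#' Positive definiteness is guaranteed by diagonal dominance: each diagonal
#' entry is set to the absolute row sum of the off-diagonal entries plus one.
#' A fraction `negative_fraction` of edges receives a negative partial
#' correlation (encoded as a positive precision off-diagonal), so that
#' negative-dominant edge groups are exercised downstream.
#'
#' The antibody annotation emulates an RPPA design: a fraction of antibodies
#' is phosphospecific, a fraction maps to two paralog gene symbols, and at
#' least one phosphospecific/total antibody pair targets the same gene
#' (which downstream gene-level mapping must skip as a self-interaction).
#'
#' @param n_antibodies number of antibodies (>= 4).
#' @param density requested edge density in (0, 0.5), i.e. |E| / C(n,2).
#'   The default matches a curated benchmark subnetwork density of 9.29%.
#' @param phospho_fraction fraction of phosphospecific antibodies; the
#'   default matches the 51 / 187 split of the pan-cancer RPPA design.
#' @param multi_gene_fraction fraction of antibodies mapping to two paralog
#'   gene symbols.
#' @param negative_fraction fraction of edges with negative partial
#'   correlation.
#' @param edge_range range of absolute edge magnitudes in the precision
#'   matrix before diagonal dominance.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return An object of class `ppi_ground_truth` with elements
#'   `antibodies`, `edges` (data frame `a`, `b`), `precision`,
#'   `annotation` (data frame `antibody`, `gene_symbols`
#'   (semicolon-separated), `phosphosite`, `phosphospecific`) and `density`.
#' @export
#' @examples
#' gt <- generate_ground_truth(20, density = 0.1, seed = 1)
#' nrow(gt$edges)
generate_ground_truth <- function(n_antibodies,
                                  density = 0.0929,
                                  phospho_fraction = 51 / 187,
                                  multi_gene_fraction = 0.1,
                                  negative_fraction = 0.3,
                                  edge_range = c(0.4, 1),
                                  seed = 1L) {
  if (n_antibodies < 4L) stop("`n_antibodies` must be at least 4", call. = FALSE)
  if (density <= 0 || density >= 0.5) {
    stop("`density` must lie in (0, 0.5)", call. = FALSE)
  }
  n_pairs <- choose(n_antibodies, 2L)
  m <- round(density * n_pairs)
  ab <- sprintf("AB%03d", seq_len(n_antibodies))

  with_seed(seed, {
    pairs <- pair_table(ab)
    sel <- sort(sample.int(n_pairs, m))
    edges <- pairs[sel, , drop = FALSE]
    rownames(edges) <- NULL

    prec <- build_precision(ab, edges, negative_fraction, edge_range)

    annotation <- build_annotation(ab, phospho_fraction, multi_gene_fraction)

    structure(
      list(antibodies = ab, edges = edges, precision = prec,
           annotation = annotation, density = m / n_pairs, seed = seed),
      class = "ppi_ground_truth"
    )
  })
}

# Precision matrix with off-diagonal support exactly `edges`, made positive
# definite by diagonal dominance (|off-diagonal row sum| + 1 on the
# diagonal). Partial correlation sign is minus the precision off-diagonal
# sign, so negative edges are stored with positive entries.
build_precision <- function(ab, edges, negative_fraction, edge_range) {
  n <- length(ab)
  prec <- matrix(0, n, n, dimnames = list(ab, ab))
  m <- nrow(edges)
  if (m > 0L) {
    mag <- runif(m, edge_range[1L], edge_range[2L])
    neg <- runif(m) < negative_fraction
    # positive partial correlation <=> negative precision entry
    val <- ifelse(neg, mag, -mag)
    ii <- match(edges$a, ab)
    jj <- match(edges$b, ab)
    prec[cbind(ii, jj)] <- val
    prec[cbind(jj, ii)] <- val
  }
  diag(prec) <- rowSums(abs(prec)) + 1
  for (try in 1:5) {
    ok <- tryCatch({ chol(prec); TRUE }, error = function(e) FALSE)
    if (ok) return(prec)
    diag(prec) <- diag(prec) + 0.1 * try
  }
  stop("failed to construct a positive-definite precision matrix",
       call. = FALSE)
}

build_annotation <- function(ab, phospho_fraction, multi_gene_fraction) {
  n <- length(ab)
  n_ph <- round(phospho_fraction * n)
  phospho <- rep(FALSE, n)
  if (n_ph > 0L) phospho[sample.int(n, n_ph)] <- TRUE

  genes <- sprintf("G%03d", seq_len(n))
  gene_sets <- as.list(genes)
  n_multi <- round(multi_gene_fraction * n)
  if (n_multi > 0L) {
    multi <- sample.int(n, n_multi)
    for (i in multi) {
      gene_sets[[i]] <- c(genes[i], sprintf("G%03dB", i))
    }
  }
  # guarantee one antibody pair targeting the same gene: make the first
  # phosphospecific antibody (or antibody 2) share antibody 1's gene,
  # emulating a total / phospho antibody pair against one protein.
  twin <- if (any(phospho)) which(phospho)[1L] else 2L
  if (twin == 1L) twin <- 2L
  gene_sets[[twin]] <- gene_sets[[1L]]
  phosphosite <- ifelse(phospho, sprintf("pS%d", 100 + seq_len(n)), "")

  data.frame(
    antibody = ab,
    gene_symbols = vapply(gene_sets, paste, "", collapse = ";"),
    phosphosite = phosphosite,
    phosphospecific = phospho,
    stringsAsFactors = FALSE
  )
}

#' Sample expression cohorts from a ground-truth model
#'
#' Draws each cohort i.i.d. from the zero-mean multivariate normal whose
#' covariance is the inverse of the ground-truth precision matrix, then adds
#' independent Gaussian measurement noise. With `heterogeneity > 0`, each
#' cohort rescales a random subset of edge magnitudes before inverting
#' (rebuilding diagonal dominance), so cohorts share the support but differ
#' in edge strength, emulating tumor-type heterogeneity.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param cohort_sizes named integer vector of per-cohort sample counts
#'   (each >= 3).
#' @param noise_sd standard deviation of additive measurement noise.
#' @param heterogeneity fraction of edges whose magnitude is rescaled per
#'   cohort (uniformly in 0.25-1.75); 0 gives identical generating models.
#' @param seed integer seed.
#' @return An object of class `ppi_study`: `ground_truth`, `cohorts`
#'   (named list of samples x antibodies matrices) and `seed`.
#' @export
sample_cohorts <- function(gt, cohort_sizes, noise_sd = 0,
                           heterogeneity = 0, seed = 1L) {
  stopifnot(inherits(gt, "ppi_ground_truth"))
  if (length(cohort_sizes) == 0L) {
    stop("`cohort_sizes` must be nonempty", call. = FALSE)
  }
  if (any(cohort_sizes < 3L)) {
    stop("every cohort size must be at least 3", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (is.null(names(cohort_sizes))) {
    names(cohort_sizes) <- sprintf("COHORT%02d", seq_along(cohort_sizes))
  }
  ab <- gt$antibodies
  with_seed(seed, {
    cohorts <- vector("list", length(cohort_sizes))
    names(cohorts) <- names(cohort_sizes)
    for (ci in seq_along(cohort_sizes)) {
      prec <- gt$precision
      if (heterogeneity > 0 && nrow(gt$edges) > 0L) {
        m <- nrow(gt$edges)
        n_scale <- round(heterogeneity * m)
        if (n_scale > 0L) {
          sel <- sample.int(m, n_scale)
          fac <- runif(n_scale, 0.25, 1.75)
          ii <- match(gt$edges$a[sel], ab)
          jj <- match(gt$edges$b[sel], ab)
          prec[cbind(ii, jj)] <- prec[cbind(ii, jj)] * fac
          prec[cbind(jj, ii)] <- prec[cbind(ii, jj)]
          diag(prec) <- 0
          diag(prec) <- rowSums(abs(prec)) + 1
        }
      }
      sigma <- tryCatch(chol2inv(chol(prec)), error = function(e) {
        stop("precision matrix is singular or not positive definite",
             call. = FALSE)
      })
      n <- cohort_sizes[[ci]]
      x <- MASS::mvrnorm(n, mu = rep(0, length(ab)), Sigma = sigma)
      if (noise_sd > 0) {
        x <- x + matrix(rnorm(n * length(ab), sd = noise_sd), n)
      }
      dimnames(x) <- list(
        sprintf("%s_S%04d", names(cohort_sizes)[ci], seq_len(n)), ab
      )
      cohorts[[ci]] <- x
    }
    structure(list(ground_truth = gt, cohorts = cohorts, seed = seed),
              class = "ppi_study")
  })
}

#' Per-cohort sample counts of the emulated pan-cancer RPPA study
#'
#' Named vector of the 11 tumor-type cohort sizes (127 to 747 samples,
#' 3,467 in total) used as the reference study design by the synthetic
#' generator's documentation and the reproduction script.
#'
#' @return named integer vector of 11 cohort sizes.
#' @export
pancan11_cohort_sizes <- function() {
  c(BLCA = 127L, BRCA = 747L, COAD = 334L, GBM = 215L, HNSC = 212L,
    KIRC = 454L, LUAD = 237L, LUSC = 195L, OV = 412L, READ = 130L,
    UCEC = 404L)
}

#' Generate a rooted gene-list hierarchy
#'
#' Produces a forest of gene lists: `n_top_level` root lists drawn from the
#' gene universe, and children whose gene sets are random nonempty subsets
#' of their parent's set, so every child is contained in its parent. This
#' emulates a curated pathway hierarchy in which the parent relation means
#' superset, with identifiers carrying a species tag (`SYN-HSA-`).
#'
#' @param genes character vector of gene symbols (nonempty).
#' @param n_lists total number of gene lists.
#' @param n_top_level number of root (top-level) lists; at most `n_lists`.
#' @param seed integer seed.
#' @return list with `gene_lists` (named list of character vectors),
#'   `descriptions` (named character) and `relations`
#'   (data frame `parent`, `child`).
#' @export
generate_genelist_hierarchy <- function(genes, n_lists, n_top_level,
                                        seed = 1L) {
  if (length(genes) == 0L) stop("`genes` must be nonempty", call. = FALSE)
  if (n_top_level > n_lists) {
    stop("`n_top_level` must not exceed `n_lists`", call. = FALSE)
  }
  if (n_top_level < 1L) stop("need at least one top-level list", call. = FALSE)
  ids <- sprintf("SYN-HSA-%06d", seq_len(n_lists))
  with_seed(seed, {
    lists <- vector("list", n_lists)
    names(lists) <- ids
    parent <- character(0)
    child <- character(0)
    for (i in seq_len(n_lists)) {
      if (i <= n_top_level) {
        k <- max(1L, round(runif(1, 0.3, 0.7) * length(genes)))
        lists[[i]] <- sort(sample(genes, k))
      } else {
        p <- sample.int(i - 1L, 1L)
        pg <- lists[[p]]
        k <- max(1L, ceiling(runif(1, 0.3, 0.8) * length(pg)))
        lists[[i]] <- sort(sample(pg, k))
        parent <- c(parent, ids[p])
        child <- c(child, ids[i])
      }
    }
    list(
      gene_lists = lists,
      descriptions = setNames(sprintf("synthetic gene list %d", seq_len(n_lists)), ids),
      relations = data.frame(parent = parent, child = child,
                             stringsAsFactors = FALSE)
    )
  })
}

#' @export
print.ppi_ground_truth <- function(x, ...) {
  cat("Ground-truth network:", length(x$antibodies), "antibodies,",
      nrow(x$edges), "edges (density",
      sprintf("%.2f%%", 100 * x$density), ")\n")
  invisible(x)
}

#' @export
print.ppi_study <- function(x, ...) {
  sizes <- vapply(x$cohorts, nrow, 0L)
  cat("Synthetic study:", length(x$cohorts), "cohorts,",
      sum(sizes), "samples,", length(x$ground_truth$antibodies),
      "antibodies\n")
  cat("  cohort sizes:", paste(sprintf("%s=%d", names(sizes), sizes),
                               collapse = ", "), "\n")
  invisible(x)
}
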