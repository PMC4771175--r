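#' Construct an expression dataset
#'
#' Container for a samples x antibodies real matrix with per-sample cohort
#' labels and optional antibody annotation.
#'
#' @param matrix numeric samples x antibodies matrix with dimnames.
#' @param cohort_labels character vector, one label per sample.
#' @param annotation optional data frame with columns `antibody`,
#'   `gene_symbols`, `phosphosite`, `phosphospecific`.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, cohort_labels, annotation = NULL) {
  if (anyDuplicated(colnames(matrix))) {
    dup <- colnames(matrix)[duplicated(colnames(matrix))][1L]
    stop("duplicated antibody id: ", dup, call. = FALSE)
  }
  if (length(cohort_labels) != nrow(matrix)) {
    stop("`cohort_labels` must have one entry per sample", call. = FALSE)
  }
  if (any(!is.finite(matrix))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  structure(
    list(matrix = matrix, sample_ids = rownames(matrix),
         cohort_labels = as.character(cohort_labels),
         antibody_ids = colnames(matrix), annotation = annotation),
    class = "expression_dataset"
  )
}

#' Stack a synthetic study into an expression dataset
#'
#' @param study a [sample_cohorts()] result.
#' @return an [expression_dataset()] whose cohort labels are the cohort
#'   names of the study.
#' @export
as_expression_dataset <- function(study) {
  stopifnot(inherits(study, "ppi_study"))
  mat <- do.call(rbind, study$cohorts)
  labels <- rep(names(study$cohorts), vapply(study$cohorts, nrow, 0L))
  expression_dataset(mat, labels, study$ground_truth$annotation)
}

#' Extract one cohort's matrix from an expression dataset
#'
#' @param ds an `expression_dataset`.
#' @param cohort cohort label.
#' @return numeric matrix of that cohort's samples.
#' @export
cohort_matrix <- function(ds, cohort) {
  stopifnot(inherits(ds, "expression_dataset"))
  keep <- ds$cohort_labels == cohort
  if (!any(keep)) stop("unknown cohort: ", cohort, call. = FALSE)
  ds$matrix[keep, , drop = FALSE]
}

#' Read a wide expression TSV
#'
#' Expects one sample per row, a sample-id column, a cohort-label column and
#' one numeric column per antibody. Any wide tab-separated layout with those
#' columns is accepted.
#'
#' @param path file path.
#' @param sample_column,cohort_column column names for sample ids and
#'   cohort labels.
#' @param missing_policy how to resolve missing values: impute each
#'   antibody's column median (default), drop samples with missing entries,
#'   or drop antibodies with missing entries.
#' @return an [expression_dataset()].
#' @export
read_expression_tsv <- function(path,
                                sample_column = "sample_id",
                                cohort_column = "cohort",
                                missing_policy = c("impute_median",
                                                   "drop_sample",
                                                   "drop_antibody")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  header <- names(raw)
  ab_cols <- header[!header %in% c(sample_column, cohort_column)]
  if (anyDuplicated(ab_cols)) {
    dup <- ab_cols[duplicated(ab_cols)][1L]
    stop("duplicated antibody column: ", dup, call. = FALSE)
  }
  if (!sample_column %in% header) {
    stop("missing sample column: ", sample_column, call. = FALSE)
  }
  if (!cohort_column %in% header) {
    stop("missing cohort column: ", cohort_column, call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow(raw), length(ab_cols),
                dimnames = list(raw[[sample_column]], ab_cols))
  for (j in seq_along(ab_cols)) {
    col <- raw[[ab_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & col != "NA" & col != "" & is.na(num))
    if (length(bad) && missing_policy != "impute_median") {
      stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                   ab_cols[j], bad[1L], col[bad[1L]]), call. = FALSE)
    }
    mat[, j] <- num
  }
  if (anyNA(mat)) {
    if (missing_policy == "impute_median") {
      for (j in seq_len(ncol(mat))) {
        nas <- is.na(mat[, j])
        if (any(nas)) mat[nas, j] <- median(mat[, j], na.rm = TRUE)
      }
    } else if (missing_policy == "drop_sample") {
      keep <- rowSums(is.na(mat)) == 0L
      mat <- mat[keep, , drop = FALSE]
      raw <- raw[keep, , drop = FALSE]
    } else {
      mat <- mat[, colSums(is.na(mat)) == 0L, drop = FALSE]
    }
  }
  expression_dataset(mat, raw[[cohort_column]])
}

#' Write an expression dataset as a wide TSV
#'
#' @param ds an `expression_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(sample_id = ds$sample_ids, cohort = ds$cohort_labels,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(ds$antibody_ids)) {
    df[[ds$antibody_ids[j]]] <- ds$matrix[, j]
  }
  write_tsv_file(df, path)
}

#' Read / write antibody annotation tables
#'
#' The annotation maps each antibody to one or more gene symbols
#' (semicolon-separated), an optional phosphosite, and a phosphospecific
#' flag.
#'
#' @param path file path.
#' @return data frame with columns `antibody`, `gene_symbols`,
#'   `phosphosite`, `phosphospecific`.
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("antibody", "gene_symbols", "phosphosite", "phosphospecific")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df$phosphospecific <- df$phosphospecific %in% c("TRUE", "true", "1")
  df[need]
}

#' @rdname read_annotation_tsv
#' @param annotation annotation data frame.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write_tsv_file(annotation, path)
}

#' Construct a gold-standard network
#'
#' @param pairs data frame with columns `a`, `b` of antibody ids.
#' @param universe optional antibody universe; defaults to all antibodies
#'   appearing in at least one pair.
#' @return object of class `gold_standard` with canonical (sorted,
#'   deduplicated, self-free) pairs, `universe` and `density`.
#' @export
gold_standard <- function(pairs, universe = NULL) {
  a <- pmin(pairs$a, pairs$b)
  b <- pmax(pairs$a, pairs$b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  pairs <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) stop("gold standard has no valid pairs", call. = FALSE)
  if (is.null(universe)) universe <- sort(unique(c(pairs$a, pairs$b)))
  n_pairs <- choose(length(universe), 2L)
  structure(
    list(pairs = pairs, universe = universe,
         density = nrow(pairs) / n_pairs),
    class = "gold_standard"
  )
}

#' Read a gold-standard edge list
#'
#' Accepts two-column (`A	B`) or three-column SIF-like (`A	relation	B`)
#' tab-separated files. Directed input is collapsed to undirected pairs;
#' duplicates and self edges are removed. The evaluation universe is the
#' set of antibodies appearing in at least one retained pair.
#'
#' @param path file path.
#' @param directed_input whether the file may contain both directions of an
#'   edge (they collapse to one undirected pair either way).
#' @return a [gold_standard()] object.
#' @export
read_gold_standard <- function(path, directed_input = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty gold-standard file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(!ncol %in% c(2L, 3L))) {
    stop("gold-standard lines must have 2 or 3 tab-separated fields",
         call. = FALSE)
  }
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, function(p) p[[length(p)]], "")
  gold_standard(data.frame(a = a, b = b, stringsAsFactors = FALSE))
}

#' @rdname read_gold_standard
#' @param gold a `gold_standard` object.
#' @export
write_gold_standard <- function(gold, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(gold$pairs$a, gold$pairs$b, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a gene-list collection (GMT) with an optional hierarchy relation
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`. The relation
#' file has two columns, parent id then child id, the parent being one
#' level above (a superset of) the child. Duplicate list names keep the
#' first occurrence; lists failing `id_filter` are dropped together with
#' relations touching them; relations referencing unknown ids are dropped
#' with a warning.
#'
#' @param gmt_path GMT file path.
#' @param relation_path optional two-column parent/child TSV; `NULL` means
#'   all lists are roots.
#' @param id_filter optional predicate on list ids (e.g. a species pattern
#'   match); lists for which it returns `FALSE` are removed.
#' @return list with `gene_lists`, `descriptions` and `relations`, the same
#'   shape as [generate_genelist_hierarchy()].
#' @export
read_gene_lists <- function(gmt_path, relation_path = NULL,
                            id_filter = NULL) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  keep <- !duplicated(ids)
  parts <- parts[keep]; ids <- ids[keep]
  if (!is.null(id_filter)) {
    keep <- vapply(ids, id_filter, TRUE)
    parts <- parts[keep]; ids <- ids[keep]
  }
  if (length(ids) == 0L) stop("no gene lists retained", call. = FALSE)
  gene_lists <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(gene_lists) <- ids
  descriptions <- setNames(vapply(parts, `[`, "", 2L), ids)

  relations <- data.frame(parent = character(), child = character(),
                          stringsAsFactors = FALSE)
  if (!is.null(relation_path)) {
    rl <- readLines(relation_path)
    rl <- rl[nzchar(trimws(rl))]
    if (length(rl)) {
      rp <- strsplit(rl, "\t", fixed = TRUE)
      relations <- data.frame(
        parent = vapply(rp, `[`, "", 1L),
        child = vapply(rp, `[`, "", 2L),
        stringsAsFactors = FALSE
      )
      known <- relations$parent %in% ids & relations$child %in% ids
      if (any(!known)) {
        warning(sum(!known), " relation(s) reference unknown gene-list ids; dropped",
                call. = FALSE)
        relations <- relations[known, , drop = FALSE]
      }
    }
  }
  list(gene_lists = gene_lists, descriptions = descriptions,
       relations = relations)
}

#' @rdname read_gene_lists
#' @param collection a gene-list collection.
#' @param path output GMT path.
#' @export
write_gene_lists <- function(collection, path) {
  ids <- names(collection$gene_lists)
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], collection$descriptions[[ids[i]]] %||% "",
            collection$gene_lists[[i]]), collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname read_gene_lists
#' @export
write_relations <- function(collection, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  rel <- collection$relations
  if (nrow(rel)) {
    writeLines(paste(rel$parent, rel$child, sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Write a weighted network with its edge ranking
#'
#' Serializes all pairs as `antibody1, antibody2, weight, rank` (tab
#' separated, 10 significant digits), most significant first.
#'
#' @param ranking an [rank_edges()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(ranking, path) {
  stopifnot(inherits(ranking, "edge_ranking"))
  df <- ranking$edges[, c("a", "b", "weight", "rank")]
  names(df) <- c("antibody1", "antibody2", "weight", "rank")
  write_tsv_file(df, path)
}

#' Read a network TSV written by [write_network_tsv()]
#'
#' @param path file path.
#' @return an `edge_ranking` object.
#' @export
read_network_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  edges <- data.frame(a = df$antibody1, b = df$antibody2,
                      weight = df$weight, rank = df$rank,
                      stringsAsFactors = FALSE)
  antibodies <- sort(unique(c(edges$a, edges$b)))
  structure(list(edges = edges, antibody_ids = antibodies,
                 method = NA_character_),
            class = "edge_ranking")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset:", nrow(x$matrix), "samples x",
      ncol(x$matrix), "antibodies;",
      length(unique(x$cohort_labels)), "cohort(s)\n")
  invisible(x)
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("Gold standard:", nrow(x$pairs), "pairs over",
      length(x$universe), "antibodies (density",
      sprintf("%.2f%%", 100 * x$density), ")\n")
  invisible(x)
}
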