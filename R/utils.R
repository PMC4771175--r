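#' @useDynLib ppinet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cov median prcomp hclust cutree dist rnorm runif
#'   sd setNames
#' @importFrom utils read.delim head combn packageVersion
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
# All stochastic operations in the package funnel through this so that
# every generator and pipeline stage is a pure function of its seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stage label, so independent
# pipeline stages use decorrelated but reproducible streams. Kept below
# .Machine$integer.max by construction.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# All C(n,2) unordered pairs of `ids` in lexicographic (i < j by position)
# order. The sorted pair of antibody identifiers is the canonical edge key
# shared by every module.
pair_table <- function(ids) {
  n <- length(ids)
  if (n < 2L) {
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- combn(n, 2L)
  data.frame(a = ids[idx[1L, ]], b = ids[idx[2L, ]], stringsAsFactors = FALSE)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Upper-triangle values of a symmetric matrix in pair_table() order
# (lexicographic by row then column, i.e. combn order, not the column-major
# order of upper.tri()).
upper_values <- function(m) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- m[upper.tri(m)]
  vals[order(ut[, 1L], ut[, 2L])]
}

assert_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  invisible(m)
}

# Deterministic text serialization used by every writer: fixed column
# order, LF endings, 10 significant digits for real values.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

write_tsv_file <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) fmt_num(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

# Matrix with row and column headers; first header cell names the rows.
write_matrix_tsv <- function(m, path, row_label = "id") {
  df <- data.frame(rownames(m), stringsAsFactors = FALSE)
  names(df) <- row_label
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  write_tsv_file(df, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
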