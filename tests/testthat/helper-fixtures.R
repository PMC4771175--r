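# Fixtures are built in code; no binary data.

# Chain ground truth A1 - A2 - ... - Ap with constant partial-correlation
# strength, wrapped as a ppi_ground_truth so the samplers accept it.
make_chain_gt <- function(p, w = 0.6) {
  ab <- sprintf("AB%03d", seq_len(p))
  prec <- diag(0, p)
  for (i in seq_len(p - 1L)) {
    prec[i, i + 1L] <- -w
    prec[i + 1L, i] <- -w
  }
  # slim dominance margin keeps the chain's marginal correlations strong
  diag(prec) <- rowSums(abs(prec)) + 0.2
  dimnames(prec) <- list(ab, ab)
  edges <- data.frame(a = ab[-p], b = ab[-1L], stringsAsFactors = FALSE)
  annotation <- data.frame(
    antibody = ab,
    gene_symbols = sprintf("G%03d", seq_len(p)),
    phosphosite = "",
    phosphospecific = FALSE,
    stringsAsFactors = FALSE
  )
  structure(
    list(antibodies = ab, edges = edges, precision = prec,
         annotation = annotation, density = nrow(edges) / choose(p, 2L),
         seed = NA_integer_),
    class = "ppi_ground_truth"
  )
}

# Wrap a symmetric weight matrix as a ppi_network.
make_net <- function(w, method = "pearsoncor", signed = TRUE) {
  diag(w) <- 0
  if (is.null(rownames(w))) {
    dimnames(w) <- list(sprintf("AB%03d", seq_len(ncol(w))),
                        sprintf("AB%03d", seq_len(ncol(w))))
  }
  structure(
    list(weights = w, antibody_ids = rownames(w), method = method,
         params = list(), signed = signed),
    class = "ppi_network"
  )
}

# Network over antibodies `ab` whose |weights| realize a given significance
# order of named pairs ("A|B" keys most significant first); unspecified
# pairs get strictly smaller weights.
make_ranked_net <- function(ab, ordered_pairs, method = "pearsoncor") {
  n <- length(ab)
  w <- matrix(0, n, n, dimnames = list(ab, ab))
  m <- choose(n, 2L)
  val <- 0.9
  for (pp in ordered_pairs) {
    w[pp[1L], pp[2L]] <- val
    w[pp[2L], pp[1L]] <- val
    val <- val - 0.5 / m
  }
  all_pairs <- ppinet:::pair_table(ab)
  for (i in seq_len(nrow(all_pairs))) {
    if (w[all_pairs$a[i], all_pairs$b[i]] == 0) {
      w[all_pairs$a[i], all_pairs$b[i]] <- val
      w[all_pairs$b[i], all_pairs$a[i]] <- val
      val <- val - 0.5 / m
    }
  }
  make_net(w, method)
}

# Directly assemble a ppi_discovery object from its fields.
make_discovery <- function(pairs, weights, significant = NULL,
                           threshold = 10) {
  if (is.null(significant)) {
    significant <- matrix(TRUE, nrow(weights), ncol(weights))
  }
  if (is.null(colnames(weights))) {
    colnames(weights) <- sprintf("C%02d", seq_len(ncol(weights)))
  }
  rownames(weights) <- ppinet:::pair_key(pairs$a, pairs$b)
  dimnames(significant) <- dimnames(weights)
  structure(
    list(pairs = pairs, weights = weights, significant = significant,
         recurrence = rowSums(significant), pan_weight = rowMeans(weights),
         threshold = threshold,
         antibody_ids = sort(unique(c(pairs$a, pairs$b)))),
    class = "ppi_discovery"
  )
}

pkey <- function(a, b) ppinet:::pair_key(a, b)

# Top-|E| overlap between a ranking and a set of true edges.
edge_overlap <- function(ranking, edges) {
  k <- nrow(edges)
  top <- ranking$edges[seq_len(k), ]
  mean(pkey(top$a, top$b) %in% pkey(edges$a, edges$b))
}
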