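planted_discovery <- function(n_per = 30L, n_cohorts = 6L, seed = 50L) {
  set.seed(seed)
  ab <- sprintf("AB%03d", 1:40)
  all_pairs <- ppinet:::pair_table(ab)
  sel <- sample.int(nrow(all_pairs), 3L * n_per)
  pairs <- all_pairs[sel, ]
  rownames(pairs) <- NULL
  arch <- rep(c("positive_dominant", "negative_dominant", "heterogeneous"),
              each = n_per)
  w <- matrix(0, nrow(pairs), n_cohorts)
  for (i in seq_len(nrow(pairs))) {
    w[i, ] <- switch(arch[i],
      positive_dominant = 0.3 + rnorm(n_cohorts, sd = 0.03),
      negative_dominant = -0.15 + rnorm(n_cohorts, sd = 0.03),
      heterogeneous = sample(c(-0.1, 0.12), n_cohorts, replace = TRUE) +
        rnorm(n_cohorts, sd = 0.05)
    )
  }
  list(discovery = make_discovery(pairs, w), archetype = arch)
}

test_that("edge-group clustering recovers planted weight archetypes", {
  pd <- planted_discovery()
  groups <- classify_edge_groups(pd$discovery, n_groups = 3)
  expect_gte(mean(as.character(groups$group) == pd$archetype), 0.9)
  # partition identity
  expect_equal(sum(groups$stats$size), nrow(pd$discovery$pairs))
  # stats recomputable from members
  for (g in levels(groups$group)) {
    members <- groups$group == g
    if (!any(members)) next
    expect_equal(groups$stats$mean_pan_weight[groups$stats$group == g],
                 mean(pd$discovery$pan_weight[members]))
  }
})

test_that("single-edge discovery forms one group with its own mean", {
  disc <- make_discovery(data.frame(a = "A", b = "B",
                                    stringsAsFactors = FALSE),
                         matrix(c(0.4, 0.2), 1, 2))
  groups <- classify_edge_groups(disc, n_groups = 1)
  expect_equal(length(groups$group), 1L)
  expect_equal(groups$stats$mean_pan_weight[!is.na(groups$stats$mean_pan_weight)],
               0.3)
  expect_error(classify_edge_groups(disc, n_groups = 2), "exceeds")
})

test_that("two disconnected cliques are separated by every algorithm", {
  ab <- sprintf("AB%03d", 1:8)
  pairs <- rbind(
    expand.grid(a = ab[1:4], b = ab[1:4], stringsAsFactors = FALSE),
    expand.grid(a = ab[5:8], b = ab[5:8], stringsAsFactors = FALSE)
  )
  pairs <- pairs[pairs$a < pairs$b, ]
  disc <- make_discovery(pairs, matrix(0.3, nrow(pairs), 2))
  g <- discovery_graph(disc)
  mc <- detect_communities(g, seed = 3)
  expect_equal(mc$n_algorithms, 5L)
  f <- mc$frequency
  expect_equal(f, t(f))
  expect_true(all(f[ab[1:4], ab[1:4]] == 1))
  expect_true(all(f[ab[5:8], ab[5:8]] == 1))
  expect_true(all(f[ab[1:4], ab[5:8]] == 0))
  # identical partitions make the matrix binary; entries live on the
  # declared 6-value lattice either way
  expect_true(all(f %in% c(0, 0.2, 0.4, 0.6, 0.8, 1)))
  # exact block recovery when cutting at 2 modules
  assignment <- cut_consensus_modules(mc, n_modules = 2)
  expect_length(unique(assignment[ab[1:4]]), 1L)
  expect_length(unique(assignment[ab[5:8]]), 1L)
  expect_false(assignment[[ab[1]]] == assignment[[ab[5]]])
})

test_that("recorded modularity equals the closed-form Newman score", {
  # 6-node graph: two triangles joined by one bridge
  pairs <- data.frame(
    a = c("A", "A", "B", "D", "D", "E", "C"),
    b = c("B", "C", "C", "E", "F", "F", "D"),
    stringsAsFactors = FALSE
  )
  disc <- make_discovery(pairs, matrix(0.2, 7, 1))
  g <- discovery_graph(disc)
  mc <- detect_communities(g, algorithms = c("fast_greedy", "louvain"),
                           seed = 1)
  # independent oracle: Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta_ij
  adj <- matrix(0, 6, 6, dimnames = list(LETTERS[1:6], LETTERS[1:6]))
  for (i in seq_len(nrow(pairs))) {
    adj[pairs$a[i], pairs$b[i]] <- 1
    adj[pairs$b[i], pairs$a[i]] <- 1
  }
  memb <- c(A = 1, B = 1, C = 1, D = 2, E = 2, F = 2)
  m2 <- sum(adj)  # 2m
  k <- rowSums(adj)
  q <- 0
  for (i in 1:6) for (j in 1:6) {
    if (memb[i] == memb[j]) q <- q + adj[i, j] - k[i] * k[j] / m2
  }
  q <- unname(q / m2)
  got <- igraph::modularity(g, memb[igraph::V(g)$name])
  expect_equal(got, q)
  # the planted 2-clique split is what the algorithms find here
  expect_equal(unname(mc$modularity[["fast_greedy"]]), q)
})

test_that("module cutting survives noisy planted blocks", {
  set.seed(60)
  n <- 40
  ab <- sprintf("AB%03d", 1:n)
  block <- rep(1:4, each = 10)
  f <- outer(block, block, `==`) * 1
  flip <- matrix(runif(n * n) < 0.1, n)
  flip[lower.tri(flip)] <- t(flip)[lower.tri(flip)]
  f[flip] <- 1 - f[flip]
  f <- (f + t(f)) / 2
  diag(f) <- 1
  dimnames(f) <- list(ab, ab)
  mc <- structure(list(frequency = f, memberships = list(),
                       modularity = numeric(0), n_algorithms = 5L),
                  class = "module_consensus")
  assignment <- cut_consensus_modules(mc, n_modules = 4)
  # sizes sum to the antibody count
  expect_equal(length(assignment), n)
  # planted recovery: best label matching per block
  acc <- mean(vapply(1:4, function(b) {
    tab <- table(assignment[block == b])
    max(tab)
  }, 0)) / 10
  expect_gte(acc, 0.9)
  expect_error(cut_consensus_modules(mc, n_modules = 41), "exceeds")
})

test_that("module statistics reproduce the degree identities", {
  # module of 50 antibodies with 193 intra-module edges: average degree
  # 2 * 193 / 50 = 7.72; module of 34 with 157 edges: 9.24
  build_module_case <- function(n_ab, n_edges, offset = 0L) {
    ab <- sprintf("M%dAB%03d", offset, seq_len(n_ab))
    pairs <- ppinet:::pair_table(ab)[seq_len(n_edges), ]
    list(ab = ab, pairs = pairs)
  }
  m1 <- build_module_case(50, 193, 1)
  m2 <- build_module_case(34, 157, 2)
  pairs <- rbind(m1$pairs, m2$pairs)
  rownames(pairs) <- NULL
  disc <- make_discovery(pairs, matrix(0.2, nrow(pairs), 1))
  assignment <- setNames(rep(c(1L, 2L), c(50, 34)), c(m1$ab, m2$ab))
  stats <- module_statistics(assignment, disc)
  expect_equal(stats$table$average_degree[1], 7.72)
  expect_equal(stats$table$average_degree[2], 2 * 157 / 34)
  expect_equal(round(stats$table$average_degree[2], 2), 9.24)
  expect_equal(stats$table$n_edges, c(193L, 157L))
  # intra/inter conservation
  expect_equal(stats$n_intra + stats$n_inter, nrow(pairs))

  # an empty module yields a zero row
  assignment2 <- c(assignment, EMPTY1 = 3L)
  stats2 <- module_statistics(assignment2, disc)
  expect_equal(stats2$table$n_edges[3], 0L)
  expect_equal(stats2$table$average_degree[3], 0)
})

test_that("module statistics split edges by group and report hubs", {
  ab <- c("HUB", "X1", "X2", "X3", "Y1")
  pairs <- data.frame(a = c("HUB", "HUB", "HUB", "X1"),
                      b = c("X1", "X2", "X3", "X2"),
                      stringsAsFactors = FALSE)
  disc <- make_discovery(pairs, matrix(c(0.5, -0.4, 0.1, 0.2), 4, 1))
  groups <- structure(list(
    group = factor(c("positive_dominant", "negative_dominant",
                     "heterogeneous", "heterogeneous"),
                   levels = c("positive_dominant", "negative_dominant",
                              "heterogeneous"))),
    class = "edge_groups")
  annotation <- data.frame(antibody = ab,
                           gene_symbols = paste0("G", 1:5),
                           phosphosite = "",
                           phosphospecific = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                           stringsAsFactors = FALSE)
  assignment <- setNames(c(1L, 1L, 1L, 1L, 2L), ab)
  stats <- module_statistics(assignment, disc, groups, annotation)
  row1 <- stats$table[1, ]
  expect_equal(row1$n_positive + row1$n_negative + row1$n_heterogeneous,
               row1$n_edges)
  expect_equal(row1$n_phospho, 1L)
  expect_equal(row1$n_nonphospho, 3L)
  hub <- stats$hubs[["1"]][1, ]
  expect_equal(hub$antibody, "HUB")
  expect_equal(hub$degree, 3L)
  expect_equal(hub$n_positive, 1L)
  expect_equal(hub$n_negative, 1L)
  expect_equal(hub$n_heterogeneous, 1L)
})
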