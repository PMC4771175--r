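test_that("single-method consensus reproduces that method's ranks", {
  set.seed(1)
  w <- matrix(rnorm(25), 5)
  net <- make_net((w + t(w)) / 2)
  cons <- build_consensus(list(C1 = list(pearsoncor = net)),
                          method_set = "pearsoncor")
  rk <- rank_edges(net)
  key <- pkey(cons$cohorts$C1$a, cons$cohorts$C1$b)
  expect_equal(cons$cohorts$C1$rank,
               rk$edges$rank[match(key, pkey(rk$edges$a, rk$edges$b))])
})

test_that("reversed rankings average to the middle rank", {
  ab <- c("A", "B", "C")
  n1 <- make_ranked_net(ab, list(c("A", "B"), c("A", "C"), c("B", "C")))
  n2 <- make_ranked_net(ab, list(c("B", "C"), c("A", "C"), c("A", "B")))
  cons <- build_consensus(list(C1 = list(m1 = n1, m2 = n2)))
  # mean of (1,3), (2,2), (3,1) is 2 everywhere
  expect_equal(cons$cohorts$C1$rank, rep(2, 3))
  # rank mass conserved without per-method ties
  expect_equal(sum(cons$cohorts$C1$rank), 3 * 4 / 2)
})

test_that("consensus sign follows the majority of signed methods", {
  ab <- c("A", "B", "C")
  pos <- matrix(0.5, 3, 3, dimnames = list(ab, ab))
  neg <- -pos
  mi <- matrix(0.4, 3, 3, dimnames = list(ab, ab))
  cons <- build_consensus(list(C1 = list(
    s1 = make_net(pos, signed = TRUE),
    s2 = make_net(neg, signed = TRUE),
    s3 = make_net(neg, signed = TRUE),
    u1 = make_net(mi, "clr", signed = FALSE)
  )))
  expect_true(all(sign(cons$cohorts$C1$weight) <= 0))
  # unsigned-only set defaults to positive sign
  cons2 <- build_consensus(list(C1 = list(u1 = make_net(mi, "clr",
                                                        signed = FALSE))))
  expect_true(all(cons2$cohorts$C1$weight >= 0))
  expect_error(build_consensus(list(C1 = list()), character(0)), "empty")
})

test_that("inflection detection finds a planted knee", {
  cand <- seq(25, 500, by = 25)
  # piecewise linear with a single knee at the 8th candidate
  knee <- 8L
  series <- c(seq(90, 76, length.out = knee),
              seq(76, 74, length.out = length(cand) - knee + 1L)[-1L])
  expect_equal(detect_inflection(series), knee)
  expect_true(is.na(detect_inflection(rep(5, 20))))
  expect_true(is.na(detect_inflection(seq(1, 20))))
})

test_that("threshold selection returns a candidate and degrades gracefully", {
  gt <- generate_ground_truth(12, density = 0.2, seed = 30)
  st <- sample_cohorts(gt, c(A = 150, B = 150, C = 150, D = 150),
                       noise_sd = 0.1, heterogeneity = 0.4, seed = 31)
  nets <- lapply(st$cohorts, function(x) {
    list(pearsoncor = infer_network(x, "pearsoncor"),
         simpleparcor = infer_network(x, "simpleparcor"))
  })
  cons <- build_consensus(nets)
  cand <- seq(5, 60, by = 5)
  sel <- select_rank_threshold(cons, candidates = cand)
  expect_true(sel$threshold %in% cand)
  expect_equal(nrow(sel$series), length(cand))
  expect_error(
    select_rank_threshold(build_consensus(nets[1]), candidates = cand),
    "2 cohorts"
  )
  # with three or fewer cohorts the first three components always explain
  # everything: a constant series degrades to the median candidate
  expect_warning(
    sel3 <- select_rank_threshold(build_consensus(nets[1:3]),
                                  candidates = cand),
    "degenerate"
  )
  expect_equal(sel3$threshold, cand[ceiling(length(cand) / 2)])
})

test_that("discovery set union, recurrence and error paths are exact", {
  pairs <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                      stringsAsFactors = FALSE)
  ab <- c("A", "B", "C")
  # two cohorts sharing one of their two significant pairs each
  mk <- function(r) {
    data.frame(a = pairs$a, b = pairs$b, rank = r,
               weight = c(0.5, 0.4, 0.3), stringsAsFactors = FALSE)
  }
  cons <- structure(
    list(cohorts = list(C1 = mk(c(1, 2, 9)), C2 = mk(c(1, 9, 2))),
         antibody_ids = ab, method_set = "m", n_pairs = 3L),
    class = "ppi_consensus"
  )
  disc <- build_discovery_set(cons, threshold = 3)
  expect_equal(nrow(disc$pairs), 3L)
  expect_equal(unname(disc$recurrence), c(2, 1, 1))
  # double-counting identity
  expect_equal(sum(disc$recurrence), sum(disc$significant))
  expect_equal(disc$pan_weight, rowMeans(disc$weights))
  expect_error(build_discovery_set(cons, threshold = 1), "significant")
})

test_that("cohort similarity computes Jaccard indices and clustering", {
  pairs <- data.frame(a = c("A", "A", "B", "C"), b = c("B", "C", "C", "D"),
                      stringsAsFactors = FALSE)
  w <- matrix(c(0.5, 0.5,
                0.4, 0.4,
                0.3, 0.3,
                0.2, 0.2), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("C1", "C2")))
  # sets {1,2,3} and {2,3,4}: Jaccard 2/4
  sig <- cbind(C1 = c(TRUE, TRUE, TRUE, FALSE),
               C2 = c(FALSE, TRUE, TRUE, TRUE))
  disc <- make_discovery(pairs, w, sig)
  sim <- cohort_similarity(disc)
  expect_equal(sim$jaccard["C1", "C2"], 0.5)

  # identical cohorts: Jaccard 1, distance 0
  disc2 <- make_discovery(pairs, w, cbind(C1 = rep(TRUE, 4),
                                          C2 = rep(TRUE, 4)))
  sim2 <- cohort_similarity(disc2)
  expect_equal(sim2$jaccard["C1", "C2"], 1)
  expect_equal(as.numeric(dist(t(disc2$weights))), 0)

  # disjoint significant sets
  disc3 <- make_discovery(pairs, w, cbind(C1 = c(TRUE, TRUE, FALSE, FALSE),
                                          C2 = c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(cohort_similarity(disc3)$jaccard["C1", "C2"], 0)
})

test_that("a high-performer consensus beats the all-method consensus under noise", {
  gt <- generate_ground_truth(15, density = 0.15, seed = 40)
  gold <- gold_standard(gt$edges)
  st <- sample_cohorts(gt, c(X = 1500), noise_sd = 0, seed = 41)
  x <- st$cohorts$X
  good <- list(
    pearsoncor = infer_network(x, "pearsoncor"),
    simpleparcor = infer_network(x, "simpleparcor"),
    genenet = infer_network(x, "genenet")
  )
  noise_nets <- lapply(1:4, function(i) {
    set.seed(100 + i)
    w <- matrix(rnorm(15 * 15), 15)
    w <- (w + t(w)) / 2
    dimnames(w) <- list(gt$antibodies, gt$antibodies)
    make_net(w, method = paste0("noise", i))
  })
  names(noise_nets) <- paste0("noise", 1:4)
  all_nets <- c(good, noise_nets)

  precision_at <- function(cons, k) {
    df <- cons$cohorts$X
    top <- df[order(df$rank), ][seq_len(k), ]
    gold_keys <- pkey(gold$pairs$a, gold$pairs$b)
    mean(pkey(top$a, top$b) %in% gold_keys)
  }
  k <- nrow(gt$edges)
  p_top <- precision_at(build_consensus(list(X = all_nets),
                                        method_set = names(good)), k)
  p_all <- precision_at(build_consensus(list(X = all_nets)), k)
  expect_gte(p_top, p_all)
})
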