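# End-to-end pipeline over a synthetic study: simulate -> infer ->
# evaluate -> consensus -> modules -> map. Each stage reads its inputs
# from and writes its outputs to the configured output directory, so the
# stages also work as standalone subcommands; run_pipeline() chains them.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "ppinet-out",
    synthetic = list(
      n_antibodies = 20L,
      density = 0.0929,
      phospho_fraction = 51 / 187,
      multi_gene_fraction = 0.1,
      cohort_sizes = list(COHORT01 = 120L, COHORT02 = 90L, COHORT03 = 60L),
      noise_sd = 0.1,
      heterogeneity = 0.3,
      n_lists = 40L,
      n_top_level = 8L
    ),
    methods = ppi_methods(),
    recall_max = 0.1,
    top_k = 6L,
    candidate_thresholds = list(from = 5L, to = 150L, by = 5L),
    n_groups = 3L,
    n_modules = 4L,
    community_algorithms = c("fast_greedy", "spinglass", "louvain",
                             "infomap", "walktrap")
  )
}

#' Load a pipeline configuration
#'
#' Reads a YAML configuration and merges it over the defaults. See the
#' packaged example `system.file("extdata", "toy-config.yaml",
#' package = "ppinet")` for the recognized fields.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_config(pipeline_defaults(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

cfg_path <- function(cfg, ...) {
  file.path(cfg$outdir, ...)
}

stage_simulate <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  sy <- cfg$synthetic
  gt <- generate_ground_truth(
    n_antibodies = sy$n_antibodies, density = sy$density,
    phospho_fraction = sy$phospho_fraction,
    multi_gene_fraction = sy$multi_gene_fraction,
    seed = derive_seed(cfg$seed, "ground_truth")
  )
  sizes <- unlist(sy$cohort_sizes)
  study <- sample_cohorts(gt, sizes, noise_sd = sy$noise_sd,
                          heterogeneity = sy$heterogeneity,
                          seed = derive_seed(cfg$seed, "cohorts"))
  ds <- as_expression_dataset(study)
  write_expression_tsv(ds, cfg_path(cfg, "expression.tsv"))
  write_annotation_tsv(gt$annotation, cfg_path(cfg, "annotation.tsv"))
  write_gold_standard(gold_standard(gt$edges),
                      cfg_path(cfg, "gold_standard.tsv"))
  genes <- unique(unlist(strsplit(gt$annotation$gene_symbols, ";")))
  gl <- generate_genelist_hierarchy(
    genes, n_lists = sy$n_lists, n_top_level = sy$n_top_level,
    seed = derive_seed(cfg$seed, "genelists")
  )
  write_gene_lists(gl, cfg_path(cfg, "gene_lists.gmt"))
  write_relations(gl, cfg_path(cfg, "gene_list_relations.tsv"))
  invisible(study)
}

stage_infer <- function(cfg) {
  ds <- read_expression_tsv(cfg_path(cfg, "expression.tsv"))
  dir.create(cfg_path(cfg, "networks"), recursive = TRUE,
             showWarnings = FALSE)
  for (cohort in unique(ds$cohort_labels)) {
    x <- cohort_matrix(ds, cohort)
    for (method in cfg$methods) {
      net <- infer_network(x, method, seed = derive_seed(cfg$seed, method))
      write_network_tsv(rank_edges(net),
                        cfg_path(cfg, "networks",
                                 paste0(cohort, "_", method, ".tsv")))
    }
  }
  invisible(NULL)
}

stage_evaluate <- function(cfg) {
  ds <- read_expression_tsv(cfg_path(cfg, "expression.tsv"))
  gold <- read_gold_standard(cfg_path(cfg, "gold_standard.tsv"))
  cohorts <- unique(ds$cohort_labels)
  dir.create(cfg_path(cfg, "networks_optimal"), recursive = TRUE,
             showWarnings = FALSE)
  aupr_tab <- matrix(NA_real_, length(cfg$methods), length(cohorts),
                     dimnames = list(cfg$methods, cohorts))
  for (cohort in cohorts) {
    x <- cohort_matrix(ds, cohort)
    for (method in cfg$methods) {
      opt <- optimize_params(x, method, gold,
                             recall_max = cfg$recall_max,
                             seed = derive_seed(cfg$seed, method))
      aupr_tab[method, cohort] <- opt$best_aupr
      write_network_tsv(rank_edges(opt$best_network),
                        cfg_path(cfg, "networks_optimal",
                                 paste0(cohort, "_", method, ".tsv")))
    }
  }
  write_matrix_tsv(aupr_tab, cfg_path(cfg, "aupr_table.tsv"),
                   row_label = "method")
  scores <- rank_methods(aupr_tab)
  write_tsv_file(scores$scores, cfg_path(cfg, "method_scores.tsv"))
  invisible(scores)
}

read_optimal_networks <- function(cfg, cohorts, methods, ab) {
  lapply(setNames(cohorts, cohorts), function(cohort) {
    lapply(setNames(methods, methods), function(method) {
      rk <- read_network_tsv(cfg_path(cfg, "networks_optimal",
                                      paste0(cohort, "_", method, ".tsv")))
      ranking_to_network(rk, ab, method)
    })
  })
}

# Rebuild a ppi_network from a serialized edge ranking.
ranking_to_network <- function(ranking, ab, method) {
  w <- matrix(0, length(ab), length(ab), dimnames = list(ab, ab))
  ii <- match(ranking$edges$a, ab)
  jj <- match(ranking$edges$b, ab)
  w[cbind(ii, jj)] <- ranking$edges$weight
  w[cbind(jj, ii)] <- ranking$edges$weight
  structure(
    list(weights = w, antibody_ids = ab, method = method, params = list(),
         signed = !(method %in% mi_family())),
    class = "ppi_network"
  )
}

stage_consensus <- function(cfg) {
  ds <- read_expression_tsv(cfg_path(cfg, "expression.tsv"))
  ab <- ds$antibody_ids
  cohorts <- unique(ds$cohort_labels)
  aupr_tab <- as.matrix(read.delim(cfg_path(cfg, "aupr_table.tsv"),
                                   row.names = 1L, check.names = FALSE))
  scores <- rank_methods(aupr_tab)
  top <- top_methods(scores, k = cfg$top_k)
  if (length(top) == 0L) top <- scores$scores$method[seq_len(cfg$top_k)]
  nets <- read_optimal_networks(cfg, cohorts, top, ab)
  cons <- build_consensus(nets, method_set = top)
  for (cohort in cohorts) {
    write_tsv_file(cons$cohorts[[cohort]],
                   cfg_path(cfg, paste0("consensus_", cohort, ".tsv")))
  }
  cand <- seq(cfg$candidate_thresholds$from, cfg$candidate_thresholds$to,
              by = cfg$candidate_thresholds$by)
  sel <- withCallingHandlers(
    select_rank_threshold(cons, candidates = cand),
    warning = function(w) invokeRestart("muffleWarning")
  )
  write_tsv_file(sel$series, cfg_path(cfg, "threshold_series.tsv"))
  disc <- build_discovery_set(cons, sel$threshold)
  disc_df <- data.frame(disc$pairs, recurrence = disc$recurrence,
                        pan_weight = disc$pan_weight,
                        stringsAsFactors = FALSE)
  for (cohort in colnames(disc$weights)) {
    disc_df[[paste0("weight_", cohort)]] <- disc$weights[, cohort]
  }
  write_tsv_file(disc_df, cfg_path(cfg, "discovery_set.tsv"))
  sim <- cohort_similarity(disc)
  write_matrix_tsv(sim$jaccard, cfg_path(cfg, "cohort_jaccard.tsv"),
                   row_label = "cohort")
  writeLines(c("threshold\ttop_methods",
               paste0(sel$threshold, "\t", paste(top, collapse = ","))),
             con = cfg_path(cfg, "consensus_summary.tsv"))
  invisible(list(consensus = cons, threshold = sel$threshold,
                 discovery = disc, top = top))
}

read_discovery <- function(cfg) {
  df <- read.delim(cfg_path(cfg, "discovery_set.tsv"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  wcols <- grep("^weight_", names(df), value = TRUE)
  weights <- as.matrix(df[, wcols, drop = FALSE])
  colnames(weights) <- sub("^weight_", "", wcols)
  rownames(weights) <- pair_key(df$a, df$b)
  summary_line <- read.delim(cfg_path(cfg, "consensus_summary.tsv"),
                             stringsAsFactors = FALSE)
  threshold <- summary_line$threshold[1L]
  cohorts <- colnames(weights)
  sig <- matrix(FALSE, nrow(df), length(cohorts),
                dimnames = dimnames(weights))
  for (cohort in cohorts) {
    cons <- read.delim(cfg_path(cfg, paste0("consensus_", cohort, ".tsv")),
                       stringsAsFactors = FALSE)
    key <- pair_key(cons$a, cons$b)
    sig[, cohort] <- cons$rank[match(rownames(weights), key)] < threshold
  }
  structure(
    list(pairs = df[, c("a", "b")], weights = weights, significant = sig,
         recurrence = rowSums(sig), pan_weight = rowMeans(weights),
         threshold = threshold,
         antibody_ids = sort(unique(c(df$a, df$b)))),
    class = "ppi_discovery"
  )
}

stage_modules <- function(cfg) {
  disc <- read_discovery(cfg)
  annotation <- read_annotation_tsv(cfg_path(cfg, "annotation.tsv"))
  n_groups <- min(cfg$n_groups, nrow(disc$pairs))
  groups <- classify_edge_groups(disc, n_groups = n_groups)
  grp_df <- data.frame(disc$pairs, group = as.character(groups$group),
                       stringsAsFactors = FALSE)
  write_tsv_file(grp_df, cfg_path(cfg, "edge_groups.tsv"))
  g <- discovery_graph(disc)
  mc <- detect_communities(g, algorithms = cfg$community_algorithms,
                           seed = derive_seed(cfg$seed, "communities"))
  write_matrix_tsv(mc$frequency, cfg_path(cfg, "module_frequency.tsv"),
                   row_label = "antibody")
  assignment <- cut_consensus_modules(
    mc, n_modules = min(cfg$n_modules, nrow(mc$frequency)))
  write_tsv_file(data.frame(antibody = names(assignment),
                            module = assignment, stringsAsFactors = FALSE),
                 cfg_path(cfg, "module_assignment.tsv"))
  stats <- module_statistics(assignment, disc, groups, annotation)
  write_tsv_file(stats$table, cfg_path(cfg, "module_statistics.tsv"))
  invisible(list(groups = groups, consensus = mc, assignment = assignment,
                 stats = stats))
}

stage_map <- function(cfg) {
  disc <- read_discovery(cfg)
  annotation <- read_annotation_tsv(cfg_path(cfg, "annotation.tsv"))
  gl <- read_gene_lists(cfg_path(cfg, "gene_lists.gmt"),
                        cfg_path(cfg, "gene_list_relations.tsv"))
  ism <- map_interactions(disc, annotation, gl)
  write_matrix_tsv(ism$strength, cfg_path(cfg, "interaction_strength.tsv"),
                   row_label = "list_id")
  hi <- hierarchy_index(gl)
  matched <- rownames(ism$strength)[rowSums(!is.na(ism$strength)) > 0L]
  trace <- data.frame(
    list_id = matched,
    depth = hi$depth[matched],
    top_level = vapply(matched, function(id) {
      paste(trace_top_level(id, hi), collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
  write_tsv_file(trace, cfg_path(cfg, "top_level_trace.tsv"))
  grp_df <- read.delim(cfg_path(cfg, "edge_groups.tsv"),
                       stringsAsFactors = FALSE)
  groups <- list(group = factor(grp_df$group,
                                levels = c("positive_dominant",
                                           "negative_dominant",
                                           "heterogeneous")))
  class(groups) <- "edge_groups"
  asn_df <- read.delim(cfg_path(cfg, "module_assignment.tsv"),
                       stringsAsFactors = FALSE)
  assignment <- setNames(asn_df$module, asn_df$antibody)
  tracks <- matches_by_module_group(ism, disc, groups, assignment)
  write_tsv_file(tracks, cfg_path(cfg, "match_tracks.tsv"))
  invisible(ism)
}

write_run_log <- function(cfg) {
  flat <- function(x, prefix = "") {
    out <- character(0)
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      if (is.list(v)) {
        out <- c(out, flat(v, key))
      } else {
        out <- c(out, paste0(key, " = ", paste(v, collapse = ",")))
      }
    }
    out
  }
  lines <- c(
    paste0("ppinet version = ", as.character(packageVersion("ppinet"))),
    paste0("R version = ", R.version.string),
    flat(cfg)
  )
  con <- file(cfg_path(cfg, "run_log.txt"), open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

#' Run the full pipeline on a synthetic study
#'
#' Chains simulate, infer, evaluate, consensus, modules and map on a
#' configuration, writing tab-separated outputs and a parameter log to the
#' configured output directory. The run is a pure function of the
#' configuration (including its seed): repeating it yields byte-identical
#' outputs.
#'
#' @param config configuration list or YAML path
#'   (see [load_pipeline_config()]).
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) load_pipeline_config(config) else
    merge_config(pipeline_defaults(), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  write_run_log(cfg)
  stage_simulate(cfg)
  stage_infer(cfg)
  stage_evaluate(cfg)
  stage_consensus(cfg)
  stage_modules(cfg)
  stage_map(cfg)
  invisible(cfg$outdir)
}

#' Command-line interface
#'
#' Subcommands `simulate`, `infer`, `evaluate`, `consensus`, `modules`,
#' `map` and `run-all`, each taking `--config <path>`. A thin wrapper
#' script is installed at `system.file("scripts", "ppinet",
#' package = "ppinet")`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
ppi_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ppinet <simulate|infer|evaluate|consensus|modules|map|run-all>",
    "--config <file.yaml>"
  )
  stages <- list(simulate = stage_simulate, infer = stage_infer,
                 evaluate = stage_evaluate, consensus = stage_consensus,
                 modules = stage_modules, map = stage_map)
  if (length(args) < 1L || !args[1L] %in% c(names(stages), "run-all")) {
    message(usage)
    return(invisible(1L))
  }
  ci <- which(args == "--config")
  if (length(ci) != 1L || ci == length(args)) {
    message(usage)
    return(invisible(1L))
  }
  extra <- setdiff(args[-1L], c("--config", args[ci + 1L]))
  if (length(extra)) {
    message("unknown argument(s): ", paste(extra, collapse = " "))
    message(usage)
    return(invisible(1L))
  }
  status <- tryCatch({
    cfg <- load_pipeline_config(args[ci + 1L])
    if (args[1L] == "run-all") {
      run_pipeline(cfg)
    } else {
      dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
      stages[[args[1L]]](cfg)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
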