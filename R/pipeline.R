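# End-to-end orchestration: one configuration in, a machine-readable
# analysis report (plus optional artifact files) out.

#' Pipeline configuration
#'
#' Exactly one input source must be given: paths to event/census CSV files,
#' or a [sim_config()] block for a synthetic colony.  Randomization counts
#' default to interactive-scale values; raise them to the per-function
#' defaults for publication-scale runs.  A single `seed` deterministically
#' derives per-stage sub-seeds, so adding a stage never perturbs earlier
#' stages' randomness.
#'
#' @param events,census paths to input CSV files (both required together).
#' @param sim a [sim_config()] for synthetic input.
#' @param seed master seed.
#' @param out_dir optional directory for artifact files (created if needed).
#' @param n_rand randomizations for DC, h', steepness, assortativity,
#'   within/between, and evenness tests.
#' @param n_rand_ttri random graphs for triangle transitivity.
#' @param n_random_extreme,extreme_replicates Bernoulli-graph draws.
#' @param n_boot bootstrap replicates for comembership.
#' @param n_perm_mantel Mantel permutations.
#' @param assign_threshold consensus assignment threshold.
#' @param n_restarts I&SI restarts.
#' @param nmds_starts nMDS starts.
#' @param behaviors optional ethogram filter for the sociomatrices.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(events = NULL, census = NULL, sim = NULL,
                            seed = 1, out_dir = NULL,
                            n_rand = 1000, n_rand_ttri = 1000,
                            n_random_extreme = 1000, extreme_replicates = 5,
                            n_boot = 200, n_perm_mantel = 1000,
                            assign_threshold = 0.5, n_restarts = 10,
                            nmds_starts = 10, behaviors = NULL) {
  has_paths <- !is.null(events) || !is.null(census)
  if (has_paths && is.null(sim)) {
    if (is.null(events) || is.null(census)) {
      stop("both 'events' and 'census' paths are required", call. = FALSE)
    }
  } else if (!is.null(sim) && !has_paths) {
    stopifnot(inherits(sim, "sim_config"))
  } else {
    stop("supply either input paths or a simulation block, not both",
         call. = FALSE)
  }
  structure(list(events = events, census = census, sim = sim, seed = seed,
                 out_dir = out_dir, n_rand = n_rand,
                 n_rand_ttri = n_rand_ttri,
                 n_random_extreme = n_random_extreme,
                 extreme_replicates = extreme_replicates, n_boot = n_boot,
                 n_perm_mantel = n_perm_mantel,
                 assign_threshold = assign_threshold,
                 n_restarts = n_restarts, nmds_starts = nmds_starts,
                 behaviors = behaviors),
            class = "pipeline_config")
}

not_computed <- function(reason) list(computed = FALSE, reason = reason)

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full colony analysis pipeline
#'
#' Stages, in dependency order: input (read or simulate), sociomatrices,
#' hierarchy statistics, network structure and position metrics, community
#' detection with bootstrap consensus, association indices and their tests,
#' and spatial-usage analyses.  Identical configuration and seed yield an
#' identical report.  Stages whose preconditions fail (for example N < 3
#' for h') are reported as not computed, with the reason.
#'
#' @param config a [pipeline_config()].
#' @return nested list of class `analysis_report`; written as `report.json`
#'   (plus TSV artifacts) when `config$out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  input <- run_stage("input", {
    if (!is.null(config$sim)) {
      colony <- simulate_colony(config$sim)
      list(events = colony$events, census = colony$census,
           truth = colony$truth, source = "simulation")
    } else {
      list(events = read_event_log(config$events),
           census = read_census_log(config$census, roster = NULL),
           truth = NULL, source = "files")
    }
  })
  log <- input$events
  n <- length(log$roster)

  mats <- run_stage("sociomatrix", {
    freq <- frequency_matrix(log, behaviors = config$behaviors)
    list(freq = freq, binary = binarize(freq), sym = symmetrize(freq))
  })

  hier <- run_stage("hierarchy", {
    if (n < 3) {
      not_computed("hierarchy statistics need at least 3 individuals")
    } else {
      h <- hierarchy_summary(log, n_rand = config$n_rand,
                             n_rand_ttri = config$n_rand_ttri,
                             seed = derive_seed(seed, 1000),
                             n_restarts = config$n_restarts)
      h$transitivity <- tryCatch(h$transitivity, error = function(e)
        not_computed(conditionMessage(e)))
      h
    }
  })

  network <- run_stage("network", {
    if (n < 3) {
      not_computed("network summary needs at least 3 individuals")
    } else {
      network_summary(mats$binary, n_rand = config$n_rand,
                      n_random = config$n_random_extreme,
                      replicates = config$extreme_replicates,
                      seed = derive_seed(seed, 2000))
    }
  })
  nodes <- run_stage("node_metrics", {
    ranking <- if (!is.null(hier$ranking)) hier$ranking else NULL
    node_metrics(mats$binary, ranking = ranking)
  })

  community <- run_stage("community", {
    if (sum(mats$sym) == 0) {
      not_computed("no interactions: community structure undefined")
    } else {
      cm <- bootstrap_comembership(log, n_boot = config$n_boot,
                                   seed = derive_seed(seed, 3000))
      list(single = girvan_newman(mats$sym),
           comembership = cm,
           consensus = consensus_communities(cm, config$assign_threshold))
    }
  })

  association <- run_stage("association", {
    hwi <- hwi_matrix(input$census)
    mantel <- if (!is.null(community$comembership)) {
      tryCatch(mantel_test(hwi, community$comembership,
                           n_perm = config$n_perm_mantel,
                           seed = derive_seed(seed, 4000)),
               error = function(e) not_computed(conditionMessage(e)))
    } else {
      not_computed("comembership matrix unavailable")
    }
    wb <- if (!is.null(community$consensus)) {
      tryCatch(within_between_test(hwi, community$consensus,
                                   n_rand = config$n_rand,
                                   seed = derive_seed(seed, 5000)),
               error = function(e) not_computed(conditionMessage(e)))
    } else {
      not_computed("consensus communities unavailable")
    }
    list(hwi = hwi, mantel = mantel, within_between = wb)
  })

  spatial <- run_stage("spatial", {
    spatial_summary(log, n_rand = config$n_rand,
                    n_starts = config$nmds_starts,
                    seed = derive_seed(seed, 6000))
  })

  report <- structure(list(
    provenance = list(
      package = "colonynet",
      version = as.character(utils::packageVersion("colonynet")),
      seed = seed, source = input$source,
      n_individuals = n, n_events = nrow(log$events),
      n_census_periods = length(input$census$periods),
      config = config[setdiff(names(config), c("sim"))]
    ),
    hierarchy = hier, network = network, node_metrics = nodes,
    community = community, association = association, spatial = spatial,
    truth = input$truth
  ), class = "analysis_report")

  if (!is.null(config$out_dir)) write_report(report, mats, config$out_dir)
  report
}

write_report <- function(report, mats, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(mats$freq, file.path(out_dir, "frequency_matrix.tsv"))
  write_matrix_tsv(mats$binary, file.path(out_dir, "binary_matrix.tsv"))
  utils::write.table(report$node_metrics, file.path(out_dir, "node_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$association$hwi)) {
    hwi <- report$association$hwi
    attributes(hwi)[c("x", "yAB", "y_only", "undefined")] <- NULL
    write_matrix_tsv(hwi, file.path(out_dir, "hwi.tsv"))
  }
  if (!is.null(report$community$comembership)) {
    cm <- report$community$comembership
    attr(cm, "n_boot") <- NULL
    write_matrix_tsv(cm, file.path(out_dir, "comembership.tsv"))
  }
  json <- report
  json$association$hwi <- NULL
  json$community$comembership <- NULL
  json$community$single$removals <- NULL
  json$community$consensus$removals <- NULL
  jsonlite::write_json(strip_for_json(json), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, force = TRUE)
  invisible(out_dir)
}

# Drop heavyweight matrix members so the JSON report stays readable.
strip_for_json <- function(x) {
  if (is.matrix(x)) return(NULL)
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_for_json)
    x <- x[!vapply(x, is.null, logical(1))]
  }
  x
}
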