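#' Run configuration for the full pipeline
#'
#' Collects every tunable of the analysis in one validated list: bin widths,
#' replicate counts, levels, the Bonferroni comparison counts, the optional
#' block-length override and the remapping-index sign convention. Defaults
#' are the analysis conditions the pipeline is designed for.
#'
#' @param acf_bin_s autocorrelation bin width, seconds (default 1).
#' @param acf_max_lag_s largest acf lag, seconds (default 30).
#' @param display_bin_s heatmap display bin, seconds (default 10).
#' @param consolidation_bin_min consolidation bin, minutes (default 15).
#' @param n_replicates bootstrap / resampling replicates (default 10000).
#' @param alpha significance level (default 0.05).
#' @param q_threshold FDR threshold (default 0.05).
#' @param responsiveness_comparisons Bonferroni divisor for the session
#'   contrasts (default 2: preC vs preS and preS vs postS).
#' @param block_length_s block-length override, seconds; `NULL` (default)
#'   estimates it from the population autocorrelation.
#' @param min_state_dwell_s minimum per-state dwell per consolidation bin
#'   (default 60).
#' @param ri_sign_convention `"text"` or `"printed"` (see [remapping_index()]).
#' @param similarity_sessions sessions entering the session-similarity
#'   clustering.
#' @param rng_seed master seed for every stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(acf_bin_s = 1, acf_max_lag_s = 30, display_bin_s = 10,
                       consolidation_bin_min = 15, n_replicates = 10000,
                       alpha = 0.05, q_threshold = 0.05,
                       responsiveness_comparisons = 2,
                       block_length_s = NULL, min_state_dwell_s = 60,
                       ri_sign_convention = c("text", "printed"),
                       similarity_sessions = c("preC", "preS", "postS", "test"),
                       rng_seed = 1) {
  ri_sign_convention <- match.arg(ri_sign_convention)
  assert_scalar_number(n_replicates, "n_replicates", lower = 1)
  assert_scalar_number(alpha, "alpha", lower = 1e-6, upper = 1 - 1e-6)
  assert_scalar_number(q_threshold, "q_threshold", lower = 1e-6, upper = 1 - 1e-6)
  structure(list(acf_bin_s = acf_bin_s, acf_max_lag_s = acf_max_lag_s,
                 display_bin_s = display_bin_s,
                 consolidation_bin_min = consolidation_bin_min,
                 n_replicates = n_replicates, alpha = alpha,
                 q_threshold = q_threshold,
                 responsiveness_comparisons = responsiveness_comparisons,
                 block_length_s = block_length_s,
                 min_state_dwell_s = min_state_dwell_s,
                 ri_sign_convention = ri_sign_convention,
                 similarity_sessions = similarity_sessions,
                 rng_seed = rng_seed),
            class = "run_config")
}

#' Run the full population-remapping pipeline on one experiment
#'
#' Executes the analysis stages in their natural order — population
#' autocorrelation and block-length estimation, per-neuron responsiveness for
#' the preC->preS and preS->postS transitions, session activity-vector
#' similarity with cluster significance, consolidation remapping traces
#' (all / sleep / wake), per-neuron remapping classification, group activity
#' profiles and subgroup clustering — and returns (optionally writes) a run
#' report carrying every seed, threshold and convention used.
#'
#' @param experiment an `abn_experiment`.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, result tables (TSV), the
#'   dendrogram (Newick) and the JSON run report are written there.
#' @return the report as a nested list (invisibly when `out_dir` is given).
#' @export
run_pipeline <- function(experiment, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(experiment, "abn_experiment"),
            inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  seeds <- derive_seeds(config$rng_seed, 5)

  acf_res <- stage("autocorrelation", {
    estimate_block_length(population_autocorrelation(
      experiment, bin_width = config$acf_bin_s, max_lag = config$acf_max_lag_s))
  })
  block <- config$block_length_s %||% acf_res$block_length

  resp <- stage("responsiveness", {
    lapply(list(c("preC", "preS"), c("preS", "postS")), function(tr) {
      classify_period_response(experiment, tr, block_length = block,
                               bin_width = config$acf_bin_s,
                               n_replicates = config$n_replicates,
                               alpha = config$alpha /
                                 config$responsiveness_comparisons,
                               rng_seed = seeds[1])
    })
  })
  names(resp) <- c("preC_preS", "preS_postS")

  sim <- stage("similarity", {
    vm <- activity_vector_matrix(
      experiment,
      as.list(stats::setNames(config$similarity_sessions,
                              config$similarity_sessions)),
      scaling = "vector_01")
    list(vectors = vm, matrix = similarity_matrix(vm),
         clusters = cluster_significance(vm, config$n_replicates,
                                         config$alpha, rng_seed = seeds[2]))
  })

  traces <- stage("remapping_trace", {
    lapply(c(all = "all", sleep = "sleep", wake = "wake"), function(sf) {
      remapping_trace(experiment, sf,
                      bin_minutes = config$consolidation_bin_min,
                      min_dwell_s = config$min_state_dwell_s,
                      sign_convention = config$ri_sign_convention)
    })
  })

  remap_labels <- stage("remapping_classification", {
    classify_remapping_neurons(experiment,
                               bin_minutes = config$consolidation_bin_min,
                               alpha = config$alpha,
                               q_threshold = config$q_threshold)
  })

  profile <- stage("group_profile", {
    group_activity_profile(experiment, remap_labels,
                           n_replicates = config$n_replicates,
                           alpha = config$alpha, rng_seed = seeds[3])
  })

  subgroups <- stage("subgroup_similarity", {
    tryCatch(
      subgroup_similarity(experiment, remap_labels,
                          sessions = config$similarity_sessions,
                          n_replicates = config$n_replicates,
                          alpha = config$alpha, rng_seed = seeds[4]),
      warning = function(w) {
        message("subgroup similarity: ", conditionMessage(w))
        suppressWarnings(
          subgroup_similarity(experiment, remap_labels,
                              sessions = config$similarity_sessions,
                              n_replicates = config$n_replicates,
                              alpha = config$alpha, rng_seed = seeds[4]))
      })
  })

  report <- list(
    config = unclass(config),
    stage_seeds = as.list(stats::setNames(seeds,
      c("responsiveness", "similarity_clusters", "group_profile",
        "subgroup_clusters", "unused"))),
    block_length_s = block,
    acf_fit_tau_s = acf_res$fit_tau,
    responsiveness = lapply(resp, function(r)
      as.list(response_fractions(r))),
    similarity = list(
      matrix = sim$matrix,
      significant_clusters = sim$clusters$significant_clusters,
      merge_pvalues = sim$clusters$merge_pvalues),
    remapping = lapply(traces, function(tr)
      list(pearson_r = tr$pearson_r, pearson_p = tr$pearson_p,
           slope_per_min = tr$slope, n_bins = nrow(tr$data),
           sign_convention = tr$sign_convention)),
    remapping_counts = as.list(table(factor(remap_labels$label,
      levels = c("decreasing", "increasing", "non_remapping")))),
    group_profile = profile$profile,
    group_comparisons = profile$comparisons,
    subgroup_significant_clusters = lapply(subgroups, function(sg)
      if (is.null(sg)) NULL else sg$clusters$significant_clusters)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(resp)) {
      utils::write.table(resp[[nm]], file.path(out_dir,
        paste0("responsiveness_", nm, ".tsv")), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    utils::write.table(remap_labels, file.path(out_dir, "remapping_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(profile$profile, file.path(out_dir, "group_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_dendrogram_newick(sim$clusters, file.path(out_dir, "similarity_dendrogram.nwk"))
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    return(invisible(report))
  }
  report
}
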