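#' Classify per-neuron activity changes between two sessions
#'
#' Each neuron's activity is binned at the autocorrelation resolution in both
#' sessions and the difference of mean binned activity (session B minus
#' session A) is tested with the moving block bootstrap, using one shared
#' block length (estimated from the population autocorrelation). A neuron is
#' labelled `increase` when the confidence interval lies entirely above zero,
#' `decrease` when entirely below, otherwise `no_change`.
#'
#' @param experiment an `abn_experiment`.
#' @param transition character pair `c(sessionA, sessionB)`.
#' @param block_length block length, seconds (default 10).
#' @param bin_width binning resolution, seconds (default 1).
#' @param n_replicates,alpha bootstrap settings.
#' @param rng_seed master seed; each neuron receives a derived sub-seed.
#' @return data.frame with one row per neuron: `neuron_id`, `mouse_id`,
#'   `transition`, `label`, `estimate`, `ci_low`, `ci_high`, `missing`.
#' @export
classify_period_response <- function(experiment, transition,
                                     block_length = 10, bin_width = 1,
                                     n_replicates = 10000, alpha = 0.05,
                                     rng_seed = 1) {
  stopifnot(inherits(experiment, "abn_experiment"), length(transition) == 2)
  for (s in transition) session_duration(experiment, s)  # errors if absent
  nt <- neuron_table(experiment)
  seeds <- derive_seeds(rng_seed, nrow(nt))
  out <- vector("list", nrow(nt))
  for (i in seq_len(nrow(nt))) {
    id <- nt$neuron_id[i]
    tr_a <- get_event_train(experiment, id, transition[1])
    tr_b <- get_event_train(experiment, id, transition[2])
    ba <- bin_events(tr_a, bin_width)
    bb <- bin_events(tr_b, bin_width)
    if (all(ba$values == 0) && all(bb$values == 0)) {
      out[[i]] <- data.frame(neuron_id = id, mouse_id = nt$mouse_id[i],
                             transition = paste(transition, collapse = "->"),
                             label = "no_change", estimate = 0,
                             ci_low = 0, ci_high = 0, missing = TRUE)
      next
    }
    bt <- moving_block_bootstrap_diff(bb, ba, block_length,
                                      n_replicates = n_replicates, alpha = alpha,
                                      rng_seed = seeds[i])
    label <- if (bt$ci_low > 0) "increase" else if (bt$ci_high < 0) "decrease"
             else "no_change"
    out[[i]] <- data.frame(neuron_id = id, mouse_id = nt$mouse_id[i],
                           transition = paste(transition, collapse = "->"),
                           label = label, estimate = bt$estimate,
                           ci_low = bt$ci_low, ci_high = bt$ci_high,
                           missing = FALSE)
  }
  do.call(rbind, out)
}

#' Proportions of increasing / decreasing / unchanged neurons
#'
#' @param labels a [classify_period_response()] result.
#' @return named numeric vector over `increase`, `decrease`, `no_change`,
#'   summing to 1.
#' @export
response_fractions <- function(labels) {
  if (!nrow(labels)) stop("no labels", call. = FALSE)
  lv <- c("increase", "decrease", "no_change")
  tab <- table(factor(labels$label, levels = lv))
  as.vector(tab / sum(tab)) |> stats::setNames(lv)
}

#' Classify a neuron as active or inactive in a period
#'
#' The period's binned activity trace is bootstrap-resampled over time bins
#' (with replacement, at the original length); the neuron is active when at
#' least the `quorum` fraction of replicates contains one or more
#' event-bearing bins. With `k` event-bearing bins out of `n`, the number of
#' resampled bins hitting an event-bearing one is Binomial(n, k/n) per
#' replicate; the replicates are drawn from that exact marginal.
#'
#' @param binned a [bin_events()] result (or numeric vector) for the period.
#' @param n_replicates resampling replicates (default 10000).
#' @param quorum required fraction of event-containing replicates (default 0.95).
#' @param rng_seed integer seed.
#' @return logical; attributes `hit_fraction` (fraction of replicates with at
#'   least one event) and `n_event_bins`.
#' @export
classify_active <- function(binned, n_replicates = 10000, quorum = 0.95,
                            rng_seed = 1) {
  x <- if (inherits(binned, "binned_activity")) binned$values else as.numeric(binned)
  n <- length(x)
  if (!n) stop("empty trace", call. = FALSE)
  k <- sum(x > 0)
  hits <- if (k == 0) rep(FALSE, n_replicates) else
    with_seed(rng_seed, stats::rbinom(n_replicates, n, k / n) > 0)
  frac <- mean(hits)
  structure(frac >= quorum, hit_fraction = frac, n_event_bins = k)
}

#' Overlap statistics between two active-neuron sets
#'
#' Reports the Jaccard index, both conditional fractions, and a hypergeometric
#' enrichment p-value (probability of an intersection at least as large under
#' random draws from the universe).
#'
#' @param set_a,set_b character vectors of neuron ids.
#' @param universe all neuron ids under consideration (non-empty; both sets
#'   must be subsets).
#' @return list with `jaccard`, `p_b_given_a`, `p_a_given_b`,
#'   `hypergeom_p`, `n_intersection`.
#' @export
population_overlap <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(as.character(universe))
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    stop("sets must be subsets of the universe", call. = FALSE)
  }
  inter <- length(intersect(set_a, set_b))
  uni <- length(union(set_a, set_b))
  p_hyper <- if (!length(set_a) || !length(set_b)) 1 else
    stats::phyper(inter - 1, length(set_b), length(universe) - length(set_b),
                  length(set_a), lower.tail = FALSE)
  list(jaccard = if (uni) inter / uni else NA_real_,
       p_b_given_a = if (length(set_a)) inter / length(set_a) else NA_real_,
       p_a_given_b = if (length(set_b)) inter / length(set_b) else NA_real_,
       hypergeom_p = p_hyper,
       n_intersection = inter)
}
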