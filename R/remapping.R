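#' Restrict an experiment to a subset of neurons
#'
#' @param experiment an `abn_experiment`.
#' @param neuron_ids ids to keep.
#' @return an `abn_experiment` over the subset.
#' @export
subset_experiment <- function(experiment, neuron_ids) {
  stopifnot(inherits(experiment, "abn_experiment"))
  neuron_ids <- as.character(neuron_ids)
  unknown <- setdiff(neuron_ids, experiment$neurons$neuron_id)
  if (length(unknown)) stop("unknown neuron(s): ",
                            paste(utils::head(unknown, 5), collapse = ", "),
                            call. = FALSE)
  gt <- experiment$ground_truth
  if (!is.null(gt)) gt <- gt[gt$neuron_id %in% neuron_ids, , drop = FALSE]
  new_experiment(
    events = experiment$events[experiment$events$neuron_id %in% neuron_ids, ,
                               drop = FALSE],
    session_durations = experiment$session_durations,
    hypnogram = experiment$hypnogram,
    neurons = experiment$neurons[experiment$neurons$neuron_id %in% neuron_ids, ,
                                 drop = FALSE],
    ground_truth = gt
  )
}

# Hypnogram intervals (non-overlapping, sorted) for a state filter.
state_intervals <- function(hypnogram, state_filter) {
  states <- switch(state_filter,
                   sleep = c("NREM", "REM"),
                   wake = "wake",
                   REM = "REM",
                   stop("unknown state filter '", state_filter, "'", call. = FALSE))
  hypnogram[hypnogram$state %in% states, c("start_s", "end_s"), drop = FALSE]
}

# Clip a set of intervals to [t0, t1); returns total dwell (s).
clip_dwell <- function(intervals, t0, t1) {
  s <- pmax(intervals$start_s, t0)
  e <- pmin(intervals$end_s, t1)
  sum(pmax(e - s, 0))
}

# TRUE for event times falling inside any of the (sorted, disjoint) intervals.
in_intervals <- function(times, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(times)))
  pos <- findInterval(times, intervals$start_s)
  pos >= 1 & times < intervals$end_s[pmax(pos, 1)]
}

#' Consolidation-period activity matrix in 15-min bins
#'
#' Divides the consolidation recording into consecutive bins and computes, per
#' neuron and bin, the mean unitary-event activity over the bin's qualifying
#' time: the whole bin (`all`), or its intersection with the hypnogram's sleep
#' (NREM + REM) or wake intervals. State-restricted bins with less than
#' `min_dwell_s` of qualifying time are dropped. Values are truncated at each
#' mouse's 95th percentile per bin; with `scaling = "neuron_max"` each
#' neuron's values are divided by its maximum across the *all-state* bins, so
#' state-restricted matrices live on the same scale as the all-state matrix.
#'
#' REM-restricted matrices are refused by default: REM occupies too little of
#' the consolidation period (and carries too little of the activity) to yield
#' stable bins. Set `allow_rem = TRUE` to force the attempt anyway.
#'
#' @param experiment an `abn_experiment` with a consolidation session (and a
#'   hypnogram when `state_filter != "all"`).
#' @param bin_minutes bin width, minutes (default 15).
#' @param state_filter `"all"`, `"sleep"`, `"wake"` (or `"REM"`, refused by
#'   default).
#' @param min_dwell_s minimum qualifying dwell per state-restricted bin
#'   (default 60 s).
#' @param truncate_p truncation percentile (default 0.95).
#' @param scaling `"neuron_max"` (default) or `"none"`.
#' @param allow_rem permit REM-restricted matrices.
#' @return matrix neurons x kept bins, with attributes `bin_centers_min`,
#'   `bin_index`, `dwell_s`, `state_filter`.
#' @export
consolidation_activity_matrix <- function(experiment, bin_minutes = 15,
                                          state_filter = c("all", "sleep", "wake", "REM"),
                                          min_dwell_s = 60, truncate_p = 0.95,
                                          scaling = c("neuron_max", "none"),
                                          allow_rem = FALSE) {
  state_filter <- match.arg(state_filter)
  scaling <- match.arg(scaling)
  if (state_filter == "REM" && !allow_rem) {
    stop("REM-restricted activity matrices are refused by default: REM sleep ",
         "is too sparse in the consolidation period for stable 15-min bins ",
         "(set allow_rem = TRUE to override)", call. = FALSE)
  }
  dur <- session_duration(experiment, "consolidation")
  bin_s <- bin_minutes * 60
  n_bins <- floor(dur / bin_s + 1e-9)
  if (n_bins < 2) stop("consolidation recording shorter than 2 bins", call. = FALSE)

  nt <- neuron_table(experiment)
  ev <- experiment$events[experiment$events$session == "consolidation", ,
                          drop = FALSE]
  ev <- ev[ev$time_s < n_bins * bin_s, , drop = FALSE]

  if (state_filter == "all") {
    dwell <- rep(bin_s, n_bins)
    qualifies <- rep(TRUE, nrow(ev))
  } else {
    if (is.null(experiment$hypnogram)) {
      stop("state-restricted binning needs a hypnogram", call. = FALSE)
    }
    ivs <- state_intervals(experiment$hypnogram, state_filter)
    dwell <- vapply(seq_len(n_bins), function(b)
      clip_dwell(ivs, (b - 1) * bin_s, b * bin_s), numeric(1))
    qualifies <- in_intervals(ev$time_s, ivs)
  }
  keep <- if (state_filter == "all") seq_len(n_bins) else
    which(dwell >= min_dwell_s)
  if (!length(keep)) {
    stop("no consolidation bin with at least ", min_dwell_s,
         " s of '", state_filter, "' time", call. = FALSE)
  }

  bin_of <- floor(ev$time_s / bin_s) + 1L
  m <- matrix(0, nrow(nt), n_bins,
              dimnames = list(nt$neuron_id, paste0("bin", seq_len(n_bins))))
  use <- qualifies
  if (any(use)) {
    key <- paste(ev$neuron_id[use], bin_of[use], sep = "\r")
    sums <- rowsum(ev$amplitude[use], key)
    parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
    ridx <- match(vapply(parts, `[[`, "", 1), nt$neuron_id)
    cidx <- as.integer(vapply(parts, `[[`, "", 2))
    m[cbind(ridx, cidx)] <- sums[, 1]
  }
  m <- sweep(m, 2, dwell / 60, "/")
  m[, dwell == 0] <- 0
  if (!is.na(truncate_p)) {
    for (b in seq_len(n_bins)) {
      m[, b] <- truncate_by_mouse(m[, b], nt$mouse_id, truncate_p)
    }
  }
  m <- m[, keep, drop = FALSE]
  if (scaling == "neuron_max") {
    ref <- if (state_filter == "all") m else
      consolidation_activity_matrix(experiment, bin_minutes, "all",
                                    min_dwell_s, truncate_p, scaling = "none")
    m <- scale_neuron_max(m, reference = ref)
  }
  structure(m,
            bin_centers_min = (keep - 0.5) * bin_minutes,
            bin_index = keep, dwell_s = dwell[keep],
            state_filter = state_filter)
}

#' Remapping index of an activity vector between two references
#'
#' Locates the current population vector `Bt` between the first (`A`) and last
#' (`C`) consolidation-bin vectors on the angular-distance scale
#' `AD(X, Y) = 1 - cos(X, Y)`. Under the default `"text"` convention,
#' `RI = (AD(C, Bt) - AD(A, Bt)) / (AD(A, Bt) + AD(C, Bt))`: +1 means a
#' perfect match to the first bin, -1 a perfect match to the last, 0
#' equidistance. The `"printed"` convention negates the numerator order. When
#' `Bt` matches both references (zero denominator) the index is defined as 0
#' and flagged degenerate.
#'
#' @param first,last,current numeric vectors of one length, nonzero norms.
#' @param sign_convention `"text"` (default; +1 = first bin) or `"printed"`.
#' @return value in `[-1, 1]`; attribute `degenerate`.
#' @export
remapping_index <- function(first, last, current,
                            sign_convention = c("text", "printed")) {
  sign_convention <- match.arg(sign_convention)
  ad_a <- 1 - cosine_similarity(first, current)
  ad_c <- 1 - cosine_similarity(last, current)
  denom <- ad_a + ad_c
  if (denom <= .Machine$double.eps^0.5) {
    return(structure(0, degenerate = TRUE))
  }
  ri <- (ad_c - ad_a) / denom
  if (sign_convention == "printed") ri <- -ri
  structure(max(-1, min(1, ri)), degenerate = FALSE)
}

#' Time-resolved remapping index over the consolidation period
#'
#' Computes the remapping index of every qualifying consolidation bin against
#' the first (`A`) and last (`C`) bins of the *all-state* matrix, optionally
#' restricting each bin's activity to sleep or wake time. The linear trend of
#' RI against bin-center time (Pearson r, two-sided p, least-squares slope per
#' minute) is computed over the non-reference bins only: the reference bins'
#' RI is +1 and -1 by construction and would bias the trend of any series,
#' including a stationary null.
#'
#' @param experiment an `abn_experiment`.
#' @param state_filter `"all"`, `"sleep"` or `"wake"`.
#' @param bin_minutes,min_dwell_s,truncate_p as in
#'   [consolidation_activity_matrix()].
#' @param sign_convention see [remapping_index()].
#' @return a `remapping_trace`: list with `data` (data.frame `bin_index`,
#'   `bin_center_min`, `ri`, `is_reference`), `state_filter`, `pearson_r`,
#'   `pearson_p`, `slope`, `sign_convention`.
#' @export
remapping_trace <- function(experiment, state_filter = c("all", "sleep", "wake"),
                            bin_minutes = 15, min_dwell_s = 60,
                            truncate_p = 0.95,
                            sign_convention = c("text", "printed")) {
  state_filter <- match.arg(state_filter)
  sign_convention <- match.arg(sign_convention)
  m_all <- consolidation_activity_matrix(experiment, bin_minutes, "all",
                                         min_dwell_s, truncate_p, "neuron_max")
  ref_idx <- range(attr(m_all, "bin_index"))
  a_vec <- m_all[, 1]
  c_vec <- m_all[, ncol(m_all)]
  if (sum(a_vec) == 0 || sum(c_vec) == 0) {
    stop("reference bin with no activity", call. = FALSE)
  }
  m <- if (state_filter == "all") m_all else {
    ref <- consolidation_activity_matrix(experiment, bin_minutes, "all",
                                         min_dwell_s, truncate_p, "none")
    ms <- consolidation_activity_matrix(experiment, bin_minutes, state_filter,
                                        min_dwell_s, truncate_p, "none")
    scale_neuron_max(ms, reference = ref)
  }
  idx <- attr(m, "bin_index")
  if (length(idx) < 3) stop("fewer than 3 qualifying bins", call. = FALSE)
  ri <- vapply(seq_along(idx), function(j) {
    col <- m[, j]
    if (sum(col) == 0) return(NA_real_)
    as.numeric(remapping_index(a_vec, c_vec, col, sign_convention))
  }, numeric(1))
  df <- data.frame(bin_index = idx,
                   bin_center_min = attr(m, "bin_centers_min"),
                   ri = ri,
                   is_reference = idx %in% ref_idx)
  fit_rows <- !df$is_reference & !is.na(df$ri)
  if (sum(fit_rows) >= 3 && stats::sd(df$ri[fit_rows]) > 0) {
    ct <- stats::cor.test(df$bin_center_min[fit_rows], df$ri[fit_rows],
                          method = "pearson", alternative = "two.sided")
    slope <- unname(stats::coef(stats::lm(ri ~ bin_center_min,
                                          data = df[fit_rows, ]))[2])
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- NA_real_; p <- NA_real_; slope <- NA_real_
  }
  structure(list(data = df, state_filter = state_filter,
                 pearson_r = r, pearson_p = p, slope = slope,
                 sign_convention = sign_convention),
            class = "remapping_trace")
}

#' @export
print.remapping_trace <- function(x, ...) {
  cat(sprintf("<remapping_trace> %s: %d bins, r = %.3f, p = %.2g, slope = %.4f/min\n",
              x$state_filter, nrow(x$data), x$pearson_r, x$pearson_p, x$slope))
  invisible(x)
}

#' Classify neurons whose consolidation activity tracks time
#'
#' Per neuron, Pearson-correlates the per-bin mean activity (truncated,
#' unscaled; the correlation is scale-invariant per neuron) with bin-center
#' time, then adjusts the p-values across neurons by Benjamini-Hochberg.
#' `decreasing` / `increasing` require both `p < alpha` and `q < q_threshold`
#' with the matching sign of r; constant-activity neurons have no defined
#' correlation and are `non_remapping` with p = 1.
#'
#' @param experiment an `abn_experiment`.
#' @param bin_minutes consolidation bin width, minutes (default 15).
#' @param alpha per-neuron p threshold (default 0.05).
#' @param q_threshold FDR threshold (default 0.05).
#' @param truncate_p truncation percentile.
#' @return data.frame: `neuron_id`, `mouse_id`, `pearson_r`, `p`, `q`, `label`.
#' @export
classify_remapping_neurons <- function(experiment, bin_minutes = 15,
                                       alpha = 0.05, q_threshold = 0.05,
                                       truncate_p = 0.95) {
  m <- consolidation_activity_matrix(experiment, bin_minutes, "all",
                                     truncate_p = truncate_p, scaling = "none")
  if (ncol(m) < 3) stop("fewer than 3 consolidation bins", call. = FALSE)
  centers <- attr(m, "bin_centers_min")
  nt <- neuron_table(experiment)
  res <- t(apply(m, 1, function(x) {
    if (stats::sd(x) == 0) return(c(0, 1))
    ct <- stats::cor.test(centers, x, method = "pearson")
    c(unname(ct$estimate), ct$p.value)
  }))
  q <- bh_fdr(res[, 2])
  label <- ifelse(res[, 2] < alpha & q < q_threshold,
                  ifelse(res[, 1] < 0, "decreasing", "increasing"),
                  "non_remapping")
  data.frame(neuron_id = nt$neuron_id, mouse_id = nt$mouse_id,
             pearson_r = res[, 1], p = res[, 2], q = q, label = label,
             row.names = NULL)
}

#' Mean scaled activity of remapping groups across paradigm periods
#'
#' For each remapping group (decreasing, increasing, non-remapping) reports
#' the mean of the neurons' scaled activity in the learning period (preS and
#' postS averaged), the consolidation period, and the test period. Per-neuron
#' activities are truncated per mouse per period and scaled by each neuron's
#' maximum across the periods; the decreasing and increasing groups are
#' compared per period by bootstrap with Bonferroni correction over the three
#' periods.
#'
#' @param experiment an `abn_experiment`.
#' @param labels a [classify_remapping_neurons()] result covering the
#'   experiment's neurons.
#' @param n_replicates,alpha bootstrap settings.
#' @param truncate_p truncation percentile.
#' @param rng_seed master seed.
#' @return list with `profile` (data.frame `group`, `period`, `mean_activity`,
#'   `n`) and `comparisons` (data.frame per period: estimate, CI,
#'   significance of decreasing - increasing).
#' @export
group_activity_profile <- function(experiment, labels, n_replicates = 10000,
                                   alpha = 0.05, truncate_p = 0.95, rng_seed = 1) {
  nt <- neuron_table(experiment)
  if (!all(nt$neuron_id %in% labels$neuron_id)) {
    stop("labels must cover every neuron of the experiment", call. = FALSE)
  }
  sessions <- c("preS", "postS", "consolidation", "test")
  m <- do.call(cbind, lapply(sessions, function(s)
    window_mean_activity(experiment, s, truncate_p)))
  colnames(m) <- sessions
  m <- scale_neuron_max(m)
  period_values <- cbind(learning = (m[, "preS"] + m[, "postS"]) / 2,
                         consolidation = m[, "consolidation"],
                         test = m[, "test"])
  grp <- labels$label[match(nt$neuron_id, labels$neuron_id)]
  groups <- c("decreasing", "increasing", "non_remapping")
  present <- groups[groups %in% grp]
  absent <- setdiff(groups, present)
  if (length(absent)) {
    warning("empty group(s) omitted: ", paste(absent, collapse = ", "),
            call. = FALSE)
  }
  profile <- do.call(rbind, lapply(present, function(g) {
    sel <- grp == g
    data.frame(group = g, period = colnames(period_values),
               mean_activity = colMeans(period_values[sel, , drop = FALSE]),
               n = sum(sel), row.names = NULL)
  }))
  comparisons <- NULL
  if (all(c("decreasing", "increasing") %in% present)) {
    seeds <- derive_seeds(rng_seed, ncol(period_values))
    comparisons <- do.call(rbind, lapply(seq_len(ncol(period_values)), function(j) {
      bt <- bootstrap_mean_diff(period_values[grp == "decreasing", j],
                                period_values[grp == "increasing", j],
                                n_replicates = n_replicates, alpha = alpha,
                                n_comparisons = ncol(period_values),
                                rng_seed = seeds[j])
      data.frame(period = colnames(period_values)[j], estimate = bt$estimate,
                 ci_low = bt$ci_low, ci_high = bt$ci_high,
                 significant = bt$significant, row.names = NULL)
    }))
  }
  list(profile = profile, comparisons = comparisons)
}

#' Session-similarity clustering within remapping subgroups
#'
#' Repeats the session activity-vector similarity and cluster-significance
#' analysis restricted to the remapping (decreasing + increasing) and
#' non-remapping neuron subsets.
#'
#' @param experiment an `abn_experiment`.
#' @param labels a [classify_remapping_neurons()] result.
#' @param sessions session windows for the vectors (default
#'   `preC`, `preS`, `postS`, `test`).
#' @param n_replicates,alpha,rng_seed passed to [cluster_significance()].
#' @param min_neurons minimum subgroup size; smaller subgroups are skipped
#'   with a warning.
#' @return named list (`remapping`, `non_remapping`) of lists with
#'   `similarity` and `clusters` (or NULL when skipped).
#' @export
subgroup_similarity <- function(experiment, labels,
                                sessions = c("preC", "preS", "postS", "test"),
                                n_replicates = 10000, alpha = 0.05,
                                rng_seed = 1, min_neurons = 2) {
  sets <- list(
    remapping = labels$neuron_id[labels$label %in% c("decreasing", "increasing")],
    non_remapping = labels$neuron_id[labels$label == "non_remapping"]
  )
  seeds <- derive_seeds(rng_seed, length(sets))
  out <- vector("list", length(sets))
  names(out) <- names(sets)
  for (i in seq_along(sets)) {
    ids <- sets[[i]]
    if (length(ids) < min_neurons) {
      warning("subgroup '", names(sets)[i], "' has fewer than ", min_neurons,
              " neurons; skipped", call. = FALSE)
      next
    }
    sub <- subset_experiment(experiment, ids)
    vm <- activity_vector_matrix(sub, as.list(stats::setNames(sessions, sessions)),
                                 scaling = "vector_01")
    out[[i]] <- list(similarity = similarity_matrix(vm),
                     clusters = cluster_significance(vm, n_replicates, alpha,
                                                     rng_seed = seeds[i]))
  }
  out
}
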