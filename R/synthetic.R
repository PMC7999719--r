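#' Configuration of the synthetic-experiment generator
#'
#' Defaults encode the study conditions the pipeline is built for: a sparse
#' population (~1 calcium transient per minute per neuron) whose transients
#' are polyphasic bursts of unitary events aggregating within ~10 s; sessions
#' preC (10 min), preS (10 min), postS (5 min), a 150-min consolidation
#' recording, and test (10 min); a context-responsive subpopulation (~28%)
#' elevated on context exposure, of which a shock-suppressed part (~10%)
#' returns to baseline after the shock; and remapping subpopulations whose
#' consolidation rates cross-fade (decreasing ~16%, increasing ~10%, rate
#' ratio 4x start to end), with the increasing population driving the test
#' session. Baseline rates vary across neurons (lognormal multipliers), which
#' is what makes population vectors of different sessions genuinely similar.
#'
#' @param n_mice number of mice (default 4).
#' @param neurons_per_mouse neurons per mouse (default 24).
#' @param session_durations named vector, seconds.
#' @param base_rate_per_min baseline transient rate (default 1/min).
#' @param rate_heterogeneity_sdlog sd (log scale) of per-neuron baseline-rate
#'   multipliers (default 0.5; 0 disables).
#' @param burst_size_mean mean unitary events per transient (size is
#'   1 + Poisson(mean - 1); default 2).
#' @param burst_spread_s exponential mean of within-burst event offsets,
#'   seconds (default 3; aggregation then decays within ~10 s).
#' @param amp_meanlog,amp_sdlog lognormal amplitude parameters (default 0, 0.3).
#' @param frac_context fraction elevated during context exposure (default 0.28).
#' @param frac_shock_suppressed fraction returning to baseline after shock
#'   (default 0.10; a subset of the context-responsive fraction).
#' @param frac_remap_decreasing,frac_remap_increasing remapping fractions
#'   (defaults 0.16 and 0.10; the decreasing set is context-responsive).
#' @param crossfade_effect rate ratio across the consolidation window
#'   (default 4; 1 = stationary).
#' @param context_rate_mult rate multiplier during context exposure (default 4).
#' @param test_rate_mult test-session multiplier for the increasing
#'   population (default 6).
#' @param test_suppression test-session multiplier for learning-active
#'   (context/decreasing) neurons (default 0.3): retrieval recruits a
#'   different population.
#' @param wake_dwell_s,nrem_dwell_s,rem_dwell_s mean state bout durations.
#' @param p_rem_after_nrem probability a NREM bout is followed by REM
#'   (default 0.25; keeps the REM fraction well under 10%).
#' @param rng_seed integer seed; the generator is fully deterministic given
#'   the config.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_mice = 4,
                             neurons_per_mouse = 24,
                             session_durations = c(preC = 600, preS = 600,
                                                   postS = 300,
                                                   consolidation = 9000,
                                                   test = 600),
                             base_rate_per_min = 1,
                             rate_heterogeneity_sdlog = 0.5,
                             burst_size_mean = 2,
                             burst_spread_s = 3,
                             amp_meanlog = 0, amp_sdlog = 0.3,
                             frac_context = 0.28,
                             frac_shock_suppressed = 0.10,
                             frac_remap_decreasing = 0.16,
                             frac_remap_increasing = 0.10,
                             crossfade_effect = 4,
                             context_rate_mult = 4,
                             test_rate_mult = 6,
                             test_suppression = 0.3,
                             wake_dwell_s = 240, nrem_dwell_s = 360,
                             rem_dwell_s = 60, p_rem_after_nrem = 0.25,
                             rng_seed = 1) {
  cfg <- list(n_mice = n_mice, neurons_per_mouse = neurons_per_mouse,
              session_durations = session_durations,
              base_rate_per_min = base_rate_per_min,
              rate_heterogeneity_sdlog = rate_heterogeneity_sdlog,
              burst_size_mean = burst_size_mean, burst_spread_s = burst_spread_s,
              amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
              frac_context = frac_context,
              frac_shock_suppressed = frac_shock_suppressed,
              frac_remap_decreasing = frac_remap_decreasing,
              frac_remap_increasing = frac_remap_increasing,
              crossfade_effect = crossfade_effect,
              context_rate_mult = context_rate_mult,
              test_rate_mult = test_rate_mult,
              test_suppression = test_suppression,
              wake_dwell_s = wake_dwell_s, nrem_dwell_s = nrem_dwell_s,
              rem_dwell_s = rem_dwell_s, p_rem_after_nrem = p_rem_after_nrem,
              rng_seed = rng_seed)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  assert_scalar_number(cfg$n_mice, "n_mice", lower = 1)
  assert_scalar_number(cfg$neurons_per_mouse, "neurons_per_mouse", lower = 1)
  stopifnot(all(SESSION_LEVELS %in% names(cfg$session_durations)))
  if (any(cfg$session_durations <= 0)) stop("durations must be > 0", call. = FALSE)
  assert_scalar_number(cfg$base_rate_per_min, "base_rate_per_min", lower = 1e-9)
  assert_scalar_number(cfg$crossfade_effect, "crossfade_effect", lower = 1)
  fr <- c(cfg$frac_context, cfg$frac_shock_suppressed,
          cfg$frac_remap_decreasing, cfg$frac_remap_increasing)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$frac_remap_decreasing + cfg$frac_remap_increasing > 1) {
    stop("remapping fractions exceed 1", call. = FALSE)
  }
  if (cfg$frac_remap_decreasing + cfg$frac_shock_suppressed > cfg$frac_context) {
    stop("context-responsive fraction must contain the decreasing and ",
         "shock-suppressed fractions", call. = FALSE)
  }
  invisible(cfg)
}

# Draw one neuron-session event train from a (possibly time-varying) transient
# rate. rate_fun maps seconds -> transients/min; rate_max bounds it (thinning).
draw_session_events <- function(duration, rate_fun, rate_max, cfg) {
  n_cand <- stats::rpois(1, rate_max / 60 * duration)
  if (!n_cand) return(list(times = numeric(0), amplitudes = numeric(0)))
  onsets <- sort(stats::runif(n_cand, 0, duration))
  keep <- stats::runif(n_cand) < rate_fun(onsets) / rate_max
  onsets <- onsets[keep]
  if (!length(onsets)) return(list(times = numeric(0), amplitudes = numeric(0)))
  sizes <- 1L + stats::rpois(length(onsets), max(cfg$burst_size_mean - 1, 0))
  total <- sum(sizes)
  times <- rep(onsets, sizes) + stats::rexp(total, 1 / cfg$burst_spread_s)
  amps <- stats::rlnorm(total, cfg$amp_meanlog, cfg$amp_sdlog)
  inside <- times <= duration
  ord <- order(times[inside])
  list(times = times[inside][ord], amplitudes = amps[inside][ord])
}

# Alternating-bout hypnogram over [0, duration): wake -> NREM -> (REM?) -> ...
generate_hypnogram <- function(duration, cfg) {
  t <- 0; rows <- list(); state <- "wake"
  while (t < duration) {
    dwell <- switch(state,
                    wake = 30 + stats::rexp(1, 1 / cfg$wake_dwell_s),
                    NREM = 30 + stats::rexp(1, 1 / cfg$nrem_dwell_s),
                    REM = 15 + stats::rexp(1, 1 / cfg$rem_dwell_s))
    end <- min(t + dwell, duration)
    rows[[length(rows) + 1]] <- data.frame(start_s = t, end_s = end, state = state)
    t <- end
    state <- switch(state,
                    wake = "NREM",
                    NREM = if (stats::runif(1) < cfg$p_rem_after_nrem) "REM" else "wake",
                    REM = "wake")
  }
  do.call(rbind, rows)
}

# Per-neuron ground-truth groups: counts rounded from the config fractions.
assign_groups <- function(n, cfg) {
  n_dec <- round(cfg$frac_remap_decreasing * n)
  n_inc <- round(cfg$frac_remap_increasing * n)
  n_shock <- round(cfg$frac_shock_suppressed * n)
  n_ctx_extra <- max(round(cfg$frac_context * n) - n_dec - n_shock, 0)
  if (n_dec + n_inc + n_shock + n_ctx_extra > n) {
    stop("infeasible subpopulation fractions for ", n, " neurons", call. = FALSE)
  }
  pool <- sample.int(n)  # random assignment of roles to neuron indices
  grp <- rep("none", n)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  grp[take(n_dec)] <- "decreasing"
  grp[take(n_inc)] <- "increasing"
  grp[take(n_shock)] <- "shock_suppressed"
  grp[take(n_ctx_extra)] <- "context_only"
  grp
}

#' Generate a complete synthetic experiment
#'
#' Events are drawn as a Poisson process of transient onsets at each neuron's
#' session-specific (and, during consolidation, time-varying) rate; each
#' transient is expanded into a polyphasic burst of unitary events with
#' exponentially spread offsets and lognormal amplitudes. Decreasing neurons'
#' consolidation rates decline linearly by the cross-fade factor, increasing
#' neurons' rise symmetrically; context-responsive neurons are elevated during
#' preS (and, unless shock-suppressed, postS); the test session is driven by
#' the increasing population while learning-active neurons are damped. A
#' bout-structured hypnogram covers the consolidation recording. Fully
#' deterministic given the config (which carries the seed).
#'
#' @param config a [generator_config()].
#' @return an `abn_experiment` whose `ground_truth` table holds each neuron's
#'   planted group (`decreasing`, `increasing`, `shock_suppressed`,
#'   `context_only`, `none`), its `context_responsive` flag and its baseline
#'   rate multiplier.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  with_seed(cfg$rng_seed, {
    n <- cfg$n_mice * cfg$neurons_per_mouse
    mouse_ids <- sprintf("m%02d", rep(seq_len(cfg$n_mice),
                                      each = cfg$neurons_per_mouse))
    neuron_ids <- sprintf("%s_n%03d", mouse_ids,
                          rep(seq_len(cfg$neurons_per_mouse), cfg$n_mice))
    grp <- assign_groups(n, cfg)
    base_mult <- if (cfg$rate_heterogeneity_sdlog > 0) {
      stats::rlnorm(n, -cfg$rate_heterogeneity_sdlog^2 / 2,
                    cfg$rate_heterogeneity_sdlog)
    } else rep(1, n)
    ctx <- grp %in% c("decreasing", "shock_suppressed", "context_only")

    ef <- cfg$crossfade_effect
    dur_cons <- cfg$session_durations[["consolidation"]]
    events <- vector("list", n * length(SESSION_LEVELS))
    ix <- 0
    for (i in seq_len(n)) {
      base <- cfg$base_rate_per_min * base_mult[i]
      for (s in SESSION_LEVELS) {
        dur <- cfg$session_durations[[s]]
        mult_flat <- 1
        rate_fun <- NULL
        if (s == "preS" && ctx[i]) mult_flat <- cfg$context_rate_mult
        if (s == "postS" && ctx[i]) {
          mult_flat <- if (grp[i] == "shock_suppressed") 1 else cfg$context_rate_mult
        }
        if (s == "test") {
          mult_flat <- if (grp[i] == "increasing") cfg$test_rate_mult
                       else if (ctx[i]) cfg$test_suppression else 1
        }
        if (s == "consolidation" && grp[i] %in% c("decreasing", "increasing") &&
            ef > 1) {
          hi <- sqrt(ef); lo <- 1 / sqrt(ef)
          from <- if (grp[i] == "decreasing") hi else lo
          to <- if (grp[i] == "decreasing") lo else hi
          rate_fun <- function(t) base * (from + (to - from) * t / dur_cons)
          rate_max <- base * max(from, to)
        }
        if (is.null(rate_fun)) {
          rate_const <- base * mult_flat
          rate_fun <- local({
            r <- rate_const
            function(t) rep(r, length(t))
          })
          rate_max <- rate_const
        }
        tr <- draw_session_events(dur, rate_fun, rate_max, cfg)
        if (length(tr$times)) {
          ix <- ix + 1
          events[[ix]] <- data.frame(mouse_id = mouse_ids[i],
                                     neuron_id = neuron_ids[i],
                                     session = s, time_s = tr$times,
                                     amplitude = tr$amplitudes)
        }
      }
    }
    events <- do.call(rbind, events[seq_len(ix)])
    hyp <- generate_hypnogram(dur_cons, cfg)
    gt <- data.frame(neuron_id = neuron_ids, mouse_id = mouse_ids,
                     group = grp, context_responsive = ctx,
                     base_rate_mult = base_mult, row.names = NULL)
    new_experiment(events, cfg$session_durations, hypnogram = hyp,
                   neurons = data.frame(mouse_id = mouse_ids,
                                        neuron_id = neuron_ids),
                   ground_truth = gt)
  })
}

#' Generate a null experiment (no planted structure)
#'
#' All subpopulation fractions are forced to zero and every effect size —
#' context elevation, test recruitment and suppression, cross-fade, and
#' baseline-rate heterogeneity — to 1 (heterogeneity to 0), so every neuron is
#' a stationary baseline-rate process in every session. The type-I-error
#' harness for the whole pipeline.
#'
#' @param config a [generator_config()]; its structural settings (sizes,
#'   durations, burst and hypnogram parameters, seed) are kept.
#' @return an `abn_experiment` with an all-`none` ground truth.
#' @export
generate_null_experiment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  null_cfg <- config
  null_cfg$frac_context <- 0
  null_cfg$frac_shock_suppressed <- 0
  null_cfg$frac_remap_decreasing <- 0
  null_cfg$frac_remap_increasing <- 0
  null_cfg$crossfade_effect <- 1
  null_cfg$context_rate_mult <- 1
  null_cfg$test_rate_mult <- 1
  null_cfg$test_suppression <- 1
  null_cfg$rate_heterogeneity_sdlog <- 0
  generate_experiment(null_cfg)
}
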