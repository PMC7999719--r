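#' Unitary calcium event train of one neuron in one session
#'
#' Deconvolution of a raw calcium trace decomposes each (possibly polyphasic)
#' transient into unitary events, each with a time and an amplitude. This
#' constructor validates the invariants every downstream statistic relies on:
#' sorted times inside the session, positive amplitudes, matched lengths.
#'
#' @param neuron_id,mouse_id opaque identifiers.
#' @param session session label (`preC`, `preS`, `postS`, `consolidation`, `test`).
#' @param times event times, seconds from session start, nondecreasing.
#' @param amplitudes positive event amplitudes (arbitrary fluorescence units).
#' @param duration session duration in seconds.
#' @return an object of class `event_train`.
#' @export
event_train <- function(neuron_id, mouse_id, session, times, amplitudes, duration) {
  assert_scalar_number(duration, "duration", lower = 1e-9)
  if (!session %in% SESSION_LEVELS) {
    stop("unknown session label '", session, "'", call. = FALSE)
  }
  times <- as.numeric(times)
  amplitudes <- as.numeric(amplitudes)
  if (length(times) != length(amplitudes)) {
    stop("times and amplitudes must have the same length", call. = FALSE)
  }
  if (is.unsorted(times)) stop("event times must be nondecreasing", call. = FALSE)
  if (length(times) && (min(times) < 0 || max(times) > duration)) {
    stop("event times must lie within [0, duration]", call. = FALSE)
  }
  if (any(amplitudes <= 0)) stop("amplitudes must be positive", call. = FALSE)
  structure(
    list(neuron_id = as.character(neuron_id), mouse_id = as.character(mouse_id),
         session = session, times = times, amplitudes = amplitudes,
         duration = duration),
    class = "event_train"
  )
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %s/%s %s: %d events over %.0f s\n",
              x$mouse_id, x$neuron_id, x$session, length(x$times), x$duration))
  invisible(x)
}

#' Bin an event train into amplitude-summed activity
#'
#' Bins are half-open `[t, t + bin_width)` anchored at the session start; each
#' bin holds the sum of amplitudes of the events falling in it, so total
#' in-range amplitude is conserved. An event at exactly `duration` is assigned
#' to the last bin.
#'
#' @param train an [event_train()] or a plain list with `times`/`amplitudes`.
#' @param bin_width bin width, seconds.
#' @param duration series duration, seconds; defaults to the train's session
#'   duration. Events beyond `duration` are an error.
#' @return a `binned_activity` object: list with `values`, `bin_width`, `origin`.
#' @export
bin_events <- function(train, bin_width, duration = train$duration) {
  assert_scalar_number(bin_width, "bin_width", lower = 1e-9)
  assert_scalar_number(duration, "duration", lower = 1e-9)
  times <- train$times
  amps <- train$amplitudes
  if (length(times) && max(times) > duration) {
    stop("events beyond the stated duration", call. = FALSE)
  }
  n_bins <- as.integer(ceiling(duration / bin_width - 1e-9))
  values <- numeric(n_bins)
  if (length(times)) {
    idx <- pmin(floor(times / bin_width) + 1L, n_bins)
    sums <- rowsum(amps, idx)
    values[as.integer(rownames(sums))] <- sums[, 1]
  }
  structure(list(values = values, bin_width = bin_width, origin = 0),
            class = "binned_activity")
}

#' Mean unitary-event activity in a window
#'
#' Amplitude-weighted by default (the sum of unitary-event amplitudes divided
#' by the window length in minutes); set `weighted = FALSE` to count events
#' instead.
#'
#' @param train an [event_train()].
#' @param window numeric `c(t0, t1)`, seconds; events in `[t0, t1)` count.
#' @param weighted sum amplitudes (default) or count events.
#' @return activity rate, units per minute; `>= 0`.
#' @export
mean_event_activity <- function(train, window, weighted = TRUE) {
  if (length(window) != 2 || !all(is.finite(window)) || window[2] <= window[1]) {
    stop("window must be c(t0, t1) with t1 > t0", call. = FALSE)
  }
  inside <- train$times >= window[1] & train$times < window[2]
  total <- if (weighted) sum(train$amplitudes[inside]) else sum(inside)
  total / ((window[2] - window[1]) / 60)
}

#' Circular autocorrelation of binned activity
#'
#' Lag-k value is the Pearson correlation of the binned series with itself
#' rotated circularly by k bins; lag 0 is 1 for any non-constant series. A
#' constant series has no defined correlation and is returned as an all-zero
#' acf flagged `degenerate`.
#'
#' @param binned a [bin_events()] result (or numeric vector, bin width 1 s).
#' @param max_lag largest lag, seconds; must be less than the circular period.
#' @return an `acf_result`: list with `lags` (s), `acf`, `bin_width`,
#'   `degenerate`, plus `fit_tau`/`block_length` slots filled by
#'   [estimate_block_length()].
#' @export
circular_autocorrelation <- function(binned, max_lag) {
  if (is.numeric(binned)) {
    binned <- structure(list(values = as.numeric(binned), bin_width = 1, origin = 0),
                        class = "binned_activity")
  }
  x <- binned$values
  n <- length(x)
  if (n < 2) stop("need at least 2 bins", call. = FALSE)
  assert_scalar_number(max_lag, "max_lag", lower = 0)
  k_max <- floor(max_lag / binned$bin_width + 1e-9)
  if (k_max >= n) stop("max_lag must be below the series circular period", call. = FALSE)
  lags <- (0:k_max) * binned$bin_width
  if (stats::sd(x) == 0) {
    return(structure(list(lags = lags, acf = numeric(k_max + 1),
                          bin_width = binned$bin_width, degenerate = TRUE,
                          fit_tau = NA_real_, block_length = NA_real_),
                     class = "acf_result"))
  }
  rho <- vapply(0:k_max, function(k) {
    if (k == 0) return(1)
    stats::cor(x, c(x[(k + 1):n], x[1:k]))
  }, numeric(1))
  structure(list(lags = lags, acf = rho, bin_width = binned$bin_width,
                 degenerate = FALSE, fit_tau = NA_real_, block_length = NA_real_),
            class = "acf_result")
}

#' Redraw event times uniformly at random (temporal shuffle)
#'
#' Destroys temporal aggregation while conserving the number of events and the
#' multiset of amplitudes; the shuffled train is the null reference against
#' which aggregation (a decaying autocorrelation) is judged.
#'
#' @param train an [event_train()].
#' @param rng_seed integer seed; same seed, same shuffle.
#' @return a shuffled [event_train()].
#' @export
temporal_shuffle <- function(train, rng_seed) {
  n <- length(train$times)
  new_times <- if (n) {
    with_seed(rng_seed, sort(stats::runif(n, 0, train$duration)))
  } else numeric(0)
  event_train(train$neuron_id, train$mouse_id, train$session,
              new_times, train$amplitudes, train$duration)
}

#' Estimate the bootstrap block length from an autocorrelation function
#'
#' Fits `a + b * exp(-lag / tau)` to the positive lags by least squares. The
#' block length is the smallest lag at which the fitted decay has shrunk to
#' within `tolerance` of its asymptote `a` (i.e. `b * exp(-lag/tau) <=
#' tolerance * b`, so `lag = tau * log(1/tolerance)`), rounded up to a whole
#' second. A non-decaying fit (`b <= 0`) or a degenerate acf falls back to
#' `default_block` with a warning.
#'
#' @param acf_result a [circular_autocorrelation()] result.
#' @param tolerance fraction of the decaying amplitude considered negligible
#'   (default 0.05).
#' @param default_block fallback block length, seconds (default 10).
#' @return the `acf_result` with `fit_tau` and `block_length` filled in.
#' @export
estimate_block_length <- function(acf_result, tolerance = 0.05, default_block = 10) {
  stopifnot(inherits(acf_result, "acf_result"))
  assert_scalar_number(tolerance, "tolerance", lower = 1e-6, upper = 0.5)
  fallback <- function(msg) {
    warning("block-length fit failed (", msg, "); using default ",
            default_block, " s", call. = FALSE)
    acf_result$fit_tau <- NA_real_
    acf_result$block_length <- default_block
    acf_result
  }
  if (isTRUE(acf_result$degenerate)) return(fallback("degenerate acf"))
  pos <- acf_result$lags > 0
  lag <- acf_result$lags[pos]
  y <- acf_result$acf[pos]
  if (length(lag) < 4 || stats::sd(y) == 0) return(fallback("flat acf"))
  a0 <- mean(y[lag >= stats::quantile(lag, 0.75)])
  b0 <- max(y[1] - a0, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * exp(-lag / tau),
                      start = list(a = a0, b = b0, tau = max(lag[2], 2)),
                      lower = c(-1, -1, 1e-3), upper = c(1, 2, max(lag) * 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback("no convergence"))
  est <- stats::coef(fit)
  if (est[["b"]] <= 0) return(fallback("non-decaying acf"))
  acf_result$fit_tau <- unname(est[["tau"]])
  acf_result$block_length <- ceiling(acf_result$fit_tau * log(1 / tolerance))
  acf_result
}

#' Population activity and its circular autocorrelation for one session
#'
#' Sums the binned activity of all neurons of an experiment in one session and
#' returns its circular autocorrelation, the input from which the bootstrap
#' block length is estimated.
#'
#' @param experiment an `abn_experiment`.
#' @param session session label (default `consolidation`, the longest recording).
#' @param bin_width acf bin width, seconds (default 1).
#' @param max_lag largest lag, seconds (default 30).
#' @return an `acf_result`.
#' @export
population_autocorrelation <- function(experiment, session = "consolidation",
                                       bin_width = 1, max_lag = 30) {
  dur <- session_duration(experiment, session)
  ev <- experiment$events[experiment$events$session == session, , drop = FALSE]
  pooled <- list(times = ev$time_s[order(ev$time_s)],
                 amplitudes = ev$amplitude[order(ev$time_s)],
                 duration = dur)
  circular_autocorrelation(bin_events(pooled, bin_width, dur), max_lag)
}
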