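test_that("bin_events sums amplitudes into half-open bins and conserves total", {
  b <- bin_events(make_train(c(1, 11), c(2, 3), duration = 20), 10, 20)
  expect_equal(b$values, c(2, 3))

  expect_equal(bin_events(make_train(numeric(0), numeric(0), duration = 30),
                          10, 30)$values, c(0, 0, 0))

  # Boundary: 9.999 stays in bin 1, 10.0 opens bin 2.
  b <- bin_events(make_train(c(9.999, 10.0), c(1, 1), duration = 20), 10, 20)
  expect_equal(b$values, c(1, 1))

  # Conservation on random trains.
  for (s in 1:5) {
    tr <- withr::with_seed(s, make_train(sort(runif(40, 0, 600)),
                                         rexp(40) + 0.1))
    expect_equal(sum(bin_events(tr, 7)$values), sum(tr$amplitudes))
  }

  expect_error(bin_events(make_train(5, 1, duration = 600), 10, duration = 2),
               "beyond")
})

test_that("mean_event_activity is amplitude mass per minute", {
  tr <- make_train(c(10, 50, 100), c(1, 2, 3), duration = 600)
  expect_equal(mean_event_activity(tr, c(0, 120)), 3.0)
  expect_equal(mean_event_activity(tr, c(200, 300)), 0.0)
  expect_equal(mean_event_activity(make_train(10, 0.5), c(0, 30)), 1.0)
  # Count mode available behind the flag.
  expect_equal(mean_event_activity(tr, c(0, 120), weighted = FALSE), 1.5)
  expect_error(mean_event_activity(tr, c(10, 10)), "t1 > t0")
})

test_that("circular autocorrelation matches the rotate-and-correlate oracle", {
  r <- circular_autocorrelation(c(1, 0, 0, 0), 3)
  expect_equal(r$acf, c(1, -1/3, -1/3, -1/3))

  r <- circular_autocorrelation(c(1, 0, 1, 0), 2)
  expect_equal(r$acf[2], -1)
  expect_equal(r$acf[3], 1)

  for (s in 1:25) {
    x <- withr::with_seed(s, rpois(sample(10:50, 1), 2) * rexp(1))
    k <- length(x) - 1
    expect_equal(circular_autocorrelation(x, k)$acf, oracle_circular_acf(x, k),
                 tolerance = 1e-10)
  }
})

test_that("autocorrelation is invariant to affine rescaling and flags constants", {
  x <- withr::with_seed(3, rpois(80, 1.5))
  base <- circular_autocorrelation(x, 20)$acf
  expect_equal(circular_autocorrelation(x + 7, 20)$acf, base, tolerance = 1e-12)
  expect_equal(circular_autocorrelation(x * 3.5, 20)$acf, base, tolerance = 1e-12)

  const <- circular_autocorrelation(rep(2, 50), 10)
  expect_true(const$degenerate)
  expect_true(all(const$acf == 0))
})

test_that("temporal shuffle conserves events, is seed-deterministic, and de-aggregates bursts", {
  tr <- make_train(c(10, 10.5, 11, 300, 300.2), c(5, 4, 3, 2, 1))
  sh <- temporal_shuffle(tr, 42)
  expect_equal(length(sh$times), 5)
  expect_equal(sort(sh$amplitudes), sort(tr$amplitudes))
  expect_true(all(sh$times >= 0 & sh$times < tr$duration))
  expect_identical(temporal_shuffle(tr, 42), sh)
  expect_false(identical(temporal_shuffle(tr, 43)$times, sh$times))

  # Bursty train: mean nearest-neighbour interval grows under shuffling.
  bursty <- make_train(sort(c(100, 100.4, 100.8, 400, 400.3, 400.7)), duration = 600)
  nn <- function(t) mean(diff(t))
  nn_shuf <- vapply(1:1000, function(s) nn(temporal_shuffle(bursty, s)$times),
                    numeric(1))
  expect_gt(mean(nn_shuf), nn(bursty$times))
})

test_that("shuffled trains stay inside the 95% shuffle band of the acf", {
  tr <- withr::with_seed(9, {
    onsets <- sort(runif(25, 0, 590))
    times <- sort(c(onsets, onsets + rexp(25, 1 / 3)))
    make_train(pmin(times, 600), rep(1, 50))
  })
  acf_of <- function(t) circular_autocorrelation(
    bin_events(t, 1), 20)$acf[-1]
  band <- apply(vapply(1:200, function(s) acf_of(temporal_shuffle(tr, s)),
                       numeric(20)), 1, quantile, c(0.025, 0.975))
  probe <- acf_of(temporal_shuffle(tr, 9999))
  outside <- mean(probe < band[1, ] | probe > band[2, ])
  expect_lte(outside, 0.15)  # ~5% expected; slack for 20 lags
})

test_that("block length recovers a known decay constant and falls back when flat", {
  lags <- 0:30
  synth <- structure(list(lags = lags, acf = exp(-lags / 2), bin_width = 1,
                          degenerate = FALSE, fit_tau = NA_real_,
                          block_length = NA_real_), class = "acf_result")
  fit <- estimate_block_length(synth)
  expect_lt(abs(fit$fit_tau - 2) / 2, 0.10)
  expect_equal(fit$block_length, ceiling(fit$fit_tau * log(20)))

  flat <- structure(list(lags = lags, acf = c(1, rep(0.01, 30)), bin_width = 1,
                         degenerate = FALSE, fit_tau = NA_real_,
                         block_length = NA_real_), class = "acf_result")
  # Flat-to-machine-precision acf: no exponential structure to fit.
  flat$acf <- rep(0.2, 31)
  expect_warning(res <- estimate_block_length(flat, default_block = 10), "default")
  expect_equal(res$block_length, 10)
})
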