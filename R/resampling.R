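#' Bootstrap test of a difference in means
#'
#' Resamples each group independently with replacement at its original size,
#' records the difference of resampled means, and reports the percentile
#' confidence interval at the Bonferroni-adjusted level
#' `alpha / n_comparisons`. The difference is judged significant when the
#' interval excludes zero.
#'
#' @param group_a,group_b numeric vectors (analysis units); non-empty.
#' @param n_replicates bootstrap replicates (default 10000).
#' @param alpha nominal level (default 0.05).
#' @param n_comparisons Bonferroni divisor for the family of contrasts this
#'   test belongs to (default 1).
#' @param rng_seed integer seed.
#' @return a `bootstrap_result`: list with `estimate` (observed mean
#'   difference A − B), `ci_low`, `ci_high`, `n_replicates`, `alpha_adjusted`,
#'   `significant`, `degenerate` (TRUE when a group has a single value).
#' @export
bootstrap_mean_diff <- function(group_a, group_b, n_replicates = 10000,
                                alpha = 0.05, n_comparisons = 1, rng_seed = 1) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  assert_scalar_number(n_replicates, "n_replicates", lower = 1)
  assert_scalar_number(alpha, "alpha", lower = 1e-6, upper = 1 - 1e-6)
  assert_scalar_number(n_comparisons, "n_comparisons", lower = 1)
  na <- length(group_a); nb <- length(group_b)
  diffs <- with_seed(rng_seed, {
    ma <- colMeans(matrix(group_a[sample.int(na, na * n_replicates, replace = TRUE)],
                          nrow = na))
    mb <- colMeans(matrix(group_b[sample.int(nb, nb * n_replicates, replace = TRUE)],
                          nrow = nb))
    ma - mb
  })
  finish_bootstrap(mean(group_a) - mean(group_b), diffs, alpha, n_comparisons,
                   degenerate = (na == 1 || nb == 1))
}

finish_bootstrap <- function(estimate, diffs, alpha, n_comparisons, degenerate) {
  adj <- alpha / n_comparisons
  ci <- unname(stats::quantile(diffs, c(adj / 2, 1 - adj / 2), type = 7))
  structure(
    list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
         n_replicates = length(diffs), alpha_adjusted = adj,
         significant = (ci[1] > 0 || ci[2] < 0), degenerate = degenerate),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> estimate %.4g, %.1f%% CI [%.4g, %.4g], %s\n",
              x$estimate, 100 * (1 - x$alpha_adjusted), x$ci_low, x$ci_high,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

# Replicate means of a series rebuilt from overlapping moving blocks (Kuensch
# construction): uniform start positions, no circular wrap, overhang truncated.
block_resample_means <- function(x, block_bins, n_replicates) {
  n <- length(x)
  b <- block_bins
  n_blocks <- ceiling(n / b)
  starts <- sample.int(n - b + 1L, n_blocks * n_replicates, replace = TRUE)
  idx <- rep(starts, each = b) + rep.int(seq_len(b) - 1L, n_blocks * n_replicates)
  idx <- matrix(idx, nrow = n_blocks * b)[seq_len(n), , drop = FALSE]
  colMeans(matrix(x[idx], nrow = n))
}

#' Moving block bootstrap test of a difference in series means
#'
#' For temporally correlated activity series, resampling individual time bins
#' destroys the correlation structure and makes naive bootstrap intervals too
#' narrow. The moving block bootstrap instead rebuilds each series from
#' uniformly drawn, overlapping, contiguous blocks of a fixed length until the
#' original length is reached (overhang truncated), preserving within-block
#' correlations. The statistic is the difference of series means A − B.
#'
#' @param series_a,series_b [bin_events()] results or numeric vectors sharing
#'   one bin width.
#' @param block_length block length in seconds (converted to whole bins; must
#'   be at least one bin and no longer than either series).
#' @param n_replicates,alpha,n_comparisons,rng_seed as in
#'   [bootstrap_mean_diff()].
#' @return a `bootstrap_result` (estimate is the observed mean difference).
#' @details The two series are given internal RNG substreams keyed by a
#'   canonical ordering of their contents rather than their argument position,
#'   so swapping the arguments exactly negates the replicate distribution and
#'   the resulting labels are antisymmetric.
#' @export
moving_block_bootstrap_diff <- function(series_a, series_b, block_length,
                                        n_replicates = 10000, alpha = 0.05,
                                        n_comparisons = 1, rng_seed = 1) {
  get_vals <- function(s) if (inherits(s, "binned_activity")) s else
    structure(list(values = as.numeric(s), bin_width = 1), class = "binned_activity")
  sa <- get_vals(series_a); sb <- get_vals(series_b)
  if (!isTRUE(all.equal(sa$bin_width, sb$bin_width))) {
    stop("series must share a bin width", call. = FALSE)
  }
  assert_scalar_number(block_length, "block_length", lower = sa$bin_width)
  b <- max(1L, as.integer(round(block_length / sa$bin_width)))
  xa <- sa$values; xb <- sb$values
  if (b > length(xa) || b > length(xb)) {
    stop("block longer than a series", call. = FALSE)
  }
  # Canonical order: substream assignment independent of argument position.
  a_first <- series_precedes(xa, xb)
  seeds <- with_seed(rng_seed, sample.int(.Machine$integer.max - 1L, 2))
  seed_a <- if (a_first) seeds[1] else seeds[2]
  seed_b <- if (a_first) seeds[2] else seeds[1]
  ma <- with_seed(seed_a, block_resample_means(xa, b, n_replicates))
  mb <- with_seed(seed_b, block_resample_means(xb, b, n_replicates))
  finish_bootstrap(mean(xa) - mean(xb), ma - mb, alpha, n_comparisons,
                   degenerate = FALSE)
}

# TRUE if x precedes y in a deterministic, position-independent ordering.
series_precedes <- function(x, y) {
  if (length(x) != length(y)) return(length(x) < length(y))
  neq <- which(x != y)
  if (!length(neq)) return(TRUE)
  x[neq[1]] < y[neq[1]]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin, validated wrapper around
#' [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (may be empty).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
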