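#' @keywords internal
"_PACKAGE"

# Session and vigilance-state vocabularies used throughout the pipeline.
SESSION_LEVELS <- c("preC", "preS", "postS", "consolidation", "test")
STATE_LEVELS <- c("wake", "NREM", "REM")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed without disturbing the global stream
#'
#' All stochastic operations in the package funnel through this helper so that
#' identical seeds give bit-identical results and user sessions keep their own
#' RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive n reproducible sub-seeds (< 2^31) from a master seed. Used when an
# operation fans out over neurons so each unit gets an independent stream.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
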