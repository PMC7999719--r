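# Fixture builders shared across the suite. Everything is constructed in code;
# no data files.

# A minimal event train.
make_train <- function(times, amplitudes = rep(1, length(times)),
                       duration = 600, session = "preC") {
  event_train("n1", "m1", session, times, amplitudes, duration)
}

# Hand-built two-neuron experiment with fully controlled event placement.
# events: data.frame(mouse_id, neuron_id, session, time_s, amplitude)
make_experiment <- function(events,
                            durations = c(preC = 600, preS = 600, postS = 300,
                                          consolidation = 9000, test = 600),
                            hypnogram = NULL, neurons = NULL) {
  new_experiment(events, durations, hypnogram = hypnogram, neurons = neurons)
}

# Brute-force circular autocorrelation oracle: rotate and Pearson-correlate.
oracle_circular_acf <- function(x, k_max) {
  n <- length(x)
  vapply(0:k_max, function(k) {
    if (k == 0) return(1)
    rot <- c(x[(k + 1):n], x[seq_len(k)])
    stats::cor(x, rot)
  }, numeric(1))
}

# Naive elementwise cosine oracle (explicit loop over the dot-product formula).
oracle_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

# Small, fast generator configs for tests.
test_config <- function(rng_seed = 1, ...) {
  generator_config(rng_seed = rng_seed, ...)
}
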