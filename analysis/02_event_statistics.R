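#!/usr/bin/env Rscript
# Temporal-aggregation statistics and per-neuron responsiveness:
#  - population circular autocorrelation and the exponential-decay fit that
#    calibrates the bootstrap block length;
#  - moving-block-bootstrap classification of each neuron across the
#    preC->preS and preS->postS transitions, with the resulting fractions;
#  - active-set overlap between the post-shock and test periods.

suppressPackageStartupMessages(library(abnremap))

seed <- 1
data_dir <- "results/data"
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(rng_seed = seed)  # durations must match the simulation
ex <- read_events(file.path(data_dir, "events.tsv"), cfg$session_durations,
                  hypnogram = read_hypnogram(file.path(data_dir, "hypnogram.tsv")))

acf_res <- estimate_block_length(population_autocorrelation(ex))
message(sprintf("acf decay tau = %.2f s -> block length %d s",
                acf_res$fit_tau, acf_res$block_length))
write.table(data.frame(lag_s = acf_res$lags, acf = acf_res$acf),
            file.path(out, "population_acf.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (tr in list(c("preC", "preS"), c("preS", "postS"))) {
  labels <- classify_period_response(ex, tr, block_length = acf_res$block_length,
                                     n_replicates = 10000,
                                     alpha = 0.05 / 2,  # Bonferroni, 2 contrasts
                                     rng_seed = seed + 100)
  fr <- response_fractions(labels)
  message(sprintf("%s -> %s: %.0f%% increase, %.0f%% decrease, %.0f%% no change",
                  tr[1], tr[2], 100 * fr["increase"], 100 * fr["decrease"],
                  100 * fr["no_change"]))
  write.table(labels, file.path(out, sprintf("responsiveness_%s_%s.tsv",
                                             tr[1], tr[2])),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# Active sets per period and their overlap.
nt <- neuron_table(ex)
active_in <- function(session) {
  nt$neuron_id[vapply(nt$neuron_id, function(id) {
    as.logical(classify_active(bin_events(get_event_train(ex, id, session), 10),
                               n_replicates = 10000,
                               rng_seed = seed + match(id, nt$neuron_id)))
  }, logical(1))]
}
act_post <- active_in("postS")
act_test <- active_in("test")
ov <- population_overlap(act_post, act_test, nt$neuron_id)
message(sprintf("active postS %d, active test %d, Jaccard %.2f, hypergeometric p %.3g",
                length(act_post), length(act_test), ov$jaccard, ov$hypergeom_p))
jsonlite::write_json(list(active_postS = act_post, active_test = act_test,
                          overlap = ov),
                     file.path(out, "active_overlap.json"),
                     auto_unbox = TRUE, digits = NA)
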