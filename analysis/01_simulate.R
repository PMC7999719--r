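#!/usr/bin/env Rscript
# Simulate one synthetic fear-conditioning experiment under the default study
# conditions (4 mice x 24 adult-born neurons, ~1 transient/min, 150-min
# consolidation recording with hypnogram) and write the raw tables that every
# later analysis step re-reads through the package's own readers.

suppressPackageStartupMessages(library(abnremap))

seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(rng_seed = seed)
ex <- generate_experiment(cfg)

write_events(ex, file.path(out, "events.tsv"))
write_hypnogram(ex$hypnogram, file.path(out, "hypnogram.tsv"))
write.table(ex$ground_truth, file.path(out, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(unclass(cfg), file.path(out, "generator_config.json"),
                     auto_unbox = TRUE, digits = NA)

gt <- table(ex$ground_truth$group)
message("simulated ", nrow(neuron_table(ex)), " neurons, ",
        nrow(ex$events), " unitary events")
message("planted groups: ", paste(names(gt), gt, sep = "=", collapse = ", "))
message("REM fraction of consolidation: ",
        round(state_fraction(ex$hypnogram, "REM"), 3))
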