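#!/usr/bin/env Rscript
# Population-vector similarity across paradigm periods: activity vectors
# (per-mouse 95th-percentile truncation, 0-1 rescaling), the cosine similarity
# matrix, and Ward clustering with permutation-calibrated significant merges.

suppressPackageStartupMessages(library(abnremap))

seed <- 1
data_dir <- "results/data"
out <- "results"

cfg <- generator_config(rng_seed = seed)
ex <- read_events(file.path(data_dir, "events.tsv"), cfg$session_durations,
                  hypnogram = read_hypnogram(file.path(data_dir, "hypnogram.tsv")))

sessions <- c("preC", "preS", "postS", "test")
vm <- activity_vector_matrix(ex, as.list(setNames(sessions, sessions)),
                             scaling = "vector_01")
sm <- similarity_matrix(vm)
write.table(round(sm, 6), file.path(out, "similarity_matrix.tsv"),
            sep = "\t", quote = FALSE)

cl <- cluster_significance(vm, n_replicates = 10000, alpha = 0.05,
                           rng_seed = seed + 200)
write_dendrogram_newick(cl, file.path(out, "similarity_dendrogram.nwk"))
write.table(data.frame(vector = names(cl$membership),
                       cluster = as.vector(cl$membership)),
            file.path(out, "cluster_membership.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("similarity matrix:")
print(round(sm, 3))
message("significant clusters (family-wise alpha 0.05):")
if (length(cl$significant_clusters)) {
  for (g in cl$significant_clusters) message("  {", paste(g, collapse = ", "), "}")
} else message("  none")
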