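test_that("remapping index hits its analytic anchors and hand value", {
  A <- c(1, 0); C <- c(0, 1)
  expect_equal(as.numeric(remapping_index(A, C, c(1, 0))), 1)
  expect_equal(as.numeric(remapping_index(A, C, c(0, 1))), -1)
  expect_equal(as.numeric(remapping_index(A, C, c(1, 1))), 0)
  expect_equal(as.numeric(remapping_index(A, C, c(2, 1))), 0.6792851,
               tolerance = 1e-6)
  # The printed-equation convention is the exact negation.
  expect_equal(as.numeric(remapping_index(A, C, c(2, 1), "printed")),
               -0.6792851, tolerance = 1e-6)
})

test_that("remapping index is swap-antisymmetric, scale-invariant, bounded", {
  for (s in 1:20) {
    v <- withr::with_seed(s, matrix(runif(30) + 0.01, 10, 3))
    ri <- as.numeric(remapping_index(v[, 1], v[, 2], v[, 3]))
    expect_gte(ri, -1); expect_lte(ri, 1)
    expect_equal(as.numeric(remapping_index(v[, 2], v[, 1], v[, 3])), -ri)
    expect_equal(as.numeric(remapping_index(v[, 1] * 5, v[, 2], v[, 3] * 0.2)),
                 ri, tolerance = 1e-12)
  }
  degen <- remapping_index(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(as.numeric(degen), 0)
  expect_true(attr(degen, "degenerate"))
})

test_that("consolidation matrix bins, scales to per-neuron max, and honors the hypnogram", {
  durations <- c(preC = 600, preS = 600, postS = 300, consolidation = 3600,
                 test = 600)
  hyp <- data.frame(start_s = c(0, 900), end_s = c(900, 3600),
                    state = c("wake", "NREM"))
  # neuron n1: growing activity 1,2,3,4 across the four 15-min bins;
  # neuron n2: events only in bins 2-4 (the sleep bins).
  ev <- rbind(
    data.frame(mouse_id = "m1", neuron_id = "n1", session = "consolidation",
               time_s = c(100, 1000, 1100, 1900, 2000, 2100, 2800, 2900, 3000, 3100),
               amplitude = rep(1, 10)),
    data.frame(mouse_id = "m1", neuron_id = "n2", session = "consolidation",
               time_s = c(1000, 2000, 3000), amplitude = 2))
  ex <- make_experiment(ev, durations = durations, hypnogram = hyp)

  m <- consolidation_activity_matrix(ex, state_filter = "all", truncate_p = NA)
  expect_equal(dim(m), c(2, 4))
  expect_equal(attr(m, "bin_centers_min"), c(7.5, 22.5, 37.5, 52.5))
  expect_equal(unname(m["n1", ]), c(1, 2, 3, 4) / 4)  # peak scaled to 1
  expect_equal(unname(m["n2", ]), c(0, 1, 1, 1))

  msleep <- consolidation_activity_matrix(ex, state_filter = "sleep", truncate_p = NA)
  expect_equal(attr(msleep, "bin_index"), 2:4)  # wake-only first bin dropped
  mwake <- consolidation_activity_matrix(ex, state_filter = "wake", truncate_p = NA)
  expect_equal(attr(mwake, "bin_index"), 1L)

  expect_error(consolidation_activity_matrix(ex, state_filter = "REM"),
               "refused")
})

test_that("crossfade experiments show a strong negative remapping trend in every state", {
  ex <- generate_experiment(test_config(rng_seed = 3))
  tr <- remapping_trace(ex, "all")
  expect_equal(tr$data$ri[1], 1)
  expect_equal(tr$data$ri[nrow(tr$data)], -1)
  expect_lte(tr$pearson_r, -0.9)
  expect_lt(tr$slope, 0)
  expect_lte(remapping_trace(ex, "sleep")$pearson_r, -0.8)
  expect_lte(remapping_trace(ex, "wake")$pearson_r, -0.8)
})

test_that("time-reversing the recording mirrors and negates the RI series", {
  # Reversal swaps the reference bins, so ri_rev(j) = -ri(n+1-j) exactly.
  ex <- generate_experiment(test_config(rng_seed = 4, n_mice = 2,
                                        neurons_per_mouse = 15))
  dur <- session_duration(ex, "consolidation")
  rev_ev <- ex$events
  cons <- rev_ev$session == "consolidation"
  rev_ev$time_s[cons] <- dur - rev_ev$time_s[cons]
  rev_ex <- make_experiment(rev_ev, durations = ex$session_durations,
                            hypnogram = ex$hypnogram, neurons = ex$neurons)
  fwd <- remapping_trace(ex, "all")
  bwd <- remapping_trace(rev_ex, "all")
  expect_equal(bwd$data$ri, -rev(fwd$data$ri), tolerance = 1e-9)
  # Trend statistics negate when the RI series is mirrored in time.
  mirrored <- fwd$data[!fwd$data$is_reference, ]
  ct_f <- cor.test(mirrored$bin_center_min, mirrored$ri)
  ct_b <- cor.test(mirrored$bin_center_min, rev(mirrored$ri))
  expect_equal(unname(ct_b$estimate), -unname(ct_f$estimate), tolerance = 1e-9)
})

test_that("stationary null experiments give calibrated remapping-trend p-values", {
  ps <- vapply(1:30, function(s) {
    ex <- generate_null_experiment(test_config(rng_seed = 700 + s, n_mice = 2,
                                               neurons_per_mouse = 20))
    remapping_trace(ex, "all")$pearson_p
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 5)  # ~1.5 expected of 30 at the nominal rate
})

test_that("classify_remapping_neurons labels trends and handles constants", {
  durations <- c(preC = 600, preS = 600, postS = 300, consolidation = 9000,
                 test = 600)
  mk_bins <- function(counts, id) {
    do.call(rbind, lapply(seq_along(counts), function(b) {
      k <- counts[b]
      if (!k) return(NULL)
      data.frame(mouse_id = "m1", neuron_id = id, session = "consolidation",
                 time_s = (b - 1) * 900 + seq(10, 800, length.out = k),
                 amplitude = 1)
    }))
  }
  ev <- rbind(mk_bins(1:10, "inc"), mk_bins(10:1, "dec"), mk_bins(rep(4, 10), "flat"))
  ex <- make_experiment(ev, durations = durations)
  labels <- classify_remapping_neurons(ex, truncate_p = NA)
  expect_equal(labels$label[labels$neuron_id == "inc"], "increasing")
  expect_equal(labels$label[labels$neuron_id == "dec"], "decreasing")
  expect_equal(labels$label[labels$neuron_id == "flat"], "non_remapping")
  expect_equal(labels$p[labels$neuron_id == "flat"], 1)
  expect_equal(labels$pearson_r[labels$neuron_id == "inc"], 1, tolerance = 1e-9)
})

test_that("planted remapping fractions are recovered and nulls stay quiet", {
  ex <- generate_experiment(test_config(rng_seed = 5, neurons_per_mouse = 25))
  labels <- classify_remapping_neurons(ex)
  fr <- table(factor(labels$label,
                     c("decreasing", "increasing", "non_remapping"))) / nrow(labels)
  expect_lt(abs(fr[["decreasing"]] - 0.16), 0.10)
  expect_lt(abs(fr[["increasing"]] - 0.10), 0.10)
  gt <- ex$ground_truth
  dec_hits <- labels$label[match(gt$neuron_id[gt$group == "decreasing"],
                                 labels$neuron_id)]
  expect_gt(mean(dec_hits == "decreasing"), 0.4)

  null_ex <- generate_null_experiment(test_config(rng_seed = 6,
                                                  neurons_per_mouse = 25))
  null_lab <- classify_remapping_neurons(null_ex)
  expect_lte(mean(null_lab$label != "non_remapping"), 0.05)
})

test_that("group_activity_profile reduces to single-neuron values and reverses order on crossfades", {
  ex <- generate_experiment(test_config(rng_seed = 7, n_mice = 2,
                                        neurons_per_mouse = 10))
  nt <- neuron_table(ex)
  labels <- data.frame(neuron_id = nt$neuron_id,
                       label = c("decreasing", "increasing",
                                 rep("non_remapping", nrow(nt) - 2)))
  prof <- group_activity_profile(ex, labels, n_replicates = 300, rng_seed = 2)
  sessions <- c("preS", "postS", "consolidation", "test")
  m <- do.call(cbind, lapply(sessions, function(s) window_mean_activity(ex, s)))
  colnames(m) <- sessions
  m <- scale_neuron_max(m)
  one <- prof$profile[prof$profile$group == "decreasing", ]
  expect_equal(one$mean_activity[one$period == "learning"],
               unname((m[1, "preS"] + m[1, "postS"]) / 2))
  expect_equal(one$mean_activity[one$period == "test"], unname(m[1, "test"]))

  # Planted crossfade: decreasing group dominates learning, increasing the test.
  ex2 <- generate_experiment(test_config(rng_seed = 8, neurons_per_mouse = 25))
  gt_labels <- data.frame(neuron_id = ex2$ground_truth$neuron_id,
                          label = ifelse(ex2$ground_truth$group %in%
                                           c("decreasing", "increasing"),
                                         ex2$ground_truth$group, "non_remapping"))
  prof2 <- group_activity_profile(ex2, gt_labels, n_replicates = 1000,
                                  rng_seed = 3)
  cmp <- prof2$comparisons
  expect_gt(cmp$estimate[cmp$period == "learning"], 0)
  expect_true(cmp$significant[cmp$period == "learning"])
  expect_lt(cmp$estimate[cmp$period == "test"], 0)
  expect_true(cmp$significant[cmp$period == "test"])
})

test_that("permuted labels rarely yield significant group differences", {
  ex <- generate_experiment(test_config(rng_seed = 9, neurons_per_mouse = 25))
  gt <- ex$ground_truth
  true_lab <- ifelse(gt$group %in% c("decreasing", "increasing"),
                     gt$group, "non_remapping")
  hits <- vapply(1:40, function(s) {
    perm <- withr::with_seed(900 + s, sample(true_lab))
    prof <- suppressWarnings(group_activity_profile(
      ex, data.frame(neuron_id = gt$neuron_id, label = perm),
      n_replicates = 400, rng_seed = 950 + s))
    any(prof$comparisons$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.25)
})

test_that("subgroup similarity restricted to all neurons matches the full analysis", {
  ex <- generate_experiment(test_config(rng_seed = 10, n_mice = 2,
                                        neurons_per_mouse = 12))
  nt <- neuron_table(ex)
  all_remap <- data.frame(neuron_id = nt$neuron_id,
                          label = rep(c("decreasing", "increasing"),
                                      length.out = nrow(nt)))
  sg <- suppressWarnings(subgroup_similarity(ex, all_remap,
                                             n_replicates = 200, rng_seed = 4))
  full <- similarity_matrix(activity_vector_matrix(
    ex, list(preC = "preC", preS = "preS", postS = "postS", test = "test")))
  expect_equal(sg$remapping$similarity, full)
  expect_null(sg$non_remapping)

  # Non-remapping subset of a null experiment: no significant clusters.
  nex <- generate_null_experiment(test_config(rng_seed = 11, n_mice = 2,
                                              neurons_per_mouse = 20))
  nnt <- neuron_table(nex)
  lab <- data.frame(neuron_id = nnt$neuron_id, label = "non_remapping")
  sg2 <- suppressWarnings(subgroup_similarity(nex, lab, n_replicates = 400,
                                              rng_seed = 5))
  expect_length(sg2$non_remapping$clusters$significant_clusters, 0)
})
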