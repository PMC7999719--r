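# Experiment with hand-placed events for exact activity-vector arithmetic:
# 5 neurons in one mouse, one event each in preC with chosen amplitudes.
vector_fixture <- function(amps = c(1, 2, 3, 4, 100), mouse = "m1") {
  n <- length(amps)
  data.frame(mouse_id = mouse, neuron_id = sprintf("%s_n%d", mouse, 1:n),
             session = "preC", time_s = seq(10, by = 10, length.out = n),
             amplitude = amps)
}

test_that("truncation uses the per-mouse interpolated 95th percentile, then min-max", {
  ex <- make_experiment(vector_fixture())
  # events of amplitude a in a 10-min session -> a/10 per min; scale-free checks.
  raw <- window_mean_activity(ex, "preC", truncate_p = NA)
  expect_equal(unname(raw), c(1, 2, 3, 4, 100) / 10)

  trunc <- window_mean_activity(ex, "preC")
  expect_equal(unname(trunc), c(1, 2, 3, 4, 80.8) / 10)  # p95 of 1,2,3,4,100 = 80.8

  v <- build_activity_vector(ex, "preC")
  expect_equal(as.numeric(v), c(0, 1 / 79.8, 2 / 79.8, 3 / 79.8, 1))

  # Re-truncating at the same threshold changes nothing, and the whole
  # computation is a pure function of the raw events.
  expect_true(all(trunc <= quantile(raw, 0.95, type = 7)))
  expect_equal(window_mean_activity(ex, "preC"), trunc)
})

test_that("truncation thresholds are local to each mouse", {
  ex <- make_experiment(rbind(vector_fixture(c(1, 2, 3, 4, 100), "m1"),
                              vector_fixture(c(1, 1, 1, 1, 1), "m2")))
  v <- window_mean_activity(ex, "preC")
  expect_equal(unname(v[6:10]), rep(0.1, 5))  # m2 untouched by m1's outlier
})

test_that("a constant vector is flagged degenerate and zeroed", {
  ex <- make_experiment(vector_fixture(rep(2, 4)))
  v <- build_activity_vector(ex, "preC")
  expect_true(attr(v, "degenerate"))
  expect_true(all(v == 0))
})

test_that("cosine similarity matches the naive dot-product oracle", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(2, 2), c(1, 1)), 1)
  expect_equal(cosine_similarity(1:3, 3:1), 10 / 14)
  for (s in 1:30) {
    ab <- withr::with_seed(s, matrix(runif(2 * sample(2:20, 1)), ncol = 2))
    expect_equal(cosine_similarity(ab[, 1], ab[, 2]),
                 oracle_cosine(ab[, 1], ab[, 2]), tolerance = 1e-12)
    # scale invariance
    expect_equal(cosine_similarity(3.7 * ab[, 1], ab[, 2]),
                 cosine_similarity(ab[, 1], ab[, 2]), tolerance = 1e-12)
  }
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(1:3, 1:4), "equal length")
})

test_that("similarity_matrix is symmetric, unit-diagonal, and oracle-exact", {
  ident <- similarity_matrix(cbind(a = c(1, 2), b = c(2, 4)))
  expect_equal(unname(ident), matrix(1, 2, 2))
  basis <- similarity_matrix(diag(3))
  expect_equal(unname(basis), diag(3))

  m <- withr::with_seed(4, matrix(runif(40), 10, 4,
                                  dimnames = list(NULL, letters[1:4])))
  s <- similarity_matrix(m)
  expect_equal(s, t(s))
  for (i in 1:4) for (j in 1:4) {
    want <- if (i == j) 1 else oracle_cosine(m[, i], m[, j])
    expect_equal(s[i, j], want, tolerance = 1e-12)
  }
  bad <- cbind(ok = c(1, 1), zero = c(0, 0))
  expect_error(similarity_matrix(bad), "zero")
})

test_that("Ward clustering merges near-duplicates first and respects scaling invariance", {
  m <- cbind(a1 = c(10, 1, 1), a2 = c(10.2, 1.1, 1), b1 = c(1, 9, 8),
             b2 = c(1.1, 9.3, 8.1))
  tree <- hierarchical_clustering(similarity_matrix(m))
  first_two <- tree$merge[1:2, ]
  expect_setequal(sort(-as.vector(first_two)), 1:4)  # both first merges join singletons
  expect_true(all(diff(tree$height) >= -1e-12))
  expect_equal(cutree(tree, 2), c(a1 = 1, a2 = 1, b1 = 2, b2 = 2))

  same <- hierarchical_clustering(similarity_matrix(m * 11.3))
  expect_equal(same$height, tree$height, tolerance = 1e-9)

  flat <- hierarchical_clustering(similarity_matrix(cbind(x = c(1, 2), y = c(1, 2),
                                                          z = c(2, 4))))
  expect_equal(flat$height, c(0, 0), tolerance = 1e-7)
})

test_that("cluster_significance recovers planted groups and ignores noise", {
  # Two groups of 3 near-identical vectors in distinct directions.
  base1 <- withr::with_seed(1, runif(60) * c(rep(3, 30), rep(0.2, 30)))
  base2 <- withr::with_seed(2, runif(60) * c(rep(0.2, 30), rep(3, 30)))
  jitter_mat <- withr::with_seed(3, matrix(runif(6 * 60, 0.95, 1.05), 60))
  m <- cbind(g1a = base1, g1b = base1, g1c = base1,
             g2a = base2, g2b = base2, g2c = base2) * jitter_mat
  cl <- cluster_significance(m, n_replicates = 500, rng_seed = 8)
  expect_length(cl$significant_clusters, 2)
  expect_true(any(vapply(cl$significant_clusters,
                         function(x) setequal(x, c("g1a", "g1b", "g1c")),
                         logical(1))))

  # A single duplicated pair among unrelated noise columns.
  noise <- withr::with_seed(5, matrix(runif(60 * 3), 60))
  dup <- withr::with_seed(6, runif(60))
  m2 <- cbind(noise, p1 = dup, p2 = dup * withr::with_seed(7, runif(60, 0.98, 1.02)))
  colnames(m2)[1:3] <- c("x", "y", "z")
  cl2 <- cluster_significance(m2, n_replicates = 500, rng_seed = 9)
  expect_true(any(vapply(cl2$significant_clusters,
                         function(x) setequal(x, c("p1", "p2")), logical(1))))

  expect_error(cluster_significance(m[, 1:2]), "at least 3")
})

test_that("iid noise vectors rarely produce significant clusters", {
  hits <- vapply(1:20, function(s) {
    m <- withr::with_seed(400 + s, matrix(runif(50 * 4), 50,
                                          dimnames = list(NULL, letters[1:4])))
    length(cluster_significance(m, n_replicates = 400,
                                rng_seed = 500 + s)$significant_clusters) > 0
  }, logical(1))
  expect_lte(sum(hits), 4)  # binomial(20, ~0.05) upper bound
})

test_that("dendrograms serialize to Newick", {
  m <- withr::with_seed(1, matrix(runif(30), 10, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))))
  tree <- hierarchical_clustering(similarity_matrix(m))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
})
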