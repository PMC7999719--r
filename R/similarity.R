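#' Per-neuron mean activity over a window, with per-mouse outlier truncation
#'
#' Computes each neuron's mean unitary-event activity over the window, then
#' truncates values above each mouse's 95th percentile (linear-interpolation
#' percentile over that mouse's neurons) to the percentile. Truncation is local
#' to a mouse: an outlier in one animal never alters another animal's values.
#'
#' @param experiment an `abn_experiment`.
#' @param window a session label (whole session) or
#'   `list(session =, t0 =, t1 =)` for a sub-window in seconds.
#' @param truncate_p percentile for truncation (default 0.95); `NA` disables.
#' @return named numeric vector over neurons in roster order.
#' @export
window_mean_activity <- function(experiment, window, truncate_p = 0.95) {
  stopifnot(inherits(experiment, "abn_experiment"))
  if (is.character(window) && length(window) == 1) {
    window <- list(session = window, t0 = 0,
                   t1 = session_duration(experiment, window))
  }
  nt <- neuron_table(experiment)
  vals <- vapply(nt$neuron_id, function(id) {
    tr <- get_event_train(experiment, id, window$session)
    mean_event_activity(tr, c(window$t0, window$t1))
  }, numeric(1))
  names(vals) <- nt$neuron_id
  if (!is.na(truncate_p)) vals <- truncate_by_mouse(vals, nt$mouse_id, truncate_p)
  vals
}

# Truncate values above each mouse's p-th percentile to that percentile
# (quantile type 7, linear interpolation between order statistics).
truncate_by_mouse <- function(values, mouse_ids, p = 0.95) {
  for (m in unique(mouse_ids)) {
    sel <- mouse_ids == m
    q <- stats::quantile(values[sel], p, type = 7, names = FALSE)
    values[sel] <- pmin(values[sel], q)
  }
  values
}

#' Build a population activity vector for one window
#'
#' Arranges per-neuron mean activities (after per-mouse 95th-percentile
#' truncation) into one vector, mice concatenated in fixed id order, and
#' rescales. `vector_01` min-max rescales the whole concatenated vector to
#' `[0, 1]`; `none` leaves truncated activities untouched (per-neuron max
#' scaling across several windows is done by [activity_vector_matrix()]).
#' A constant vector cannot be rescaled and comes back all-zero, flagged.
#'
#' @param experiment an `abn_experiment`.
#' @param window as in [window_mean_activity()].
#' @param scaling `"vector_01"` (default) or `"none"`.
#' @param truncate_p truncation percentile (default 0.95).
#' @return named numeric vector; attribute `degenerate` TRUE when constant.
#' @export
build_activity_vector <- function(experiment, window, scaling = c("vector_01", "none"),
                                  truncate_p = 0.95) {
  scaling <- match.arg(scaling)
  v <- window_mean_activity(experiment, window, truncate_p)
  if (scaling == "vector_01") v <- rescale_01(v)
  v
}

rescale_01 <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) {
    v[] <- 0
    attr(v, "degenerate") <- TRUE
    return(v)
  }
  out <- (v - rng[1]) / diff(rng)
  attr(out, "degenerate") <- FALSE
  out
}

#' Matrix of activity vectors across several windows
#'
#' Columns are windows, rows are neurons in roster order. Truncation is per
#' mouse per window. `vector_01` rescales each column independently (the
#' session-similarity display convention); `neuron_max` divides each row by
#' its maximum across windows so every neuron peaks at 1 (the consolidation
#' time-course convention); all-zero rows stay zero.
#'
#' @param experiment an `abn_experiment`.
#' @param windows list of windows (see [window_mean_activity()]); names label
#'   the columns.
#' @param scaling `"vector_01"` or `"neuron_max"`.
#' @param truncate_p truncation percentile.
#' @return numeric matrix, neurons x windows.
#' @export
activity_vector_matrix <- function(experiment, windows,
                                   scaling = c("vector_01", "neuron_max"),
                                   truncate_p = 0.95) {
  scaling <- match.arg(scaling)
  cols <- lapply(windows, function(w)
    window_mean_activity(experiment, w, truncate_p))
  m <- do.call(cbind, cols)
  colnames(m) <- names(windows) %||%
    vapply(windows, function(w) if (is.character(w)) w else w$session, "")
  if (scaling == "vector_01") {
    m <- apply(m, 2, function(col) as.numeric(rescale_01(col)))
    rownames(m) <- neuron_table(experiment)$neuron_id
  } else {
    m <- scale_neuron_max(m)
  }
  m
}

#' Scale each neuron (row) by its maximum across columns
#'
#' @param m numeric matrix, neurons x windows.
#' @param reference optional matrix supplying the per-row maxima (used to put
#'   state-restricted consolidation matrices on the all-state scale).
#' @return matrix with row maxima of the reference equal to 1 (zero rows stay 0).
#' @export
scale_neuron_max <- function(m, reference = m) {
  mx <- apply(reference, 1, max)
  mx[mx == 0] <- 1
  sweep(m, 1, mx, "/")
}

#' Cosine similarity of two activity vectors
#'
#' The normalized dot product `A.B / (||A|| ||B||)`; scale-invariant and, for
#' nonnegative vectors, in `[0, 1]`. Angular distance is `1 - cosine`.
#'
#' @param a,b numeric vectors of equal length, each with a nonzero norm.
#' @return similarity value.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector",
                               call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Pairwise cosine similarity matrix
#'
#' @param vectors a matrix (columns are activity vectors) or list of vectors.
#' @return symmetric matrix with unit diagonal, labelled from column names.
#' @export
similarity_matrix <- function(vectors) {
  m <- if (is.matrix(vectors)) vectors else do.call(cbind, vectors)
  if (ncol(m) < 2) stop("need at least 2 vectors", call. = FALSE)
  norms <- sqrt(colSums(m^2))
  zero <- norms == 0
  if (any(zero)) {
    stop("zero activity vector(s): ",
         paste(colnames(m)[zero] %||% which(zero), collapse = ", "), call. = FALSE)
  }
  s <- crossprod(m) / tcrossprod(norms)
  s[cbind(seq_len(ncol(m)), seq_len(ncol(m)))] <- 1
  dimnames(s) <- list(colnames(m), colnames(m))
  s
}

#' Agglomerative clustering of a similarity matrix
#'
#' Ward linkage on the angular distance `d = 1 - similarity`, as is
#' conventional for population-vector similarity matrices (Ward on a
#' non-Euclidean distance is a pragmatic, not a geometric, choice).
#'
#' @param sim a [similarity_matrix()].
#' @return an [stats::hclust] tree.
#' @export
hierarchical_clustering <- function(sim) {
  d <- stats::as.dist(pmax(1 - sim, 0))
  stats::hclust(d, method = "ward.D2")
}

#' Resampling-calibrated significant clusters of activity vectors
#'
#' Builds the observed Ward tree, then a reference distribution of linkages:
#' in each replicate every vector's entries are independently permuted across
#' neuron positions (destroying inter-vector correlation while preserving each
#' vector's marginal), and the linkage is recomputed. Each observed merge
#' height is compared with the same-rank null merge heights via a permutation
#' p-value (with the +1 correction), Bonferroni-corrected over the k-1 merges
#' and accepted bottom-up (a merge counts only when every tighter merge below
#' it is also significant), so the family-wise rate of spurious significant
#' clusters stays at or below `alpha`. Clusters are read off by cutting the
#' dendrogram at the largest significant merge.
#'
#' @param vectors matrix with >= 3 columns (activity vectors) or list thereof.
#' @param n_replicates null replicates (default 10000).
#' @param alpha family-wise level (default 0.05).
#' @param rng_seed integer seed.
#' @return a `cluster_result`: list with `tree`, `merge_pvalues`,
#'   `significant_merges`, `threshold` (largest significant height or NA),
#'   `membership` (integer vector over vector labels), `significant_clusters`
#'   (list of label vectors, size >= 2, formed by significant merges),
#'   `n_replicates`, `alpha`.
#' @export
cluster_significance <- function(vectors, n_replicates = 10000, alpha = 0.05,
                                 rng_seed = 1) {
  m <- if (is.matrix(vectors)) vectors else do.call(cbind, vectors)
  k <- ncol(m)
  if (k < 3) stop("need at least 3 vectors", call. = FALSE)
  labels <- colnames(m) %||% paste0("V", seq_len(k))
  colnames(m) <- labels
  tree <- hierarchical_clustering(similarity_matrix(m))
  n_merges <- k - 1
  null_heights <- with_seed(rng_seed, {
    h <- matrix(NA_real_, n_replicates, n_merges)
    for (r in seq_len(n_replicates)) {
      perm <- apply(m, 2, sample)
      h[r, ] <- sort(hierarchical_clustering(similarity_matrix(perm))$height)
    }
    h
  })
  obs <- tree$height  # nondecreasing by construction
  pvals <- vapply(seq_len(n_merges), function(i) {
    (1 + sum(null_heights[, i] <= obs[i])) / (n_replicates + 1)
  }, numeric(1))
  sig <- pvals <= alpha / n_merges
  # Keep only the maximal prefix of significant merges: a merge can only be
  # called significant if every tighter merge below it is. Tight genuine
  # structure lowers all later Ward heights, so upper merges can otherwise be
  # flagged as a knock-on artifact, contradicting a single dendrogram cut.
  first_ns <- match(FALSE, sig, nomatch = n_merges + 1L)
  if (first_ns <= n_merges) sig[first_ns:n_merges] <- FALSE
  threshold <- if (any(sig)) max(obs[sig]) else NA_real_
  membership <- if (any(sig)) {
    stats::cutree(tree, h = threshold)
  } else stats::setNames(seq_len(k), labels)
  sig_clusters <- if (any(sig)) {
    cl <- split(names(membership), membership)
    Filter(function(x) length(x) >= 2, cl)
  } else list()
  structure(
    list(tree = tree, merge_pvalues = pvals, significant_merges = sig,
         threshold = threshold, membership = membership,
         significant_clusters = unname(sig_clusters),
         n_replicates = n_replicates, alpha = alpha),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", length(x$membership), "vectors;",
      sum(x$significant_merges), "significant merges;",
      length(x$significant_clusters), "significant cluster(s)\n")
  invisible(x)
}

#' Serialize a clustering tree as Newick
#'
#' @param tree an [stats::hclust] tree (or a `cluster_result`).
#' @param path output file path.
#' @export
write_dendrogram_newick <- function(tree, path) {
  if (inherits(tree, "cluster_result")) tree <- tree$tree
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
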