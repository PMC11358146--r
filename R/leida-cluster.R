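#' Dunn cluster-validity index
#'
#' Point-based Dunn variant: the minimum Euclidean distance between
#' points of different clusters, divided by the maximum intra-cluster
#' diameter (largest within-cluster pairwise distance). Larger is better.
#' When every cluster has zero diameter (all member points coincide) the
#' separation is infinite and `Inf` is returned with attribute
#' `zero_diameter = TRUE`.
#'
#' @param points Numeric matrix (rows = observations).
#' @param labels Integer cluster labels, one per row; at least two
#'   nonempty clusters.
#' @param d Optional precomputed `dist` object for `points`.
#' @return A nonnegative number (possibly `Inf`).
#' @export
dunn_index <- function(points, labels, d = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("need at least 2 clusters")
  d <- d %||% stats::dist(points)
  if (length(labels) != attr(d, "Size")) abort("labels do not match points")
  pr <- dist_pair_labels(labels)
  same <- pr$i == pr$j
  inter <- min(d[!same])
  intra <- if (any(same)) max(d[same]) else 0
  if (intra == 0) {
    out <- Inf
    attr(out, "zero_diameter") <- TRUE
    return(out)
  }
  inter / intra
}

# labels of both endpoints of every pair in a dist object,
# in dist's storage order (columns i = 1..n-1, rows i+1..n)
dist_pair_labels <- function(labels) {
  n <- length(labels)
  list(
    i = rep(labels[-n], times = (n - 1):1),
    j = labels[sequence((n - 1):1, from = 2:n)]
  )
}

#' Pool leading eigenvectors across subjects and cluster into states
#'
#' All subjects' per-volume leading eigenvectors are stacked and
#' partitioned by k-means (Euclidean distance, `n_restarts` random
#' initialisations, best within-cluster sum of squares kept) for every
#' candidate `k` in `k_min:k_max`. The Dunn index scores each candidate
#' partition and the `k` maximising it is selected. Cluster numbering is
#' made deterministic by relabelling states in order of decreasing size
#' (ties by first occurrence). Assignments are split back per subject in
#' the original volume order.
#'
#' On unit-norm rows, Euclidean k-means is monotone in cosine distance,
#' matching the usual leading-eigenvector clustering convention.
#'
#' @param eigs Named list of per-subject `v1` matrices (as returned by
#'   [leading_eigenvectors()], or the `$v1` components).
#' @param k_min,k_max Candidate state-count range (defaults 5 and 10).
#' @param seed Integer seed; mandatory, every restart derives from it.
#' @param n_restarts k-means restarts per candidate k (default 50).
#' @return An object of class `state_repertoire`: list with `k`,
#'   `centroids` (k x N), `dunn_by_k` (tibble `k, dunn`), `assignments`
#'   (named list of per-subject integer sequences), `sizes`, `seed`,
#'   `n_restarts`.
#' @export
pool_and_cluster <- function(eigs, k_min = 5, k_max = 10, seed,
                             n_restarts = 50) {
  if (missing(seed)) abort("`seed` is required for reproducible clustering")
  stopifnot(k_min >= 2, k_max >= k_min)
  mats <- lapply(eigs, function(e) if (is.list(e)) e$v1 else e)
  if (is.null(names(mats))) names(mats) <- paste0("subject", seq_along(mats))
  pool <- do.call(rbind, mats)
  if (nrow(pool) < k_max) abort("fewer pooled eigenvectors than k_max")
  subj_of_row <- rep(names(mats), vapply(mats, nrow, 1L))

  d <- stats::dist(pool)
  ks <- k_min:k_max
  fits <- vector("list", length(ks))
  dunn <- numeric(length(ks))
  for (i in seq_along(ks)) {
    set.seed(derive_seed(seed, 100 + ks[i]))
    fits[[i]] <- stats::kmeans(pool, centers = ks[i], nstart = n_restarts,
                               iter.max = 200)
    dunn[i] <- dunn_index(pool, fits[[i]]$cluster, d = d)
  }
  best <- which.max(dunn)
  fit <- fits[[best]]
  k <- ks[best]

  # deterministic state numbering: decreasing cluster size
  ord <- order(-fit$size, seq_len(k))
  relab <- integer(k); relab[ord] <- seq_len(k)
  cluster <- relab[fit$cluster]
  centroids <- fit$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("state", seq_len(k))

  structure(list(
    k = k,
    centroids = centroids,
    dunn_by_k = tibble(k = ks, dunn = dunn),
    assignments = split(cluster, factor(subj_of_row, levels = names(mats))),
    sizes = as.integer(table(factor(cluster, levels = seq_len(k)))),
    seed = seed,
    n_restarts = n_restarts
  ), class = "state_repertoire")
}

#' @export
print.state_repertoire <- function(x, ...) {
  cat(sprintf("State repertoire: k = %d states over %d ROIs (%d subjects)\n",
              x$k, ncol(x$centroids), length(x$assignments)))
  cat("Dunn index by candidate k:\n")
  print(as.data.frame(x$dunn_by_k), row.names = FALSE)
  invisible(x)
}

#' @rdname pool_and_cluster
#' @param x A `state_repertoire`.
#' @param ... Unused.
#' @return `tidy()`: a long tibble `state, roi, weight` of centroid
#'   entries; `glance()`: a one-row tibble with `k`, `best_dunn`,
#'   `n_subjects`, `n_pooled`.
#' @method tidy state_repertoire
#' @export
tidy.state_repertoire <- function(x, ...) {
  tibble(
    state = rep(seq_len(x$k), each = ncol(x$centroids)),
    roi = rep(colnames(x$centroids) %||% paste0("roi", seq_len(ncol(x$centroids))),
              times = x$k),
    weight = as.vector(t(x$centroids))
  )
}

#' @rdname pool_and_cluster
#' @method glance state_repertoire
#' @export
glance.state_repertoire <- function(x, ...) {
  tibble(
    k = x$k,
    best_dunn = max(x$dunn_by_k$dunn),
    n_subjects = length(x$assignments),
    n_pooled = sum(lengths(x$assignments))
  )
}
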