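#' Pairwise distance matrix
#'
#' Full symmetric n x n distance matrix between the rows of a points matrix.
#' Euclidean (default) or cosine distance (1 - cosine similarity; an all-zero
#' row has undefined direction and gets cosine distance 1 to every other row).
#'
#' @param points Numeric matrix (n x d), n >= 2, all entries finite.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return n x n numeric matrix with zero diagonal, class `"dist_matrix"`.
#' @export
pairwise_distances <- function(points, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  if (nrow(points) < 2) abort_input("need at least 2 points")
  if (!all(is.finite(points))) abort_input("points matrix contains non-finite values")
  if (metric == "euclidean") {
    d <- as.matrix(dist(points, method = "euclidean"))
  } else {
    nrm <- sqrt(rowSums(points^2))
    zero <- nrm == 0
    nrm[zero] <- 1
    u <- points / nrm
    sim <- tcrossprod(u)
    sim[zero, ] <- 0
    sim[, zero] <- 0
    sim <- pmin(pmax(sim, -1), 1)
    d <- 1 - sim
  }
  diag(d) <- 0
  dimnames(d) <- NULL
  class(d) <- c("dist_matrix", class(d))
  d
}

as_dist_matrix <- function(d) {
  d <- unclass(as.matrix(d))
  if (nrow(d) != ncol(d)) abort_input("distance matrix must be square")
  if (any(d < 0) || !all(is.finite(d))) {
    abort_input("distance matrix must be finite and non-negative")
  }
  if (max(abs(d - t(d))) > 1e-8) abort_input("distance matrix must be symmetric")
  d
}

#' K-distance profile: row-sorted distance matrix
#'
#' Sorts each row of the distance matrix in ascending order. Column 1 is the
#' all-zero self-distance vector; column `k + 1` holds every point's distance
#' to its k-th nearest neighbor.
#'
#' @param d A square symmetric distance matrix (e.g. from
#'   [pairwise_distances()]).
#' @return n x n matrix with non-decreasing rows.
#' @export
kdistance_profile <- function(d) {
  d <- as_dist_matrix(d)
  t(apply(d, 1, sort.int, method = "quick"))
}

#' Epsilon candidate list from K-average nearest-neighbor distances
#'
#' For each neighbor rank k the candidate epsilon is the mean over all points
#' of their k-th nearest-neighbor distance (the K-average nearest-neighbor
#' distance). Because each profile row is sorted, the candidate list is
#' non-decreasing in k. Ranks run 1..n-1: a point has no n-th neighbor
#' distinct from itself.
#'
#' @param profile Matrix from [kdistance_profile()], or a distance matrix
#'   (profiled automatically).
#' @return Tibble: `k`, `eps`.
#' @export
eps_candidates <- function(profile) {
  if (!all(diff(profile[1, ]) >= 0) || any(profile[, 1] != 0)) {
    profile <- kdistance_profile(profile)
  }
  n <- ncol(profile)
  tibble(k = seq_len(n - 1), eps = colMeans(profile[, -1, drop = FALSE]))
}

#' Expected epsilon-neighborhood size (density threshold)
#'
#' For a given epsilon, counts for every point the number of points within
#' epsilon (the point itself included) and returns the mean count — the
#' mathematical expectation of the neighborhood size, used as the DBSCAN
#' density threshold `pmin`. Generally fractional; it is used directly in the
#' core-point test (count >= pmin) without rounding.
#'
#' @param d Distance matrix.
#' @param eps Neighborhood radius, >= 0.
#' @return A single number in `[1, n]`.
#' @export
pmin_expectation <- function(d, eps) {
  d <- as_dist_matrix(d)
  if (eps < 0) abort_config("eps must be >= 0")
  mean(rowSums(d <= eps))
}

#' DBSCAN on a precomputed distance matrix
#'
#' Classical density-based clustering. A point is a core point iff at least
#' `pmin` points (itself included) lie within `eps` of it. Clusters are the
#' connected components of the graph on core points with edges between core
#' pairs within `eps`; a non-core point within `eps` of a core point is a
#' border point and joins the cluster of the lowest-index such core point
#' (deterministic tie-break); everything else is noise.
#'
#' @param d Distance matrix.
#' @param eps Neighborhood radius, >= 0.
#' @param pmin Density threshold, >= 1 (may be fractional).
#' @return Integer label vector: clusters `0..N-1` (numbered by lowest member
#'   index), noise `-1`. Attribute `"core"` is the logical core-point mask.
#' @examples
#' d <- pairwise_distances(cbind(c(0, 1, 3)))
#' dbscan_fit(d, eps = 1, pmin = 2) # 0 0 -1
#' @export
dbscan_fit <- function(d, eps, pmin) {
  d <- as_dist_matrix(d)
  if (eps < 0) abort_config("eps must be >= 0")
  if (pmin < 1) abort_config("pmin must be >= 1")
  n <- nrow(d)
  within <- d <= eps
  core <- rowSums(within) >= pmin
  labels <- rep(-1L, n)
  # flood-fill connected components over core points
  cluster <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    queue <- i
    labels[i] <- cluster
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      nb <- which(within[p, ] & core & labels == -1L)
      labels[nb] <- cluster
      queue <- c(queue, nb)
    }
    cluster <- cluster + 1L
  }
  # border points: lowest-index core neighbor wins
  for (i in seq_len(n)) {
    if (core[i]) next
    cands <- which(within[i, ] & core)
    if (length(cands) > 0) labels[i] <- labels[min(cands)]
  }
  attr(labels, "core") <- core
  labels
}

#' Adaptive DBSCAN parameter search over neighbor ranks
#'
#' The parameter-selection procedure at the heart of the pipeline. For each
#' neighbor rank k (ascending) it sets `eps_k` to the K-average
#' nearest-neighbor distance, `pmin_k` to the expected `eps_k`-neighborhood
#' size, runs DBSCAN, and records the cluster count `C_k`. The first run of
#' `stability_window` consecutive equal counts defines the stable cluster
#' count N; the scan then continues while `C_k == N`, and the optimal rank
#' `k*` is the largest k with `C_k == N` before the first deviation (or the
#' end of the range). The returned solution is the DBSCAN run at `k*`.
#'
#' @param d Distance matrix.
#' @param k_range Integer vector of ranks to scan (default
#'   `1:min(n - 1, 60)`); must lie in `1..n-1`.
#' @param stability_window Number of consecutive equal cluster counts that
#'   defines stability (default 3, >= 2).
#' @return An object of class `"kann_dbscan"`: a list with elements `k`,
#'   `eps`, `pmin`, `n_clusters`, `labels` (noise `-1`), `core`, and `trace`
#'   (tibble `k`, `eps`, `pmin`, `n_clusters`). If no stable run exists the
#'   error condition (class `"complaintlens_no_stable_clustering"`) carries
#'   the trace in its `trace` field.
#' @seealso [kann_dbscan()] for the points-matrix front end, [tidy()],
#'   [glance()], [autoplot.kann_dbscan()].
#' @export
select_parameters <- function(d, k_range = NULL, stability_window = 3L) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (is.null(k_range)) k_range <- seq_len(min(n - 1L, 60L))
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > n - 1) {
    abort_config(paste0("k_range must lie within 1..", n - 1))
  }
  if (stability_window < 2) abort_config("stability_window must be >= 2")
  profile <- kdistance_profile(d)
  cand <- eps_candidates(profile)
  eps_k <- cand$eps[match(k_range, cand$k)]
  trace <- tibble(
    k = k_range,
    eps = eps_k,
    pmin = vapply(eps_k, function(e) pmin_expectation(d, e), double(1)),
    n_clusters = NA_integer_
  )
  runs_labels <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    lab <- dbscan_fit(d, trace$eps[i], max(trace$pmin[i], 1))
    runs_labels[[i]] <- lab
    trace$n_clusters[i] <- n_distinct_clusters(lab)
  }
  sel <- stable_run_end(trace$n_clusters, stability_window)
  if (is.null(sel)) {
    rlang::abort(
      paste0(
        "no stable clustering: no ", stability_window,
        " consecutive equal cluster counts in the scanned k range"
      ),
      class = c("complaintlens_no_stable_clustering", "complaintlens_input_error"),
      trace = trace
    )
  }
  last_idx <- sel$index
  structure(
    list(
      k = trace$k[last_idx],
      eps = trace$eps[last_idx],
      pmin = trace$pmin[last_idx],
      n_clusters = trace$n_clusters[last_idx],
      labels = as.integer(runs_labels[[last_idx]]),
      core = attr(runs_labels[[last_idx]], "core"),
      trace = trace,
      stability_window = as.integer(stability_window),
      n = n
    ),
    class = "kann_dbscan"
  )
}

n_distinct_clusters <- function(labels) {
  length(unique(labels[labels >= 0]))
}

# Stability rule over the scanned cluster counts: the first maximal run of
# >= window consecutive equal counts defines the stable count N; its last
# position (just before the first deviation, or the end of the scan) is the
# selected index. NULL when no such run exists.
stable_run_end <- function(counts, window) {
  r <- rle(counts)
  stable <- which(r$lengths >= window)
  if (length(stable) == 0) {
    return(NULL)
  }
  run <- stable[1]
  list(n_clusters = r$values[run], index = cumsum(r$lengths)[run])
}

#' Cluster points with adaptive-parameter DBSCAN
#'
#' Front end over [pairwise_distances()] plus either [select_parameters()]
#' (the default adaptive search) or a fixed-parameter run: supplying
#' `fixed_k` takes `eps` from that rank's K-average nearest-neighbor distance
#' (or `fixed_eps` when given) and `pmin` from the neighborhood-size
#' expectation, skipping the stability search.
#'
#' @param x Points matrix (rows = objects), or a precomputed square distance
#'   matrix when `precomputed = TRUE`.
#' @param metric Distance metric for the points matrix.
#' @param k_range,stability_window Passed to [select_parameters()].
#' @param fixed_k,fixed_eps Fixed-parameter override; see Details.
#' @param precomputed Treat `x` as a distance matrix.
#' @return A `"kann_dbscan"` object (see [select_parameters()]).
#' @examples
#' pts <- make_blobs(blob_spec(centers = rbind(c(0, 0), c(4, 4)), seed = 1))
#' fit <- kann_dbscan(pts$points)
#' glance(fit)
#' @export
kann_dbscan <- function(x, metric = c("euclidean", "cosine"), k_range = NULL,
                        stability_window = 3L, fixed_k = NULL, fixed_eps = NULL,
                        precomputed = FALSE) {
  d <- if (precomputed) as_dist_matrix(x) else pairwise_distances(x, match.arg(metric))
  if (is.null(fixed_k) && is.null(fixed_eps)) {
    return(select_parameters(d, k_range = k_range, stability_window = stability_window))
  }
  if (is.null(fixed_eps)) {
    cand <- eps_candidates(kdistance_profile(d))
    if (!fixed_k %in% cand$k) abort_config(paste0("fixed_k must lie within 1..", nrow(d) - 1))
    fixed_eps <- cand$eps[cand$k == fixed_k]
  }
  pm <- max(pmin_expectation(d, fixed_eps), 1)
  lab <- dbscan_fit(d, fixed_eps, pm)
  structure(
    list(
      k = if (is.null(fixed_k)) NA_integer_ else as.integer(fixed_k),
      eps = fixed_eps, pmin = pm,
      n_clusters = n_distinct_clusters(lab),
      labels = as.integer(lab), core = attr(lab, "core"),
      trace = tibble(
        k = if (is.null(fixed_k)) NA_integer_ else as.integer(fixed_k),
        eps = fixed_eps, pmin = pm, n_clusters = n_distinct_clusters(lab)
      ),
      stability_window = NA_integer_, n = nrow(d)
    ),
    class = "kann_dbscan"
  )
}

#' @export
print.kann_dbscan <- function(x, ...) {
  cat("Adaptive DBSCAN fit (", x$n, " points)\n", sep = "")
  cat("  k* = ", x$k, ", eps = ", signif(x$eps, 5),
    ", pmin = ", signif(x$pmin, 5), "\n",
    sep = ""
  )
  cat("  clusters: ", x$n_clusters, ", noise points: ",
    sum(x$labels == -1L), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-rank trace of the parameter search
#'
#' @param x A `"kann_dbscan"` object.
#' @param ... Unused.
#' @return Tibble: `k`, `eps`, `pmin`, `n_clusters` — one row per scanned
#'   neighbor rank.
#' @export
tidy.kann_dbscan <- function(x, ...) x$trace

#' One-row summary of an adaptive DBSCAN fit
#'
#' @param x A `"kann_dbscan"` object.
#' @param ... Unused.
#' @return Tibble: `k`, `eps`, `pmin`, `n_clusters`, `n_noise`, `n_points`.
#' @export
glance.kann_dbscan <- function(x, ...) {
  tibble(
    k = x$k, eps = x$eps, pmin = x$pmin,
    n_clusters = x$n_clusters, n_noise = sum(x$labels == -1L), n_points = x$n
  )
}

#' Attach cluster labels to the clustered data
#'
#' @param x A `"kann_dbscan"` object.
#' @param data Optional data frame or matrix the fit was computed from
#'   (`x$n` rows).
#' @param ... Unused.
#' @return Tibble of `data` (if given) with columns `.cluster` (integer,
#'   noise `-1`) and `.core` appended.
#' @export
augment.kann_dbscan <- function(x, data = NULL, ...) {
  out <- if (is.null(data)) {
    tibble(.rownum = seq_len(x$n))
  } else {
    df <- as_tibble(as.data.frame(data))
    if (nrow(df) != x$n) abort_input("data must have one row per clustered point")
    df
  }
  out$.cluster <- x$labels
  out$.core <- x$core
  out
}
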