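test_that("pairwise distances satisfy the metric-matrix invariants", {
  d <- pairwise_distances(rbind(c(0, 0), c(3, 4)))
  expect_equal(d[1, 2], 5) # 3-4-5 triangle
  d2 <- pairwise_distances(rbind(c(1, 1), c(1, 1), c(1, 1)))
  expect_true(all(d2 == 0))

  set.seed(2)
  pts <- matrix(rnorm(18), 6, 3)
  d3 <- pairwise_distances(pts)
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) {
    for (j in 1:6) oracle[i, j] <- sqrt(sum((pts[i, ] - pts[j, ])^2))
  }
  expect_equal(unclass(d3), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(d3), t(unclass(d3)))
  expect_true(all(diag(d3) == 0))
  expect_error(pairwise_distances(rbind(c(0, NA), c(1, 1))), class = "complaintlens_input_error")
})

test_that("cosine distance is bounded, symmetric and zero-safe", {
  pts <- rbind(c(1, 0), c(0, 1), c(2, 0), c(0, 0))
  d <- pairwise_distances(pts, metric = "cosine")
  expect_equal(d[1, 3], 0, tolerance = 1e-12) # parallel vectors
  expect_equal(d[1, 2], 1) # orthogonal
  expect_true(all(d >= 0 & d <= 2))
  expect_true(all(diag(d) == 0))
})

test_that("the k-distance profile sorts each row ascending", {
  d <- pairwise_distances(cbind(c(0, 1, 3)))
  p <- kdistance_profile(d)
  expect_equal(p[, 1], c(0, 0, 0))
  expect_equal(p[, 2], c(1, 1, 2)) # 1-NN distances
  expect_equal(p[, 3], c(3, 2, 3)) # 2-NN distances

  set.seed(9)
  pts <- matrix(runif(30), 10, 3)
  d2 <- pairwise_distances(pts)
  p2 <- kdistance_profile(d2)
  for (i in 1:10) expect_equal(p2[i, ], sort(unclass(d2)[i, ]))
})

test_that("epsilon candidates are the column means and non-decreasing in k", {
  d <- pairwise_distances(cbind(c(0, 1, 3)))
  cand <- eps_candidates(d)
  expect_equal(cand$eps, c(4 / 3, 8 / 3))
  expect_equal(cand$k, c(1, 2))

  set.seed(14)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    d2 <- pairwise_distances(matrix(runif(n * 2), n, 2))
    cand2 <- eps_candidates(d2)
    expect_true(all(diff(cand2$eps) >= -1e-12))
    # brute-force means of the k-th-NN column
    p <- t(apply(unclass(d2), 1, sort))
    expect_equal(cand2$eps, colMeans(p)[-1], ignore_attr = TRUE)
  }
})

test_that("the density threshold is the expected neighborhood size (self included)", {
  d <- pairwise_distances(cbind(c(0, 1, 3)))
  expect_equal(pmin_expectation(d, 1), 5 / 3)
  expect_equal(pmin_expectation(d, 0), 1) # distinct points: only self
  expect_equal(pmin_expectation(d, 3), 3) # eps >= max distance: everyone
  expect_error(pmin_expectation(d, -1), class = "complaintlens_config_error")
})

test_that("dbscan reproduces hand-run labelings and degenerate cases", {
  d <- pairwise_distances(cbind(c(0, 1, 3)))
  lab <- dbscan_fit(d, eps = 1, pmin = 2)
  expect_equal(as.integer(lab), c(0L, 0L, -1L))
  expect_equal(attr(lab, "core"), c(TRUE, TRUE, FALSE))

  dd <- pairwise_distances(matrix(1, 5, 2))
  expect_equal(as.integer(dbscan_fit(dd, eps = 0.1, pmin = 5)), rep(0L, 5))
  expect_error(dbscan_fit(d, eps = 1, pmin = 0.5), class = "complaintlens_config_error")
})

test_that("dbscan core partition equals eps-graph connected components (igraph oracle)", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    d <- pairwise_distances(matrix(runif(n * 2), n, 2))
    eps <- runif(1, 0.05, 0.6)
    pm <- sample(2:5, 1)
    lab <- dbscan_fit(d, eps, pm)
    core <- attr(lab, "core")
    if (!any(core)) {
      expect_true(all(lab == -1L))
      next
    }
    adj <- (unclass(d) <= eps)[core, core, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    expect_true(same_partition(as.integer(lab)[core], as.integer(comp)))
  }
})

test_that("the core partition is invariant under point reordering", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    pts <- matrix(runif(n * 2), n, 2)
    perm <- sample(n)
    d1 <- pairwise_distances(pts)
    d2 <- pairwise_distances(pts[perm, ])
    eps <- runif(1, 0.1, 0.5)
    pm <- sample(2:4, 1)
    l1 <- dbscan_fit(d1, eps, pm)
    l2 <- dbscan_fit(d2, eps, pm)
    c1 <- attr(l1, "core")
    expect_equal(attr(l2, "core"), c1[perm])
    core_ids <- which(c1)
    expect_true(same_partition(
      as.integer(l1)[core_ids],
      as.integer(l2)[match(core_ids, perm)]
    ))
    # noise set likewise invariant
    expect_equal(as.integer(l2) == -1L, (as.integer(l1) == -1L)[perm])
  }
})

test_that("growing eps with pmin fixed never increases the noise count", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    d <- pairwise_distances(matrix(runif(n * 2), n, 2))
    pm <- sample(2:4, 1)
    eps_grid <- sort(runif(5, 0.05, 0.7))
    noise <- vapply(
      eps_grid,
      function(e) sum(dbscan_fit(d, e, pm) == -1L), numeric(1)
    )
    expect_true(all(diff(noise) <= 0))
  }
})

test_that("the stability rule picks the last k of the first stable run", {
  # trace C = (5,3,3,3,3,2): stable count 3, selected index = last 3
  sel <- complaintlens:::stable_run_end(c(5L, 3L, 3L, 3L, 3L, 2L), 3L)
  expect_equal(sel$n_clusters, 3L)
  expect_equal(sel$index, 5L)
  expect_null(complaintlens:::stable_run_end(c(1L, 2L, 3L, 4L), 3L))
  sel2 <- complaintlens:::stable_run_end(c(2L, 2L, 2L), 2L)
  expect_equal(sel2$index, 3L)
})

test_that("identical points give one stable cluster at the largest scanned k", {
  d <- pairwise_distances(matrix(1, 8, 2))
  fit <- select_parameters(d)
  expect_equal(fit$n_clusters, 1L)
  expect_equal(fit$k, 7L) # end of the default range
  expect_true(all(fit$labels == 0L))
})

test_that("planted three-blob data is recovered with its parameters", {
  b <- make_blobs(blob_spec(rbind(c(0, 0), c(1, 0), c(0, 1)),
    points_per_center = 15, sigma = 0.05, seed = 7
  ))
  fit <- kann_dbscan(b$points)
  expect_equal(fit$n_clusters, 3L)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(fit$labels, b$labels), 1)
})

test_that("an unstable trace raises an error carrying the diagnostics", {
  # on this blob draw the count drops 5 -> 3 across k = 1, 2, so a 2-wide
  # window restricted to those ranks can never stabilize
  b <- make_blobs(blob_spec(rbind(c(0, 0), c(1, 0), c(0, 1)), 15, 0.05, seed = 7))
  d <- pairwise_distances(b$points)
  err <- tryCatch(
    select_parameters(d, k_range = 1:2, stability_window = 2),
    error = function(e) e
  )
  expect_s3_class(err, "complaintlens_no_stable_clustering")
  expect_s3_class(err$trace, "tbl_df")
  expect_equal(nrow(err$trace), 2)
  expect_true(length(unique(err$trace$n_clusters)) > 1)
})

test_that("fixed-parameter mode bypasses the search", {
  b <- make_blobs(blob_spec(rbind(c(0, 0), c(1, 0)), 10, 0.05, seed = 3))
  fit <- kann_dbscan(b$points, fixed_k = 5)
  cand <- eps_candidates(pairwise_distances(b$points))
  expect_equal(fit$eps, cand$eps[cand$k == 5])
  expect_equal(fit$k, 5L)
  fit2 <- kann_dbscan(b$points, fixed_eps = 0.5)
  expect_equal(fit2$eps, 0.5)
  expect_equal(fit2$n_clusters, 2L)
})

test_that("tidy/glance/augment expose the fit in broom shape", {
  b <- make_blobs(blob_spec(rbind(c(0, 0), c(2, 2)), 8, 0.05, seed = 1))
  fit <- kann_dbscan(b$points)
  tr <- tidy(fit)
  expect_true(all(c("k", "eps", "pmin", "n_clusters") %in% names(tr)))
  g <- glance(fit)
  expect_equal(g$n_points, 16)
  expect_equal(g$n_clusters, fit$n_clusters)
  aug <- augment(fit, b$points)
  expect_equal(nrow(aug), 16)
  expect_true(all(c(".cluster", ".core") %in% names(aug)))
  expect_error(augment(fit, b$points[-1, ]), class = "complaintlens_input_error")
})
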