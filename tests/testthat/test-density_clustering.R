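test_that("two well-separated blobs yield exactly two clusters (ARI 1)", {
  fx <- make_blobs(1000, rbind(c(0, 0, 0), c(10, 10, 10)), seed = 51)
  fm <- flowpeaks_cluster(fx$m, cluster_params(seed = 7))
  expect_identical(fm$n_clusters, 2L)
  expect_equal(ari(fm$labels, fx$labels), 1)
  # relabeling by size: cluster 1 is the largest
  expect_true(all(diff(fm$cluster_sizes) <= 0))
})

test_that("a single blob collapses to one cluster even with k0 = 20", {
  fx <- make_blobs(3000, rbind(c(0, 0)), seed = 52)
  fm <- flowpeaks_cluster(fx$m, cluster_params(k0 = 20, seed = 3))
  expect_identical(fm$n_clusters, 1L)
})

test_that("k separated blobs match the nearest-true-center oracle partition", {
  for (k in c(3L, 5L)) {
    centers <- matrix(0, k, 3)
    for (i in seq_len(k)) centers[i, ] <- 9 * i * c(1, -1, 1) / sqrt(3)
    fx <- make_blobs(400, centers, seed = 60 + k)
    fm <- flowpeaks_cluster(fx$m, cluster_params(seed = 5))
    # brute-force oracle: assign each point to its nearest true center
    X <- fx$m$values
    d2 <- vapply(seq_len(k), function(i) {
      rowSums(sweep(X, 2L, centers[i, ])^2)
    }, numeric(nrow(X)))
    oracle <- max.col(-d2)
    expect_identical(fm$n_clusters, k)
    expect_equal(ari(fm$labels, oracle), 1)
  }
})

test_that("cluster count is non-increasing in the smoothing parameter h", {
  fx <- make_blobs(600, rbind(c(0, 0), c(4, 0), c(0, 4)), seed = 55)
  counts <- vapply(c(0.5, 1, 2, 4), function(h) {
    flowpeaks_cluster(fx$m, cluster_params(h = h, seed = 13))$n_clusters
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("partitions are invariant to row permutation", {
  fx <- make_blobs(500, rbind(c(0, 0), c(8, 8)), seed = 56)
  fm1 <- flowpeaks_cluster(fx$m, cluster_params(seed = 2))
  set.seed(1); perm <- sample(nrow(fx$m$values))
  m2 <- trait_matrix(fx$m$values[perm, ])
  fm2 <- flowpeaks_cluster(m2, cluster_params(seed = 2))
  expect_equal(ari(fm1$labels[perm], fm2$labels), 1)
})

test_that("clustering is deterministic and stable across seeds on 10-SD blobs", {
  fx <- make_blobs(800, rbind(c(0, 0, 0), c(10, 0, 0)), seed = 57)
  a <- flowpeaks_cluster(fx$m, cluster_params(seed = 4))
  b <- flowpeaks_cluster(fx$m, cluster_params(seed = 4))
  expect_identical(a$labels, b$labels)
  for (s in 1:10) {
    fm <- flowpeaks_cluster(fx$m, cluster_params(seed = s))
    expect_identical(fm$n_clusters, 2L)
  }
})

test_that("assignment reproduces training labels and handles new points", {
  fx <- make_blobs(600, rbind(c(0, 0), c(9, 9)), seed = 58)
  fm <- flowpeaks_cluster(fx$m, cluster_params(seed = 6))
  expect_identical(assign_to_clusters(fm, fx$m), fm$labels)
  # a point at a component mean inherits that component's cluster
  j <- which.max(fm$weights)
  x_at_mean <- fm$means[j, ] * fm$standardization$sd + fm$standardization$mean
  m1 <- trait_matrix(matrix(x_at_mean, 1,
                            dimnames = list(NULL, fm$traits)))
  expect_identical(assign_to_clusters(fm, m1), fm$merge_map[j])
  # column mismatch is a domain error
  bad <- fx$m$values; colnames(bad) <- c("x", "y")
  expect_error(assign_to_clusters(fm, trait_matrix(bad)), "domain error")
  expect_error(flowpeaks_cluster(trait_matrix(fx$m$values[1:5, ]),
                                 cluster_params(k0 = 50, seed = 1)),
               "domain error")
})

test_that("cluster summary reports accurate centroids and unit fractions", {
  fx <- make_blobs(1500, rbind(c(0, 0), c(7, 7)), seed = 59)
  fm <- flowpeaks_cluster(fx$m, cluster_params(seed = 8))
  sm <- cluster_summary(fm, fx$m)
  expect_equal(sum(sm$fractions), 1, tolerance = 1e-9)
  truth <- rbind(c(0, 0), c(7, 7))
  got <- sm$centroids[order(sm$centroids[, 1]), ]
  expect_lt(max(abs(got - truth)), 0.1)
})
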