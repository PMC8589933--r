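test_that("two items merge once at their distance", {
  d <- trace_dist(matrix(c(0, 3, 3, 0), 2))
  tr <- hierarchical_complete(d)
  expect_equal(tr$height, 3)
  expect_equal(tr$size, 2L)
  expect_equal(tr$alpha, 0)  # h(i) = h_max for both leaves
})

test_that("two tight pairs merge low then join high", {
  tr <- hierarchical_complete(two_pairs_dist(0.1, 10))
  expect_equal(tr$height, c(0.1, 0.1, 10))
  ct <- cut_tree(tr, 2)
  expect_equal(ct$labels, c(1L, 1L, 2L, 2L))
  tr2 <- hierarchical_complete(two_pairs_dist(0.01, 10))
  expect_equal(tr2$alpha, mean(1 - 0.01 / 10))
})

test_that("merge heights and partitions match stats::hclust on random matrices", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(8:10, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 4), n)))
    tr <- hierarchical_complete(trace_dist(D))
    hc <- hclust(as.dist(D), method = "complete")
    expect_equal(tr$height, hc$height, tolerance = 1e-12)
    for (k in c(2L, 3L, n - 1L)) {
      a <- cut_tree(tr, k)$labels
      b <- cutree(hc, k)
      expect_equal(outer(a, a, "=="), outer(b, b, "=="),
                   ignore_attr = TRUE)
    }
  }
})

test_that("agglomerative coefficient matches cluster::agnes and its bounds", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    tr <- hierarchical_complete(trace_dist(D))
    expect_gte(tr$alpha, 0); expect_lte(tr$alpha, 1)
    # invariant to uniform distance scaling
    tr5 <- hierarchical_complete(trace_dist(5 * D))
    expect_equal(tr5$alpha, tr$alpha, tolerance = 1e-12)
    ag <- cluster::agnes(as.dist(D), method = "complete")
    expect_equal(tr$alpha, ag$ac, tolerance = 1e-8)
  }
  # all pairwise distances equal: every leaf first merges at h_max
  Deq <- matrix(1, 5, 5); diag(Deq) <- 0
  expect_equal(hierarchical_complete(trace_dist(Deq))$alpha, 0)
  # identical items: h_max = 0 defined as alpha = 0
  expect_equal(hierarchical_complete(trace_dist(matrix(0, 3, 3)))$alpha, 0)
})

test_that("cut_tree covers the boundary cuts and labels by first appearance", {
  set.seed(4)
  D <- as.matrix(dist(matrix(rnorm(6 * 2), 6)))
  tr <- hierarchical_complete(trace_dist(D))
  expect_equal(cut_tree(tr, 6)$labels, 1:6)
  expect_equal(cut_tree(tr, 1)$labels, rep(1L, 6))
  lab <- cut_tree(tr, 3)$labels
  expect_equal(sort(unique(lab)), 1:3)
  expect_equal(lab[1], 1L)  # first appearance ordering
  expect_error(cut_tree(tr, 0), "parameter error")
  expect_error(cut_tree(tr, 7), "parameter error")
})

test_that("silhouette agrees with the cluster package and its conventions", {
  tr <- hierarchical_complete(two_pairs_dist())
  expect_gt(silhouette_precomputed(two_pairs_dist(), cut_tree(tr, 2)), 0.9)
  set.seed(6)
  for (i in 1:10) {
    n <- 10
    D <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_precomputed(trace_dist(D), lab),
                 mean(cluster::silhouette(lab, as.dist(D))[, 3]),
                 tolerance = 1e-10)
  }
  # random labels on a uniform-distance matrix score ~0
  Du <- matrix(1, 12, 12); diag(Du) <- 0
  expect_equal(silhouette_precomputed(trace_dist(Du),
                                      rep(1:3, each = 4)), 0,
               tolerance = 1e-12)
  # k = n - 1 accepted; k = n rejected
  D <- as.matrix(dist(matrix(rnorm(10 * 2), 5)))
  expect_no_error(silhouette_precomputed(trace_dist(D), c(1, 2, 3, 4, 4)))
  expect_error(silhouette_precomputed(trace_dist(D), 1:5), "parameter error")
})

test_that("Davies-Bouldin is zero for duplicated rows and matches the textbook form", {
  m <- rbind(matrix(1:4, 3, 4, byrow = TRUE),
             matrix(c(9, 7, 5, 3), 3, 4, byrow = TRUE))
  lab <- rep(1:2, each = 3)
  expect_equal(davies_bouldin_emd(m, lab), 0)
  expect_equal(davies_bouldin_emd(m, lab, metric = "euclidean"), 0)
  set.seed(17)
  for (i in 1:10) {
    mm <- matrix(rnorm(18 * 5), 18)
    ll <- rep(1:3, each = 6)
    expect_equal(davies_bouldin_emd(mm, ll, metric = "euclidean"),
                 db_euclidean_textbook(mm, ll), tolerance = 1e-10)
  }
  expect_error(davies_bouldin_emd(m, rep(1, 6)), "k >= 2")
  expect_error(davies_bouldin_emd(rbind(m, m), rep(1:2, each = 6),
                                  metric = "euclidean"),
               "coincident")
})

test_that("a degraded labeling raises the EMD Davies-Bouldin index", {
  set.seed(9)
  g <- generate_traces(cells_per = 10L, n_frames = 600L, seed = 12)
  sf <- dft_log_magnitude(normalize_minmax(g$traces), 200)
  planted <- as.integer(factor(g$labels, levels = unique(g$labels)))
  db_planted <- davies_bouldin_emd(sf, planted)
  merged <- planted
  merged[merged == 2L] <- 1L                # merge two distinct clusters
  merged[seq(1, 40, by = 7)] <- 4L          # and splatter noise
  db_merged <- davies_bouldin_emd(sf, merged)
  expect_gt(db_merged, db_planted)
})

test_that("silhouette maxima select the planted number of clusters", {
  g4 <- generate_traces(cells_per = 8L, n_frames = 3000L, seed = 5)
  sf <- dft_log_magnitude(normalize_minmax(g4$traces), 1000)
  d <- pairwise_distances(sf, "emd")
  tr <- hierarchical_complete(d)
  expect_equal(as.integer(select_k_silhouette(tr, d, 2:8)), 4L)

  g2 <- generate_traces(default_archetypes()[c(1, 4)], cells_per = 10L,
                        n_frames = 3000L, seed = 6)
  sf2 <- dft_log_magnitude(normalize_minmax(g2$traces), 1000)
  d2 <- pairwise_distances(sf2, "emd")
  tr2 <- hierarchical_complete(d2)
  expect_equal(as.integer(select_k_silhouette(tr2, d2, 2:8)), 2L)
  expect_equal(as.integer(select_k_silhouette(tr2, d2, 5L)), 5L)
  expect_error(select_k_silhouette(tr2, d2, integer(0)), "parameter error")
})

test_that("linkage trees convert to hclust and validate input", {
  D <- as.matrix(dist(matrix(rnorm(12), 6)))
  tr <- hierarchical_complete(trace_dist(D))
  hc <- as.hclust(tr)
  expect_s3_class(hc, "hclust")
  expect_setequal(hc$order, 1:6)
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(trace_dist(bad), "symmetric")
  expect_error(trace_dist(matrix(c(0, -1, -1, 0), 2)), "non-negative")
})
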