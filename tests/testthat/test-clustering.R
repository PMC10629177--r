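test_that("agglomerative clustering recovers forced structures", {
  # diag-1 / off-diag-0 at k = n gives singletons
  m <- diag(6)
  expect_equal(sort(unique(agglomerative_from_similarity(m, 6)$labels)), 0:5)

  # perfect 2-block similarity at k = 2 recovers the blocks
  bl <- make_block_sim(c(4, 3))
  res <- agglomerative_from_similarity(bl, 2)
  expect_equal(ari(attr(bl, "labels"), res$labels), 1)
  expect_s3_class(res, "clustering_result")
  expect_equal(res$k, 2L)

  # perfect blocks with 10:1 imbalance still attain ARI 1
  bl10 <- make_block_sim(c(30, 10, 3))
  expect_equal(ari(attr(bl10, "labels"),
                   agglomerative_from_similarity(bl10, 3)$labels), 1)

  expect_error(agglomerative_from_similarity(matrix(runif(9), 3, 3), 2),
               "symmetric")
})

test_that("agglomerative partitions match a brute-force average-linkage oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    k <- sample(2:(n - 2), 1)
    got <- agglomerative_from_similarity(m, k)$labels
    want <- oracle_avg_linkage(1 - m, k)
    expect_equal(ari(want, got), 1)
  }
})

test_that("dendrogram cuts at k and k+1 are nested", {
  set.seed(32)
  m <- matrix(runif(400), 20, 20)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  for (k in 2:6) {
    a <- agglomerative_from_similarity(m, k)$labels
    b <- agglomerative_from_similarity(m, k + 1)$labels
    # each finer cluster lies inside exactly one coarser cluster
    expect_true(all(tapply(a, b, function(v) length(unique(v))) == 1))
  }
})

test_that("k-means and spectral variants recover separated structures", {
  set.seed(33)
  pts <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  truth <- rep(1:2, each = 20)
  km <- cluster_variants(pts, 2, "KM", seed = 1)
  expect_equal(ari(truth, km$labels), 1)
  expect_equal(km$method, "KM")

  bl <- make_block_sim(c(12, 8))
  sc <- cluster_variants(bl, 2, "SC", seed = 1)
  expect_equal(ari(attr(bl, "labels"), sc$labels), 1)
  expect_error(cluster_variants(pts, 41, "KM"), "exceeds")
})

test_that("silhouette sweep estimates k on block matrices and breaks ties small", {
  bl <- make_block_sim(c(6, 5, 4))
  expect_equal(estimate_num_clusters(bl), 3)
  flat <- make_block_sim(c(12), between = 0.5)  # constant off-diagonal
  flat[] <- 0.5; diag(flat) <- 1
  expect_equal(estimate_num_clusters(flat), 2)  # k_min wins all ties
  expect_error(estimate_num_clusters(make_block_sim(c(2, 1))), "at least 4")

  # mean_silhouette agrees with the textbook definition on a tiny case
  d <- as.matrix(dist(c(0, 0.1, 1, 1.1)))
  lab <- c(1, 1, 2, 2)
  a <- c(0.1, 0.1, 0.1, 0.1)
  b <- c(mean(c(1, 1.1)), mean(c(0.9, 1)), mean(c(1, 0.9)), mean(c(1.1, 1)))
  expect_equal(mean_silhouette(d, lab), mean((b - a) / pmax(a, b)),
               tolerance = 1e-12)
})

test_that("cluster labels are permutation-insensitive downstream", {
  set.seed(34)
  m <- make_block_sim(c(7, 6, 5), within = 0.9, between = 0.1)
  res <- agglomerative_from_similarity(m, 3)
  relab <- c(17, 5, 99)[res$labels + 1]
  expect_equal(ari(attr(m, "labels"), relab),
               ari(attr(m, "labels"), res$labels))
})
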