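test_that("simulated counts honour the spec and are deterministic", {
  spec <- synthetic_spec(n_cells = 60, n_genes = 300, k = 3,
                         n_marker_genes_per_cluster = 40,
                         proportions = c(0.5, 0.3, 0.2), seed = 7)
  sim <- simulate_counts(spec)
  expect_s3_class(sim$expr, "expr_matrix")
  expect_equal(dim(sim$expr), c(60L, 300L))
  expect_true(all(sim$expr >= 0) && all(is.finite(sim$expr)))
  expect_equal(as.integer(table(sim$labels)), c(30L, 18L, 12L))
  expect_identical(names(sim$labels), rownames(sim$expr))

  sim2 <- simulate_counts(spec)
  expect_identical(unclass(sim$expr), unclass(sim2$expr))

  expect_error(simulate_counts(
    synthetic_spec(n_cells = 20, k = 2, proportions = c(0.96, 0.04),
                   n_genes = 300, n_marker_genes_per_cluster = 10)),
    "infeasible")
  expect_error(synthetic_spec(k = 1), "k")
  expect_error(synthetic_spec(proportions = c(0.5, 0.2), k = 2), "sum to 1")
  expect_error(synthetic_spec(dropout_rate = 1), "dropout_rate")
})

test_that("default separation gives kernel-space silhouette >= 0.5; dropout degrades it", {
  sils <- vapply(1:10, function(sd) {
    sim <- simulate_counts(synthetic_spec(n_cells = 60, n_genes = 1000, k = 2,
                                          dropout_rate = 0, seed = sd))
    s <- kernel_embedding(sim$expr)
    mean_silhouette(1 - unclass(s) / tanh(1), sim$labels)
  }, numeric(1))
  expect_true(all(sils >= 0.5))

  heavy <- vapply(1:3, function(sd) {
    sim <- simulate_counts(synthetic_spec(n_cells = 60, n_genes = 1000, k = 2,
                                          dropout_rate = 0.9, seed = sd))
    s <- kernel_embedding(sim$expr)
    mean_silhouette(1 - unclass(s) / tanh(1), sim$labels)
  }, numeric(1))
  light <- sils[1:3]
  expect_true(all(heavy < light))
})

test_that("marker strength is a monotone difficulty knob for the full pipeline", {
  med_ari <- vapply(c(0.5, 2, 4), function(lfc) {
    median(vapply(1:5, function(sd) {
      sim <- simulate_counts(synthetic_spec(n_cells = 80, n_genes = 800,
                                            k = 3, log_fold_change = lfc,
                                            seed = sd))
      run <- run_pipeline(sim$expr, labels = sim$labels, k = 3, seed = sd)
      run$metrics$ari
    }, numeric(1)))
  }, numeric(1))
  # weakly increasing in the log fold change
  expect_true(all(diff(med_ari) >= -1e-8))
  expect_gt(med_ari[3], med_ari[1])
})

test_that("regime fixtures match the published shapes", {
  fx <- paper_regime_fixtures(c("biase_like", "yan_like"))
  expect_equal(nrow(fx$biase_like$expr), 56)
  expect_equal(length(unique(fx$biase_like$labels)), 4)
  expect_equal(nrow(fx$yan_like$expr), 90)
  expect_equal(length(unique(fx$yan_like$labels)), 7)
  cls <- table(fx$yan_like$labels)
  expect_equal(as.integer(max(cls) / min(cls)), 10)

  # bit-exact reproducibility
  fx2 <- paper_regime_fixtures("yan_like")
  expect_identical(unclass(fx$yan_like$expr), unclass(fx2$yan_like$expr))

  tenx <- paper_regime_fixtures("tenx_like")$tenx_like
  expect_equal(nrow(tenx$expr), 3000)
  expect_equal(length(unique(tenx$labels)), 5)
  expect_gt(mean(tenx$expr == 0), 0.5)  # droplet-like sparsity
})
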