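# small, well-separated kernel-like similarity used across these tests
sep_sim <- function(sizes = c(12, 8), within = 0.7, between = 0.15, seed = 40) {
  set.seed(seed)
  m <- make_block_sim(sizes, within, between)
  noise <- matrix(rnorm(length(m), sd = 0.02), nrow(m))
  m <- m + (noise + t(noise)) / 2
  diag(m) <- tanh(1)
  m <- pmin(pmax(m, 0), tanh(1))
  class(m) <- c("kernel_matrix", class(matrix()))
  m
}

test_that("pseudo-labels recover block structure and are equivariant", {
  s <- sep_sim(c(12, 8))
  pl <- derive_pseudo_labels(s, 2)
  expect_equal(ari(attr(s, "labels"), pl), 1)
  expect_error(derive_pseudo_labels(s, 1), "k0")
  expect_error(derive_pseudo_labels(s, 20), "k0")

  # k0 = n - 1 leaves exactly one pair sharing a label
  pl2 <- derive_pseudo_labels(s, nrow(s) - 1)
  expect_equal(sort(table(pl2), decreasing = TRUE)[[1]], 2)
  expect_equal(length(unique(pl2)), nrow(s) - 1)

  pp <- sample(nrow(s))
  sp <- unclass(s)[pp, pp]
  class(sp) <- class(s)
  plp <- derive_pseudo_labels(sp, 2)
  expect_equal(ari(pl[pp], plp), 1)
})

test_that("pair generation respects counts, validity and determinism", {
  labels <- c("A", "A", "B", "B")
  cfg <- siamese_config(pairs_per_cell = 2, positive_fraction = 0.5, seed = 5)
  ps <- generate_pairs(labels, cfg)
  expect_true(all(ps$i != ps$j))
  expect_true(all((labels[ps$i] == labels[ps$j]) == (ps$y == 1)))
  expect_equal(sum(ps$y == 1), 4)   # 1 positive per cell
  expect_equal(sum(ps$y == 0), 4)
  expect_identical(generate_pairs(labels, cfg), ps)  # same seed, same pairs

  expect_error(generate_pairs(c("A", "A", "A"), cfg), "one class")
  expect_error(generate_pairs(c("A", "B", "C"), cfg), "singleton")

  # approximately pairs_per_cell * n pairs on a larger instance
  labs <- rep(1:3, times = c(10, 8, 6))
  cfg3 <- siamese_config(pairs_per_cell = 10, seed = 1)
  ps3 <- generate_pairs(labs, cfg3)
  expect_equal(nrow(ps3), 10 * length(labs))
  expect_equal(mean(ps3$y), 0.5, tolerance = 1e-12)
})

test_that("compiled LSTM forward matches a plain-R oracle", {
  s <- sep_sim(c(6, 5), seed = 41)
  cfg <- siamese_config(hidden_units = 4, dense_units = 3,
                        embed_mode = "chunked", chunk_width = 3, seed = 2)
  x <- scLSTM:::row_sequences(s, cfg)
  w <- scLSTM:::with_seed(2, scLSTM:::init_weights(dim(x)[1], cfg))
  e_cpp <- scLSTM:::sclstm_embed_cpp(x, w)
  e_r <- oracle_lstm_embed(x, w)
  expect_equal(e_cpp, e_r, tolerance = 1e-12)

  p_cpp <- scLSTM:::sclstm_score_cpp(e_cpp, w)
  for (pair in list(c(1, 2), c(3, 9), c(11, 4))) {
    expect_equal(p_cpp[pair[1], pair[2]],
                 oracle_pair_score(e_cpp[pair[1], ], e_cpp[pair[2], ], w),
                 tolerance = 1e-12)
  }
})

test_that("training separates within-class from between-class pairs", {
  s <- sep_sim(c(12, 8))
  truth <- attr(s, "labels")
  cfg <- siamese_config(epochs = 25, seed = 3, pairs_per_cell = 8)
  pairs <- generate_pairs(truth, cfg)
  fit <- train_siamese(s, pairs, cfg)

  # loss strictly decreases from first to final epoch on separable input
  expect_lt(fit$epoch_losses[length(fit$epoch_losses)], fit$epoch_losses[1])

  m <- score_all_pairs(fit, s)
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(diag(m) == 1))
  expect_gte(min(m), 0); expect_lte(max(m), 1)
  w <- outer(truth, truth, "=="); diag(w) <- NA
  within <- mean(m[w & !is.na(w)]); between <- mean(m[!w & !is.na(w)])
  expect_gt(within, between)
  expect_gte(within - between, 0.2)  # separation property at silhouette >= 0.5

  # deterministic retraining: bit-identical similarity
  fit2 <- train_siamese(s, pairs, cfg)
  expect_identical(score_all_pairs(fit2, s), m)

  # single-branch embedding: shape, determinism, identical rows collapse
  e <- embed_single_branch(fit, s)
  expect_equal(dim(e), c(nrow(s), cfg$hidden_units))
  s2 <- unclass(s); s2[2, ] <- s2[1, ]; s2[, 2] <- s2[, 1]
  class(s2) <- class(s)
  e2 <- embed_single_branch(fit, s2)
  expect_equal(e2[1, ], e2[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("two cells yield a single symmetrised off-diagonal value", {
  s <- matrix(c(tanh(1), 0.3, 0.3, tanh(1)), 2, 2)
  class(s) <- c("kernel_matrix", class(matrix()))
  cfg <- siamese_config(hidden_units = 4, dense_units = 3, seed = 1)
  x <- scLSTM:::row_sequences(s, cfg)
  w <- scLSTM:::with_seed(1, scLSTM:::init_weights(dim(x)[1], cfg))
  model <- structure(list(weights = w, config = cfg, n = 2,
                          epoch_losses = NA_real_, seq_dim = dim(x)[1:2],
                          cell_ids = NULL),
                     class = "sclstm_model")
  m <- score_all_pairs(model, s)
  expect_identical(m[1, 2], m[2, 1])
  expect_equal(unname(diag(m)), c(1, 1))
  expect_gte(m[1, 2], 0); expect_lte(m[1, 2], 1)
})

test_that("untrained scorer is deterministic and unconstrained pre-symmetrization", {
  s <- sep_sim(c(5, 5), seed = 44)
  cfg <- siamese_config(hidden_units = 8, seed = 9)
  x <- scLSTM:::row_sequences(s, cfg)
  w <- scLSTM:::with_seed(9, scLSTM:::init_weights(dim(x)[1], cfg))
  e <- scLSTM:::sclstm_embed_cpp(x, w)
  p1 <- scLSTM:::sclstm_score_cpp(e, w)
  p2 <- scLSTM:::sclstm_score_cpp(e, w)
  expect_identical(p1, p2)
  # f(i,j) and f(j,i) may differ before symmetrization
  expect_false(isTRUE(all.equal(p1, t(p1))))
})
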