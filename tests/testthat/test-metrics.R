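test_that("nmi matches hand-computable cases", {
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(nmi(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)    # relabeling invariant
  expect_equal(nmi(c(0, 0, 1, 1), c(5, 5, 5, 5)), 0)    # constant prediction
  # independent partitions: joint is uniform, mutual information 0
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_error(nmi(1:3, 1:4), "length")
})

test_that("hungarian assignment equals brute force on random costs", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    cost <- matrix(round(runif(n * n), 3), n, n)
    m1 <- solve_assignment(cost)
    m2 <- oracle_assignment_brute(cost)
    expect_equal(sum(cost[cbind(seq_len(n), m1)]),
                 sum(cost[cbind(seq_len(n), m2)]), tolerance = 1e-12)
    expect_setequal(m1, seq_len(n))
  }
})

test_that("clustering accuracy equals exhaustive-mapping brute force", {
  expect_equal(clustering_acc(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(clustering_acc(c(1, 1, 2, 2), c(7, 7, 7, 7)), 0.5)
  set.seed(22)
  for (rep in 1:30) {
    n <- 30
    t <- sample(1:3, n, replace = TRUE)
    p <- sample(1:4, n, replace = TRUE)
    expect_equal(clustering_acc(t, p), oracle_acc_brute(t, p),
                 tolerance = 1e-12)
  }
})

test_that("ari matches Eq-style hand values and the pair-counting oracle", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(23)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    t <- sample(seq_len(sample(2:5, 1)), n, replace = TRUE)
    p <- sample(seq_len(sample(2:5, 1)), n, replace = TRUE)
    expect_equal(ari(t, p), oracle_ari_pairs(t, p), tolerance = 1e-12)
  }
})

test_that("bas covers binary TPR/TNR and the macro-recall extension", {
  expect_equal(bas(c(1, 1, 1, 0), c(1, 1, 1, 0)), 1)
  # TPR = 2/3 for class 1, TNR = 1 for class 0 -> 5/6
  expect_equal(bas(c(1, 1, 1, 0), c(1, 0, 1, 0)), 5 / 6)
  expect_equal(bas(c(0, 0, 1, 1), c(0, 0, 0, 0)), 0.5)  # constant, balanced
  expect_error(bas(c(0, 0, 1, 1), c(9, 9, 9, 9)), "map")
  # NA (unmatched predicted class after mapping) counts as an error
  expect_equal(bas(c(0, 0, 1, 1), c(0, NA, 1, 1)), 0.75)
})

test_that("hungarian_map relabels predictions onto the reference set", {
  t <- c("a", "a", "b", "b", "c")
  p <- c(2, 2, 3, 3, 1)
  expect_identical(hungarian_map(t, p), c("a", "a", "b", "b", "c"))
  # more predicted than true classes: the extra class maps to NA
  t2 <- c(1, 1, 2, 2)
  p2 <- c(1, 3, 2, 2)
  mp <- hungarian_map(t2, p2)
  expect_true(any(is.na(mp)))
  expect_equal(bas(t2, mp), mean(c(1 / 2, 1)))
})

test_that("all metrics are invariant to consistent relabeling", {
  set.seed(24)
  for (rep in 1:10) {
    n <- 40
    t <- sample(1:4, n, replace = TRUE)
    p <- sample(1:3, n, replace = TRUE)
    # random injective relabelings
    tr <- c(10, 20, 30, 40)[t]
    pr <- c("x", "y", "z")[p]
    expect_equal(ari(t, p), ari(tr, pr), tolerance = 1e-12)
    expect_equal(nmi(t, p), nmi(tr, pr), tolerance = 1e-12)
    expect_equal(clustering_acc(t, p), clustering_acc(tr, pr),
                 tolerance = 1e-12)
  }
  t <- sample(1:3, 30, replace = TRUE)
  expect_equal(evaluate_clustering(t, t),
               list(ari = 1, nmi = 1, acc = 1, bas = 1))
})
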