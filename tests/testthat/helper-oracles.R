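# Independent oracles: naive, literal implementations used only to check the
# package's vectorised/compiled code paths. They deliberately share no code
# with R/.

# literal scalar-loop implementation of the four kernel stages
oracle_kernel <- function(a) {
  n <- nrow(a); m <- ncol(a)
  l <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) l[i, j] <- log(a[i, j] + 1)
  inner <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (g in seq_len(m)) acc <- acc + l[i, g] * l[j, g]
    inner[i, j] <- acc
  }
  imin <- min(inner); imax <- max(inner)
  upd <- matrix(0, n, n)
  if (imax > imin) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      upd[i, j] <- (inner[i, j] - imin) / (imax - imin)
    }
  }
  s <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- upd[i, j]
    s[i, j] <- (exp(x) - exp(-x)) / (exp(x) + exp(-x))
  }
  s
}

# pair-counting adjusted Rand index: enumerate all C(n,2) pairs
oracle_ari_pairs <- function(t, p) {
  n <- length(t)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- t[i] == t[j]; sp <- p[i] == p[j]
    if (st && sp) n11 <- n11 + 1
    else if (st && !sp) n10 <- n10 + 1
    else if (!st && sp) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (n11 + n10) * (n11 + n01) / tot
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == exp_idx) return(1)
  (n11 - exp_idx) / (max_idx - exp_idx)
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# clustering accuracy by exhaustive search over one-to-one label mappings
oracle_acc_brute <- function(t, p) {
  tl <- unique(t); pl <- unique(p)
  s <- max(length(tl), length(pl))
  best <- 0
  pm <- perms(s)
  for (r in seq_len(nrow(pm))) {
    # mapping: predicted class q -> true class pm[r, q] (dummy if > kt)
    agree <- 0
    for (q in seq_along(pl)) {
      ti <- pm[r, q]
      if (ti <= length(tl)) {
        agree <- agree + sum(p == pl[q] & t == tl[ti])
      }
    }
    best <- max(best, agree)
  }
  best / length(t)
}

# minimum-cost assignment by brute force over permutations
oracle_assignment_brute <- function(cost) {
  n <- nrow(cost)
  pm <- perms(n)
  costs <- apply(pm, 1, function(pr) sum(cost[cbind(seq_len(n), pr)]))
  pm[which.min(costs), ]
}

# naive average-linkage agglomeration on a distance matrix, cut at k
oracle_avg_linkage <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < best[1]) best <- c(dd, a, b)
      }
    }
    a <- best[2]; b <- best[3]
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
  }
  labels <- integer(n)
  for (cl in seq_along(clusters)) labels[clusters[[cl]]] <- cl
  labels
}

# plain-R LSTM forward + head, literal loops over time steps; independent of
# the compiled path
oracle_lstm_embed <- function(x, w) {
  # x: d x T x n array; returns n x H final hidden states
  sig <- function(z) 1 / (1 + exp(-z))
  h_dim <- ncol(w$U)
  n <- dim(x)[3]; tt <- dim(x)[2]
  out <- matrix(0, n, h_dim)
  for (cell in seq_len(n)) {
    h <- numeric(h_dim); cc <- numeric(h_dim)
    for (t in seq_len(tt)) {
      z <- w$W %*% x[, t, cell, drop = FALSE] + w$U %*% h + w$b
      i <- sig(z[1:h_dim])
      f <- sig(z[(h_dim + 1):(2 * h_dim)])
      g <- tanh(z[(2 * h_dim + 1):(3 * h_dim)])
      o <- sig(z[(3 * h_dim + 1):(4 * h_dim)])
      cc <- f * cc + i * g
      h <- o * tanh(cc)
    }
    out[cell, ] <- h
  }
  out
}

oracle_pair_score <- function(e_i, e_j, w) {
  sig <- function(z) 1 / (1 + exp(-z))
  a1 <- sig(w$W1 %*% c(e_i, e_j) + w$b1)
  as.numeric(sig(w$W2 %*% a1 + w$b2))
}

# block similarity matrix: within-block `within`, between `between`, diag 1
make_block_sim <- function(sizes, within = 1, between = 0) {
  labels <- rep(seq_along(sizes), sizes)
  m <- outer(labels, labels, function(a, b) ifelse(a == b, within, between))
  diag(m) <- 1
  rownames(m) <- colnames(m) <- paste0("cell_", seq_along(labels))
  attr(m, "labels") <- labels
  m
}

# strip class and dimnames for raw numeric comparison
bare <- function(m) {
  m <- unclass(m)
  dimnames(m) <- NULL
  m
}
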