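#' Configuration of the siamese LSTM pair scorer
#'
#' Hyperparameters of the twin-LSTM similarity learner. The published
#' architecture fixes the wiring (two weight-sharing LSTM branches; head =
#' concatenate, two dense layers, two sigmoid layers) but leaves sizes,
#' epochs and optimiser free; the defaults here are sized so a 200-cell data
#' set trains in seconds on one CPU.
#'
#' @param hidden_units LSTM state size.
#' @param dense_units width of the first head dense layer.
#' @param epochs training epochs.
#' @param batch_size pairs per gradient step.
#' @param learning_rate Adam step size.
#' @param pairs_per_cell sampled training pairs per cell.
#' @param positive_fraction fraction of same-class pairs, in (0, 1).
#' @param seed master seed (weight init, pair sampling, shuffling).
#' @param n_repeats independent training runs (seeds `seed..seed+n-1`); the
#'   run whose learned similarity has the best unsupervised silhouette is
#'   kept.
#' @param embed_mode how a kernel row becomes an LSTM sequence:
#'   `"row_as_sequence"` (length-n sequence of scalars), `"chunked"`
#'   (`ceiling(n/w)` steps of width `w = chunk_width`), or `"auto"`
#'   (row_as_sequence for n <= 32, chunked otherwise).
#' @param chunk_width step width for chunked mode.
#' @param loss_tol early-stopping tolerance: training stops once the epoch
#'   mean binary cross-entropy falls to this value (0 disables).
#' @return A `siamese_config` list.
#' @export
siamese_config <- function(hidden_units = 32, dense_units = 16, epochs = 100,
                           batch_size = 32, learning_rate = 3e-3,
                           pairs_per_cell = 10, positive_fraction = 0.5,
                           seed = 0, n_repeats = 2,
                           embed_mode = c("auto", "row_as_sequence", "chunked"),
                           chunk_width = 16, loss_tol = 0.02) {
  embed_mode <- match.arg(embed_mode)
  for (nmv in c("hidden_units", "dense_units", "epochs", "batch_size",
                "learning_rate", "pairs_per_cell", "chunk_width", "n_repeats")) {
    check_that(get(nmv) > 0, sprintf("`%s` must be positive", nmv))
  }
  check_that(positive_fraction > 0 && positive_fraction < 1,
             "`positive_fraction` must be in (0, 1)")
  check_that(loss_tol >= 0, "`loss_tol` must be >= 0")
  structure(list(hidden_units = as.integer(hidden_units),
                 dense_units = as.integer(dense_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 pairs_per_cell = as.integer(pairs_per_cell),
                 positive_fraction = positive_fraction,
                 seed = as.integer(seed), n_repeats = as.integer(n_repeats),
                 embed_mode = embed_mode,
                 chunk_width = as.integer(chunk_width),
                 loss_tol = loss_tol),
            class = "siamese_config")
}

# kernel rows -> LSTM input sequences, as a d x T x n array.
# The similarity values are standardised (global mean/sd of S) before
# sequencing: raw kernel rows are all-positive with small relative
# differences, which leaves the two branch states nearly identical and the
# optimiser on a long plateau at the base-rate loss. Zero padding of the
# tail chunk is then neutral.
row_sequences <- function(s, cfg) {
  s <- unclass(s)
  sdev <- stats::sd(s)
  s <- if (sdev > 0) (s - mean(s)) / sdev else s - mean(s)
  n <- nrow(s)
  mode <- cfg$embed_mode
  if (mode == "auto") mode <- if (n <= 32) "row_as_sequence" else "chunked"
  if (mode == "row_as_sequence") {
    d <- 1L; tt <- n
  } else {
    d <- min(cfg$chunk_width, n); tt <- ceiling(n / d)
  }
  x <- array(0, dim = c(d, tt, n))
  for (cell in seq_len(n)) {
    row <- s[cell, ]
    length(row) <- d * tt          # zero-pad the tail chunk
    row[is.na(row)] <- 0
    x[, , cell] <- row
  }
  x
}

#' Pseudo-labels for pair supervision
#'
#' When no true labels are available, training pairs are built from a
#' provisional partition: agglomerative clustering (average linkage on
#' `1 - S` with `S` rescaled to `[0, 1]`) of the kernel matrix at `k0`
#' classes. These labels supervise pair generation only.
#'
#' @param s a `kernel_matrix` (or similarity in `[0, 1]`).
#' @param k0 number of pseudo-classes, `2 <= k0 <= n - 1`.
#' @return Integer label vector `0..k0-1`, named by cell id.
#' @export
derive_pseudo_labels <- function(s, k0) {
  n <- nrow(s)
  check_that(k0 >= 2 && k0 <= n - 1, sprintf("`k0` must be in [2, %d]", n - 1))
  agglomerative_from_similarity(s, k0)$labels
}

#' Sample same/different training pairs
#'
#' Draws about `pairs_per_cell * n` index pairs: for each cell,
#' `round(pairs_per_cell * positive_fraction)` partners from its own class
#' (skipped for singleton classes) and the remainder from other classes.
#' Deterministic given `cfg$seed`.
#'
#' @param labels class labels (true or pseudo).
#' @param cfg a [siamese_config()].
#' @return A `pair_set` data frame with columns `i`, `j` (1-based cell
#'   indices, `i != j`) and `y` (1 same class, 0 different).
#' @export
generate_pairs <- function(labels, cfg) {
  n <- length(labels)
  check_that(n >= 2, "need at least 2 cells")
  f <- as.integer(factor(labels))
  counts <- tabulate(f)
  check_that(length(counts) >= 2,
             "only one class: no negative pairs can be formed")
  if (all(counts < 2)) {
    stop("all classes are singletons: no positive pairs can be formed",
         call. = FALSE)
  }
  npos_per <- round(cfg$pairs_per_cell * cfg$positive_fraction)
  nneg_per <- cfg$pairs_per_cell - npos_per
  # index-safe sampling (avoids the sample(length-1 vector) pitfall); samples
  # with replacement only when fewer candidates than requested
  sample_from <- function(v, size) {
    v[sample.int(length(v), size, replace = length(v) < size)]
  }
  pairs <- with_seed(cfg$seed, {
    res_i <- integer(0); res_j <- integer(0); res_y <- integer(0)
    idx_by_class <- split(seq_len(n), f)
    for (i in seq_len(n)) {
      own <- setdiff(idx_by_class[[f[i]]], i)
      other <- seq_len(n)[f != f[i]]
      if (length(own) > 0 && npos_per > 0) {
        res_i <- c(res_i, rep(i, npos_per))
        res_j <- c(res_j, sample_from(own, npos_per))
        res_y <- c(res_y, rep(1L, npos_per))
      }
      if (length(other) > 0 && nneg_per > 0) {
        res_i <- c(res_i, rep(i, nneg_per))
        res_j <- c(res_j, sample_from(other, nneg_per))
        res_y <- c(res_y, rep(0L, nneg_per))
      }
    }
    data.frame(i = res_i, j = res_j, y = res_y)
  })
  class(pairs) <- c("pair_set", class(pairs))
  pairs
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_weights <- function(d, cfg) {
  h <- cfg$hidden_units; du <- cfg$dense_units
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1            # forget-gate bias opens the memory path
  list(W = glorot(4 * h, d), U = glorot(4 * h, h), b = b,
       W1 = glorot(du, 2 * h), b1 = numeric(du),
       W2 = glorot(1, du), b2 = 0)
}

#' Train the twin-LSTM pair scorer
#'
#' Both branches share one set of LSTM weights; the head concatenates the two
#' final hidden states and applies dense -> sigmoid -> dense -> sigmoid to a
#' scalar score, trained with binary cross-entropy and Adam.
#'
#' @param s `kernel_matrix` (each cell's kernel row is the branch input).
#' @param pairs a `pair_set` from [generate_pairs()].
#' @param cfg a [siamese_config()].
#' @return An `sclstm_model` with the learned weights, the per-epoch training
#'   losses and the sequence layout.
#' @export
train_siamese <- function(s, pairs, cfg = siamese_config()) {
  check_that(nrow(pairs) > 0, "`pairs` is empty")
  n <- nrow(s)
  check_that(max(pairs$i, pairs$j) <= n, "pair indices exceed the matrix size")
  x <- row_sequences(s, cfg)
  w0 <- with_seed(cfg$seed, init_weights(dim(x)[1], cfg))
  fit <- sclstm_train_cpp(x, pairs$i - 1L, pairs$j - 1L, as.numeric(pairs$y),
                          w0, cfg$epochs, cfg$batch_size, cfg$learning_rate,
                          cfg$seed + 1L, cfg$loss_tol)
  structure(list(weights = fit$weights,
                 epoch_losses = as.numeric(fit$epoch_losses),
                 config = cfg, n = n, seq_dim = dim(x)[1:2],
                 cell_ids = rownames(s)),
            class = "sclstm_model")
}

#' @export
print.sclstm_model <- function(x, ...) {
  cat(sprintf("<sclstm_model> n = %d, hidden = %d, %d epochs (loss %.4f -> %.4f)\n",
              x$n, x$config$hidden_units, length(x$epoch_losses),
              x$epoch_losses[1], x$epoch_losses[length(x$epoch_losses)]))
  invisible(x)
}

check_model_matches <- function(model, s) {
  check_that(inherits(model, "sclstm_model"), "`model` must be an sclstm_model")
  check_that(nrow(s) == model$n,
             sprintf("model was trained on n = %d cells, matrix has %d",
                     model$n, nrow(s)))
}

#' Score every cell pair with a trained model
#'
#' The raw scorer `f(i, j)` need not be symmetric; the learned similarity is
#' symmetrised as `M_ij = (f(i,j) + f(j,i)) / 2` with the diagonal forced to
#' 1 (a cell is maximally similar to itself).
#'
#' @param model an `sclstm_model`.
#' @param s the `kernel_matrix` the model was trained on.
#' @return A `learned_similarity` matrix, symmetric with entries in `[0, 1]`
#'   and unit diagonal.
#' @export
score_all_pairs <- function(model, s) {
  check_model_matches(model, s)
  x <- row_sequences(s, model$config)
  e <- sclstm_embed_cpp(x, model$weights)
  p <- sclstm_score_cpp(e, model$weights)
  m <- (p + t(p)) / 2
  diag(m) <- 1
  dimnames(m) <- list(rownames(s), rownames(s))
  class(m) <- c("learned_similarity", class(matrix()))
  m
}

#' @export
print.learned_similarity <- function(x, ...) {
  cat(sprintf("<learned_similarity> %d x %d, off-diagonal range [%.4f, %.4f]\n",
              nrow(x), ncol(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' Per-cell embedding from a single LSTM branch
#'
#' Support for the single-branch ablation variant: each cell's kernel row is
#' run through one (trained) LSTM branch and its final hidden state is
#' returned as the cell's feature vector.
#'
#' @inheritParams score_all_pairs
#' @return Numeric matrix, n x hidden_units, rows named by cell id.
#' @export
embed_single_branch <- function(model, s) {
  check_model_matches(model, s)
  x <- row_sequences(s, model$config)
  e <- sclstm_embed_cpp(x, model$weights)
  rownames(e) <- rownames(s)
  colnames(e) <- paste0("h", seq_len(ncol(e)))
  e
}
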