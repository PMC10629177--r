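#' External clustering validation metrics
#'
#' Four external indices comparing a predicted partition `p` with a reference
#' partition `t` of the same cells:
#' \describe{
#'   \item{`nmi`}{normalised mutual information `2 I(T,P) / (H(T) + H(P))`
#'     with plug-in entropies (natural log; the ratio is base-invariant).}
#'   \item{`clustering_acc`}{fraction of cells whose predicted label matches
#'     the true label after the optimal one-to-one relabelling of predicted
#'     classes, found with the Hungarian algorithm on the negated contingency
#'     table (rectangular tables are zero-padded square).}
#'   \item{`ari`}{adjusted Rand index from pair counts over the contingency
#'     table — 1 for identical partitions up to relabelling, ~0 for
#'     independent random labelings, can be negative.}
#'   \item{`bas`}{balanced accuracy: `(TPR + TNR)/2` for two classes, and its
#'     standard multiclass generalisation — the unweighted mean of per-class
#'     recall — otherwise. Predictions must already carry labels from the
#'     reference label set (use [hungarian_map()] first); `NA` predictions
#'     (classes left unmatched by the mapping) count as errors.}
#' }
#'
#' @param t reference labels (any atomic type).
#' @param p predicted labels, same length.
#' @return A number: `nmi`, `clustering_acc`, `bas` in `[0, 1]`; `ari` in
#'   `[-1, 1]`.
#' @examples
#' nmi(c(0, 0, 1, 1), c(1, 1, 0, 0))          # 1: same partition
#' ari(c(1, 1, 2, 2), c(1, 2, 1, 2))          # -0.5
#' clustering_acc(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: permutation mapped away
#' @export
nmi <- function(t, p) {
  ct <- contingency(t, p)
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  ht <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hp <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (ht + hp == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  2 * mi / (ht + hp)
}

contingency <- function(t, p) {
  check_that(length(t) == length(p),
             sprintf("label vectors differ in length (%d vs %d)",
                     length(t), length(p)))
  check_that(length(t) >= 1, "empty label vectors")
  table(factor(t), factor(p))
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' O(n^3) shortest-augmenting-path implementation for a square cost matrix.
#'
#' @param cost square numeric cost matrix.
#' @return Integer vector `match` with `match[i]` the column assigned to row
#'   `i` (a permutation of `1:n`).
#' @export
solve_assignment <- function(cost) {
  check_that(is.matrix(cost) && nrow(cost) == ncol(cost) && all(is.finite(cost)),
             "`cost` must be a finite square matrix")
  n <- nrow(cost)
  # arrays are 1-offset: index j+1 holds column j, column 0 is virtual
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) match[p[j + 1]] <- j
  match
}

# optimal one-to-one map predicted class -> true class maximising agreement;
# returns a named character vector (NA for predicted classes left unmatched)
hungarian_class_map <- function(ct) {
  kt <- nrow(ct); kp <- ncol(ct)
  s <- max(kt, kp)
  cost <- matrix(0, s, s)
  cost[seq_len(kp), seq_len(kt)] <- -t(unclass(ct))  # rows: predicted classes
  match <- solve_assignment(cost)
  map <- rep(NA_character_, kp)
  for (jp in seq_len(kp)) {
    it <- match[jp]
    if (it <= kt) map[jp] <- rownames(ct)[it]
  }
  stats::setNames(map, colnames(ct))
}

#' @rdname nmi
#' @export
clustering_acc <- function(t, p) {
  ct <- contingency(t, p)
  map <- hungarian_class_map(ct)
  mapped <- map[as.character(p)]
  sum(!is.na(mapped) & mapped == as.character(t)) / length(t)
}

#' Map predicted labels onto the reference label set
#'
#' Applies the Hungarian-optimal one-to-one relabelling used by
#' [clustering_acc()]. Predicted classes without a true-class partner (when
#' the prediction has more classes than the reference) become `NA` and are
#' counted as errors by [bas()].
#'
#' @inheritParams nmi
#' @return `p` relabelled into `t`'s label set (character, `NA` for unmatched
#'   classes).
#' @export
hungarian_map <- function(t, p) {
  map <- hungarian_class_map(contingency(t, p))
  unname(map[as.character(p)])
}

#' @rdname nmi
#' @export
ari <- function(t, p) {
  ct <- contingency(t, p)
  n <- sum(ct)
  check_that(n >= 2, "ARI needs at least 2 samples")
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial and equal
  (sum_ij - expected) / (max_index - expected)
}

#' @rdname nmi
#' @param p_mapped predictions already mapped onto `t`'s label set.
#' @export
bas <- function(t, p_mapped) {
  check_that(length(t) == length(p_mapped),
             sprintf("label vectors differ in length (%d vs %d)",
                     length(t), length(p_mapped)))
  t <- as.character(t)
  p <- as.character(p_mapped)
  stray <- setdiff(p[!is.na(p)], t)
  if (length(stray) > 0) {
    stop(sprintf(paste0("predicted labels not in the reference label set (%s); ",
                        "map them first with hungarian_map() or use ",
                        "evaluate_clustering()"),
                 paste(utils::head(stray, 3), collapse = ", ")), call. = FALSE)
  }
  classes <- unique(t)
  recalls <- vapply(classes, function(cl) {
    idx <- t == cl
    sum(!is.na(p[idx]) & p[idx] == cl) / sum(idx)
  }, numeric(1))
  mean(recalls)
}

#' All four metrics at once
#'
#' @inheritParams nmi
#' @return Named list with `ari`, `nmi`, `acc`, `bas`.
#' @export
evaluate_clustering <- function(t, p) {
  list(ari = ari(t, p),
       nmi = nmi(t, p),
       acc = clustering_acc(t, p),
       bas = bas(t, hungarian_map(t, p)))
}
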