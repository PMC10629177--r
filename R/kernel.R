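#' Improved sigmoid-kernel cell-cell similarity
#'
#' The kernel embedding maps a cells x genes expression matrix `A` to an
#' n x n similarity matrix `S` in four deterministic steps:
#' \enumerate{
#'   \item `L = log(A + 1)` element-wise (natural logarithm);
#'   \item `I = L L'` — inner products of the log-expression profiles of
#'     every cell pair;
#'   \item global min-max normalisation
#'     `I' = (I - min(I)) / (max(I) - min(I))`, taken over the full matrix
#'     including the diagonal;
#'   \item `S = tanh(I')`, the "improved sigmoid kernel".
#' }
#' Because normalised inner products lie in `[0, 1]`, every similarity lies
#' in `[0, tanh(1)] ~= [0, 0.7616]`.
#'
#' When the inner-product matrix is constant (`max == min`, e.g. an all-zero
#' input) the normalisation is degenerate; the kernel then returns the
#' all-zero matrix ("no signal, no similarity") instead of NaN.
#'
#' @param a an [expression_matrix()] or non-negative numeric matrix
#'   (cells x genes).
#' @return For `kernel_embedding`, an n x n `kernel_matrix` with cell ids as
#'   dimnames; intermediate stages return plain matrices.
#' @examples
#' a <- matrix(c(exp(1) - 1, 0), 2, 1)
#' kernel_embedding(a)   # [[tanh(1), 0], [0, 0]]
#' @export
kernel_embedding <- function(a) {
  s <- sigmoid_kernel(minmax_update(row_inner_products(log_transform(a))))
  dimnames(s) <- list(rownames(a), rownames(a))
  class(s) <- c("kernel_matrix", class(matrix()))
  s
}

#' @rdname kernel_embedding
#' @export
log_transform <- function(a) {
  check_that(is.numeric(a), "`a` must be numeric")
  check_that(!anyNA(a) && all(is.finite(a)), "`a` must be finite")
  check_that(min(a) >= 0, "negative expression values are not allowed")
  log1p(unclass(a))
}

#' @rdname kernel_embedding
#' @param l log-transformed matrix.
#' @export
row_inner_products <- function(l) {
  check_that(is.matrix(l) && all(is.finite(l)), "`l` must be a finite matrix")
  tcrossprod(l)
}

#' @rdname kernel_embedding
#' @param i inner-product matrix.
#' @export
minmax_update <- function(i) {
  check_that(is.matrix(i) && all(is.finite(i)), "`i` must be a finite matrix")
  rng <- range(i)
  if (rng[2] == rng[1]) {
    return(array(0, dim(i)))
  }
  (i - rng[1]) / (rng[2] - rng[1])
}

#' @rdname kernel_embedding
#' @param i_norm min-max-normalised inner-product matrix, entries in `[0, 1]`.
#' @export
sigmoid_kernel <- function(i_norm) {
  check_that(is.matrix(i_norm) && all(is.finite(i_norm)),
             "`i_norm` must be a finite matrix")
  tanh(i_norm)
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %d x %d, range [%.4f, %.4f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# similarity in [0,1]: learned similarities pass through, kernel matrices are
# rescaled by 1/tanh(1)
as_unit_similarity <- function(m) {
  if (inherits(m, "kernel_matrix")) m <- unclass(m) / TANH1
  m <- unclass(m)
  check_that(nrow(m) == ncol(m), "similarity matrix must be square")
  check_that(max(abs(m - t(m))) <= 1e-8, "similarity matrix is not symmetric")
  pmin(pmax(m, 0), 1)
}
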