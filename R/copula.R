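#' Sample from a Gaussian copula
#'
#' Draws n rows from the Gaussian copula with the given (validated, positive
#' definite) correlation matrix: correlated standard normals via the Cholesky
#' factor, pushed to uniforms with the normal CDF. Each column is marginally
#' uniform on (0, 1) and each pair has population Spearman correlation
#' (6 / pi) * asin(r / 2) of its copula parameter r.
#'
#' @param n number of rows (>= 1).
#' @param matrix positive-definite copula correlation matrix (typically the
#'   `matrix` component of [validate_correlation_matrix()]).
#' @param seed integer seed; the draw is a pure function of `(n, matrix, seed)`.
#' @return an `n x ncol(matrix)` matrix of uniforms in (0, 1).
#' @export
sample_copula <- function(n, matrix, seed) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  d <- ncol(matrix)
  ev <- eigen(matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("sample_copula: matrix is not positive definite; run validate_correlation_matrix first",
         call. = FALSE)
  L <- chol(matrix)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  Z <- base::matrix(rnorm(n * d), nrow = n, ncol = d) %*% L
  U <- pnorm(Z)
  # guard against numerically exact 0/1 in extreme tails
  eps <- .Machine$double.eps
  U[U <= 0] <- eps; U[U >= 1] <- 1 - eps
  colnames(U) <- colnames(matrix)
  U
}
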