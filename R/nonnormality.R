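#' Frobenius commutator metric of non-normality
#'
#' A matrix is normal iff it commutes with its conjugate transpose,
#' `A* A = A A*`; this metric is the square root of the Frobenius norm of the
#' commutator `A* A - A A*`, quantifying the discrepancy. Zero exactly for
#' normal matrices; positively homogeneous of degree 1 in `A`.
#'
#' @param A square real matrix.
#' @return dimensionless value >= 0.
#' @export
frobenius_metric <- function(A) {
  A <- as_square(A)
  As <- Conj(t(A))
  sqrt(norm(As %*% A - A %*% As, type = "F"))
}

#' Henrici departure from normality
#'
#' `sqrt(||A||_F^2 - sum_k |lambda_k|^2)`: the part of the matrix "energy"
#' (squared Frobenius norm) not accounted for by its eigenvalues. Schur's
#' inequality guarantees the argument is >= 0.
#'
#' Evaluated through the real Schur form `A = Q T Q'`: the argument equals
#' the off-diagonal energy of `T` (for each 2x2 block of a complex pair,
#' `(a - d)^2 + (b + c)^2`), a sum of squares. This is algebraically
#' identical to the defining formula but avoids the catastrophic cancellation
#' of subtracting two nearly equal large numbers, so the metric is an exact
#' zero (to machine precision) on normal matrices. The argument is still
#' floored at zero before the root.
#'
#' @param A square real matrix.
#' @return dimensionless value >= 0.
#' @export
henrici_metric <- function(A) {
  A <- as_square(A)
  n <- nrow(A)
  if (n == 1) return(0)
  T <- as.matrix(Matrix::Schur(A, vectors = FALSE)$T)
  h2 <- sum(T[upper.tri(T)]^2)
  sub <- which(abs(T[cbind(2:n, 1:(n - 1))]) > 0)
  for (i in sub) {   # 2x2 block of a complex conjugate pair at (i, i+1)
    a <- T[i, i]; b <- T[i, i + 1]; cc <- T[i + 1, i]; d <- T[i + 1, i + 1]
    h2 <- h2 - b^2 + (a - d)^2 + (b + cc)^2
  }
  sqrt(max(h2, 0))
}

#' Ruhe metric: singular values against eigenvalue magnitudes
#'
#' Singular values and eigenvalue magnitudes, each sorted in descending
#' order and paired by rank; the metric is the maximum absolute pairwise
#' difference `max_k |sigma_k - |lambda_k||`. The two sets coincide exactly
#' for normal matrices and diverge with increasing asymmetry.
#'
#' @param A square real matrix.
#' @return dimensionless value >= 0.
#' @export
ruhe_metric <- function(A) {
  A <- as_square(A)
  sv <- svd(A, nu = 0, nv = 0)$d
  ev <- sort(Mod(eigen(A, only.values = TRUE)$values), decreasing = TRUE)
  max(abs(sv - ev))
}

as_square <- function(A) {
  A <- unclass(A)
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop(errorCondition("non-normality metrics require a square matrix",
                        class = c("transppm_validation_error", "error")))
  A
}

#' All three non-normality metrics on the raw and standardised matrix
#'
#' Computes Frobenius, Henrici and Ruhe metrics on `A` and on
#' `Ahat = A / lambda1` (real part taken after scaling). Since all three
#' metrics are homogeneous of degree 1, each scaled value equals the raw
#' value divided by `lambda1` -- so standardisation raises every metric when
#' the population is declining (`lambda1 < 1`).
#'
#' @param A square nonnegative matrix.
#' @param lambda1 dominant eigenvalue (> 0); computed from `A` when omitted.
#' @return list with elements `raw` and `scaled`, each a list with
#'   `frobenius`, `henrici`, `ruhe` and a `scaled` flag.
#' @export
metric_suite <- function(A, lambda1 = NULL) {
  if (is.null(lambda1)) lambda1 <- eigendata(A)$lambda1
  Ahat <- scale_matrix(A, lambda1)
  triple <- function(M, scaled) list(frobenius = frobenius_metric(M),
                                     henrici = henrici_metric(M),
                                     ruhe = ruhe_metric(M),
                                     scaled = scaled)
  list(raw = triple(unclass(A), FALSE), scaled = triple(Ahat, TRUE))
}
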