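#' Eigendecomposition summary of a projection matrix
#'
#' Full spectrum sorted by non-increasing magnitude (ties broken by
#' descending real, then descending imaginary part), the real dominant
#' eigenvalue, and the dominant right eigenvector rescaled to a nonnegative
#' unit-one-norm stable age structure.
#'
#' @param A square matrix.
#' @param tol tolerance for discarding a numerically spurious imaginary part
#'   of the dominant eigenvalue.
#' @return list with `values` (complex, sorted), `lambda1` (real),
#'   `stable_structure` (nonnegative, sums to 1; `NULL` if not recoverable).
#' @export
eigendata <- function(A, tol = 1e-9) {
  e <- eigen(unclass(A))
  ord <- order(-Mod(e$values), -Re(e$values), -Im(e$values))
  values <- e$values[ord]
  l1 <- values[1]
  if (abs(Im(l1)) > tol)
    stop(errorCondition(
      sprintf("dominant eigenvalue has imaginary part %.3g: not a Perron root",
              Im(l1)),
      class = c("transppm_non_perron_error", "error")))
  w <- e$vectors[, ord[1]]
  stable <- NULL
  if (max(abs(Im(w))) <= tol * max(abs(w))) {
    w <- Re(w)
    w <- w / sum(w)
    if (all(w >= -tol)) stable <- pmax(w, 0) / sum(pmax(w, 0))
  }
  list(values = values, lambda1 = Re(l1), stable_structure = stable)
}

#' Damping ratio
#'
#' The dominant eigenvalue divided by the magnitude of the subdominant one,
#' `lambda1 / |lambda2|`: the asymptotic rate at which transient deviations
#' from the stable structure decay (not their amplitude). Infinite (flagged by
#' the value itself) when the subdominant eigenvalue is zero.
#'
#' @param ed an [eigendata()] result.
#' @return dimensionless ratio >= 1 when `lambda1` is strictly dominant.
#' @export
damping_ratio <- function(ed) {
  m2 <- Mod(ed$values[2])
  if (m2 == 0) Inf else ed$lambda1 / m2
}

#' Standardise a matrix by its asymptotic growth rate
#'
#' `Ahat = A / lambda1`, whose dominant eigenvalue is 1. Scaling factors out
#' population growth or decline, isolating the transient part of the
#' dynamics. Any numerically spurious imaginary part is discarded.
#'
#' @param A square matrix.
#' @param lambda1 dominant eigenvalue; computed from `A` when omitted.
#' @return the scaled real matrix.
#' @export
scale_matrix <- function(A, lambda1 = NULL) {
  if (is.null(lambda1)) lambda1 <- eigendata(A)$lambda1
  if (!is.finite(lambda1) || lambda1 <= 0)
    stop(errorCondition("lambda1 must be positive to standardise",
                        class = c("transppm_degenerate_matrix", "error")))
  Re(unclass(A)) / lambda1
}

#' Normalise a population vector to proportions
#'
#' Divides by the one-norm so the entries give the proportion of the
#' population in each age bin.
#'
#' @param n nonnegative vector with positive sum.
#' @return vector summing to 1.
#' @export
normalize_structure <- function(n) {
  s <- sum(n)
  if (!is.finite(s) || s <= 0)
    stop(errorCondition("cannot normalise a zero or non-finite vector",
                        class = c("transppm_validation_error", "error")))
  n / s
}

one_norm <- function(v) sum(abs(v))

#' Case-specific reactivity
#'
#' Relative population size after one projection interval, with asymptotic
#' growth factored out: the one-norm of `Ahat %*% n0` for a standardised
#' matrix and a proportion-scaled initial structure. Values below 1 indicate
#' first-timestep attenuation rather than amplification and are reported
#' as-is.
#'
#' @param Ahat standardised matrix (`A / lambda1`).
#' @param n0 initial structure, normalised to sum to 1.
#' @return dimensionless relative population size.
#' @export
reactivity <- function(Ahat, n0) {
  one_norm(unclass(Ahat) %*% as.numeric(n0))
}

#' Population inertia
#'
#' Relative population size after the transient period -- by default 100
#' timesteps (500 years) -- with asymptotic growth factored out: the one-norm
#' of `Ahat^horizon %*% n0`, computed by iterated multiplication for
#' numerical stability. The lasting multiplicative offset an unstable initial
#' structure leaves on eventual population size.
#'
#' @inheritParams reactivity
#' @param horizon number of timesteps (>= 1), default 100.
#' @return dimensionless relative population size (`NaN`/`Inf` flag numerical
#'   overflow from a mis-estimated `lambda1`).
#' @export
inertia <- function(Ahat, n0, horizon = 100L) {
  stopifnot(horizon >= 1)
  v <- as.numeric(n0)
  M <- unclass(Ahat)
  for (k in seq_len(horizon)) v <- as.numeric(M %*% v)
  one_norm(v)
}

#' All per-matrix transient and non-normality metrics
#'
#' Convenience wrapper producing one record per projection matrix: the
#' asymptotic growth rate, damping ratio, case-specific reactivity and
#' inertia (both on the standardised matrix with the observed initial
#' structure), and the three non-normality metrics on the raw and
#' standardised matrix.
#'
#' @param A a `ppm` (or any nonnegative square matrix).
#' @param n0 observed initial population vector (any positive scale).
#' @param horizon inertia horizon in timesteps.
#' @return one-row data.frame with columns country, year, lambda1,
#'   damping_ratio, reactivity, inertia, nn_frobenius_raw, nn_henrici_raw,
#'   nn_ruhe_raw, nn_frobenius_scaled, nn_henrici_scaled, nn_ruhe_scaled.
#' @export
transient_record <- function(A, n0, horizon = 100L) {
  ed <- eigendata(A)
  Ahat <- scale_matrix(A, ed$lambda1)
  n0 <- normalize_structure(as.numeric(n0))
  nn <- metric_suite(A, ed$lambda1)
  data.frame(
    country = attr(A, "country") %||% NA_character_,
    year = attr(A, "year") %||% NA_integer_,
    lambda1 = ed$lambda1,
    damping_ratio = damping_ratio(ed),
    reactivity = reactivity(Ahat, n0),
    inertia = inertia(Ahat, n0, horizon),
    nn_frobenius_raw = nn$raw$frobenius,
    nn_henrici_raw = nn$raw$henrici,
    nn_ruhe_raw = nn$raw$ruhe,
    nn_frobenius_scaled = nn$scaled$frobenius,
    nn_henrici_scaled = nn$scaled$henrici,
    nn_ruhe_scaled = nn$scaled$ruhe,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
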