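#' Leslie-type population projection matrix with metadata
#'
#' An 18x18 nonnegative matrix advancing the female population vector by one
#' 5-year step: fertility on the top row, survival/progression on the
#' subdiagonal, and a "stasis" entry in the bottom-right corner letting the
#' open 85+ class persist. All other entries must be zero.
#'
#' @param A 18x18 numeric matrix.
#' @param country,year metadata labels.
#' @return `A` with class `ppm` and metadata attributes.
#' @export
new_ppm <- function(A, country = NA_character_, year = NA_integer_) {
  if (!is.matrix(A) || nrow(A) != 18 || ncol(A) != 18)
    stop("a ppm must be an 18x18 matrix")
  allowed <- matrix(FALSE, 18, 18)
  allowed[1, ] <- TRUE
  allowed[cbind(2:18, 1:17)] <- TRUE
  allowed[18, 18] <- TRUE
  if (any(A[!allowed] != 0))
    stop(errorCondition(
      "ppm has nonzero entries outside the top row, subdiagonal and stasis cell",
      class = c("transppm_construction_error", "error")))
  if (any(A < 0))
    stop(errorCondition("ppm entries must be nonnegative",
                        class = c("transppm_construction_error", "error")))
  sub <- A[cbind(2:18, 1:17)]
  if (any(sub > 1 + 1e-12))
    stop(errorCondition("survival entries must not exceed 1",
                        class = c("transppm_construction_error", "error")))
  structure(A, class = c("ppm", class(A)),
            country = country, year = as.integer(year), timestep_years = 5L)
}

#' @export
print.ppm <- function(x, ...) {
  cat(sprintf("18x18 population projection matrix (%s, %s); 5-year timestep\n",
              attr(x, "country"), attr(x, "year")))
  cat(sprintf("  fertility bins: %s; subdiagonal survival range [%.3f, %.3f]; stasis %.3f\n",
              paste(range(which(x[1, ] > 0)), collapse = "-"),
              min(x[cbind(2:18, 1:17)]), max(x[cbind(2:18, 1:17)]), x[18, 18]))
  invisible(x)
}

stop_degenerate <- function(country, year, msg) {
  stop(errorCondition(sprintf("[%s %s] %s", country, year, msg),
                      class = c("transppm_degenerate_bin", "error")))
}

#' Five-year survival probability from deaths and population
#'
#' `max(0, 1 - 5 * deaths / population)`: the annual death count is
#' quintupled to the 5-year step; where quintupled deaths exceed the
#' population the negative value is replaced with zero.
#'
#' @param deaths annual deaths in the bin.
#' @param population person-count of the bin (> 0).
#' @param country,year labels used in error messages.
#' @return survival probability in `[0, 1]`.
#' @export
survival_rate <- function(deaths, population, country = "?", year = "?") {
  if (any(population <= 0))
    stop_degenerate(country, year, "bin with zero population")
  pmax(0, 1 - 5 * deaths / population)
}

#' Combined survival of the 0--4 bin from its infant/child split
#'
#' Infant (under 1) deaths are much higher than child (1--4) deaths, so the
#' first bin's survival is computed separately for the two groups and combined
#' with fixed weights: `0.2 * s0 + 0.8 * s1_4`.
#'
#' @param s0 infant (age 0) survival in `[0, 1]`.
#' @param s1_4 child (ages 1--4) survival in `[0, 1]`.
#' @return combined 0--4 survival.
#' @export
combined_infant_child_survival <- function(s0, s1_4) {
  if (s0 < 0 || s0 > 1 || s1_4 < 0 || s1_4 > 1)
    stop(errorCondition("survival inputs must lie in [0, 1]",
                        class = c("transppm_validation_error", "error")))
  0.2 * s0 + 0.8 * s1_4
}

#' Per-bin fertility with the birth-flow approximation
#'
#' `(5 * female_births / population) * sqrt(s_maternal) * sqrt(s_04)`: the
#' annual daughter count is quintupled to the step, and the square-root
#' survival factors account for mothers and newborns being exposed to
#' mortality for half the interval on average (births flow continuously
#' within the 5-year step).
#'
#' @param female_births annual female births to mothers in the bin.
#' @param population person-count of the maternal bin (> 0).
#' @param s_maternal survival of the maternal bin.
#' @param s_04 combined survival of the 0--4 bin.
#' @param country,year labels used in error messages.
#' @return expected daughters per female per 5-year step.
#' @export
fertility_rate <- function(female_births, population, s_maternal, s_04,
                           country = "?", year = "?") {
  if (any(population <= 0))
    stop_degenerate(country, year, "bin with zero population")
  (5 * female_births / population) * sqrt(s_maternal) * sqrt(s_04)
}

#' Build the 18x18 projection matrix from binned demography
#'
#' Survival (via [survival_rate()]) fills the subdiagonal for bins 1--17, with
#' bin 1 using the weighted infant/child combination
#' ([combined_infant_child_survival()]); the open 85+ class receives a stasis
#' entry in the bottom-right corner using the same survival formula.
#' Fertility ([fertility_rate()]) fills the top row, with each bin's own
#' survival as the maternal factor (stasis for bin 18) and the combined 0--4
#' survival as the offspring factor.
#'
#' @param binned a [bin_to_five_year()] result.
#' @return a [new_ppm()] matrix with the country/year metadata.
#' @export
build_ppm <- function(binned) {
  stopifnot(inherits(binned, "binned_demography"))
  cy <- list(binned$country, binned$year)
  if (any(binned$population <= 0))
    stop_degenerate(cy[[1]], cy[[2]],
                    sprintf("zero population in bin(s) %s",
                            paste(which(binned$population <= 0), collapse = ",")))
  s <- survival_rate(binned$deaths, binned$population, cy[[1]], cy[[2]])
  s0 <- survival_rate(binned$infant_deaths, binned$infant_population, cy[[1]], cy[[2]])
  s14 <- survival_rate(binned$child_deaths, binned$child_population, cy[[1]], cy[[2]])
  s[1] <- combined_infant_child_survival(s0, s14)
  f <- fertility_rate(binned$female_births, binned$population, s, s[1],
                      cy[[1]], cy[[2]])
  A <- matrix(0, 18, 18)
  A[1, ] <- f
  A[cbind(2:18, 1:17)] <- s[1:17]
  A[18, 18] <- s[18]
  new_ppm(A, country = binned$country, year = binned$year)
}

#' Project a population vector through a matrix
#'
#' Premultiplies repeatedly: returns `n0, A n0, A^2 n0, ...` as the columns of
#' an 18 x (steps + 1) matrix.
#'
#' @param A projection matrix.
#' @param n0 nonnegative population vector of matching dimension.
#' @param steps number of 5-year steps (>= 0).
#' @return matrix whose column `k + 1` is `A^k n0`.
#' @export
project <- function(A, n0, steps) {
  if (length(n0) != ncol(A))
    stop(errorCondition("population vector length does not match matrix dimension",
                        class = c("transppm_validation_error", "error")))
  stopifnot(steps >= 0)
  out <- matrix(NA_real_, length(n0), steps + 1)
  v <- as.numeric(n0)
  out[, 1] <- v
  for (k in seq_len(steps)) {
    v <- as.numeric(A %*% v)
    out[, k + 1] <- v
  }
  out
}

#' Write a stack of projection matrices as long-format CSV
#'
#' Columns country, year, row, col, value; one row per matrix entry.
#'
#' @param ppms list of `ppm` matrices.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ppm_stack <- function(ppms, path) {
  rows <- lapply(ppms, function(A) {
    data.frame(country = attr(A, "country"), year = attr(A, "year"),
               row = rep(1:18, 18), col = rep(1:18, each = 18),
               value = as.vector(unclass(A)[1:18, 1:18]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
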