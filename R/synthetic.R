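#' Configuration for the synthetic demographic data generator
#'
#' Bundles the parameters of the vital-rate schedules and the shape of the
#' emitted tables. The generator produces Eurostat-shaped single-year tables
#' (female population, deaths, and births by maternal age, for ages 0--84 plus
#' an open "85+" class) whose underlying rates are known exactly, so that the
#' downstream matrix builder can be validated by rate recovery.
#'
#' Mortality follows a Gompertz--Makeham law per 5-year step,
#' `a + b * exp(c * age)`, multiplied by `infant_excess` at age 0 and clamped
#' to `[0, 1]`. Fertility is a Gaussian kernel centred at
#' `fertility_peak_age`, zero outside `repro_window`, scaled so the rates sum
#' to `tfr_scale` (daughters per female per 5-year step, summed over
#' single-year ages; the implied net reproduction is roughly `tfr_scale / 5`).
#'
#' @param n_countries number of synthetic countries.
#' @param years integer vector of observation years.
#' @param base_population mean female population per single-year age class.
#' @param makeham_a,gompertz_b,gompertz_c Gompertz--Makeham parameters for the
#'   death rate per 5-year step.
#' @param infant_excess multiplier (>= 1) on the age-0 death rate.
#' @param fertility_peak_age,fertility_width centre and width (years) of the
#'   Gaussian fertility kernel.
#' @param tfr_scale total of the per-age fertility rates (dimensionless >= 0).
#' @param repro_window inclusive age range outside which fertility is zero.
#' @param sex_ratio_at_birth male births per female birth.
#' @param seed integer seed; fixing it makes the output bit-identical.
#' @param noise `"none"` (real-valued expected counts, the default) or
#'   `"poisson"` (integer counts drawn under `seed`).
#' @param boom_birth_years two-element vector: birth-year range of an
#'   amplified "baby boom" cohort (creates non-trivial transient dynamics);
#'   `NULL` for a stable pyramid.
#' @param boom_amplitude multiplicative bulge applied to boom-cohort ages.
#' @param country_rate_spread relative spread of mortality (and, with opposite
#'   sign, fertility) across countries, so countries differ deterministically.
#' @param anomaly_spec optional list of anomalies for [inject_anomalies()].
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_countries = 3,
                             years = 1960:1989,
                             base_population = 1e5,
                             makeham_a = 0.001,
                             gompertz_b = 3e-4,
                             gompertz_c = 0.095,
                             infant_excess = 15,
                             fertility_peak_age = 28,
                             fertility_width = 6,
                             tfr_scale = 4.75,
                             repro_window = c(12, 55),
                             sex_ratio_at_birth = 1.05,
                             seed = 1L,
                             noise = c("none", "poisson"),
                             boom_birth_years = c(1955, 1965),
                             boom_amplitude = 1.2,
                             country_rate_spread = 0.05,
                             anomaly_spec = NULL) {
  noise <- match.arg(noise)
  num <- c(base_population = base_population, makeham_a = makeham_a,
           gompertz_b = gompertz_b, gompertz_c = gompertz_c,
           infant_excess = infant_excess, fertility_peak_age = fertility_peak_age,
           fertility_width = fertility_width, tfr_scale = tfr_scale,
           sex_ratio_at_birth = sex_ratio_at_birth)
  if (!all(is.finite(num)))
    stop_config("non-finite parameter(s): ",
                paste(names(num)[!is.finite(num)], collapse = ", "))
  if (gompertz_b <= 0) stop_config("gompertz_b must be > 0")
  if (fertility_width <= 0) stop_config("fertility_width must be > 0")
  if (tfr_scale < 0) stop_config("tfr_scale must be >= 0")
  if (sex_ratio_at_birth <= 0) stop_config("sex_ratio_at_birth must be > 0")
  if (infant_excess < 1) stop_config("infant_excess must be >= 1")
  if (n_countries < 1) stop_config("need at least one country")
  structure(list(
    n_countries = as.integer(n_countries), years = as.integer(years),
    base_population = base_population, makeham_a = makeham_a,
    gompertz_b = gompertz_b, gompertz_c = gompertz_c,
    infant_excess = infant_excess, fertility_peak_age = fertility_peak_age,
    fertility_width = fertility_width, tfr_scale = tfr_scale,
    repro_window = repro_window, sex_ratio_at_birth = sex_ratio_at_birth,
    seed = as.integer(seed), noise = noise,
    boom_birth_years = boom_birth_years, boom_amplitude = boom_amplitude,
    country_rate_spread = country_rate_spread, anomaly_spec = anomaly_spec
  ), class = "synthetic_config")
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("transppm_config_error", "error")))
}

#' Single-year age labels used throughout: "0".."84" plus the open class
#' @return character vector of length 86.
#' @export
age_labels <- function() c(as.character(0:84), "85+")

# ages as integers 0..85, where 85 stands for the open class
.ages <- 0:85

# deterministic per-country multiplier in [1 - s, 1 + s]
country_multiplier <- function(i, n, spread) {
  if (n == 1) return(1)
  1 + spread * (2 * i - n - 1) / (n - 1)
}

#' Per-age death rates implied by a configuration
#'
#' Gompertz--Makeham death rates per 5-year projection step,
#' `a + b exp(c age)`, with the age-0 rate multiplied by `infant_excess`,
#' clamped to `[0, 1]`. The last element is the rate for the open 85+ class
#' (evaluated at age 85).
#'
#' @param config a [synthetic_config()].
#' @param country country index (1-based) for the deterministic cross-country
#'   spread; default 0 means the unmodified baseline schedule.
#' @return numeric vector of length 86 named by [age_labels()].
#' @export
make_mortality_schedule <- function(config, country = 0L) {
  mult <- if (country >= 1L)
    country_multiplier(country, config$n_countries, config$country_rate_spread)
  else 1
  rate <- config$makeham_a + config$gompertz_b * exp(config$gompertz_c * .ages)
  rate[1] <- rate[1] * config$infant_excess
  rate <- pmin(1, pmax(0, rate * mult))
  names(rate) <- age_labels()
  rate
}

#' Per-age fertility rates implied by a configuration
#'
#' Gaussian-kernel fertility (daughters per female per 5-year step) centred at
#' `fertility_peak_age`, zero outside `repro_window`, normalised so the rates
#' sum to `tfr_scale`.
#'
#' @inheritParams make_mortality_schedule
#' @return numeric vector of length 86 named by [age_labels()].
#' @export
make_fertility_schedule <- function(config, country = 0L) {
  mult <- if (country >= 1L)
    1 / country_multiplier(country, config$n_countries, config$country_rate_spread)
  else 1
  f <- exp(-0.5 * ((.ages - config$fertility_peak_age) / config$fertility_width)^2)
  f[.ages < config$repro_window[1] | .ages > config$repro_window[2]] <- 0
  total <- sum(f)
  f <- if (total > 0 && config$tfr_scale > 0)
    f / total * config$tfr_scale * mult
  else
    rep(0, length(f))
  names(f) <- age_labels()
  f
}

# survivorship-based age pyramid (persons per single-year class), with the
# open class sized at its stationary mass l(85) / (1 - s85)
base_pyramid <- function(config, death_rate) {
  surv1 <- pmax(0, 1 - death_rate / 5)            # annual survival approx
  l <- cumprod(c(1, surv1[1:85]))                 # l[1]=l(0) .. l[86]=l(85)
  open_s <- surv1[86]
  l[86] <- l[86] / max(1 - open_s, 1e-6)
  config$base_population * length(l) * l / sum(l)
}

pyramid_for_year <- function(config, death_rate, year) {
  pop <- base_pyramid(config, death_rate)
  b <- config$boom_birth_years
  if (!is.null(b) && config$boom_amplitude != 1) {
    boom_ages <- (year - b[2]):(year - b[1])
    boom_ages <- boom_ages[boom_ages >= 0 & boom_ages <= 84]
    pop[boom_ages + 1] <- pop[boom_ages + 1] * config$boom_amplitude
  }
  pop
}

#' Simulate Eurostat-shaped demographic tables for all configured countries
#'
#' For every country--year emits single-year female population, deaths and
#' births by maternal age. Deaths are `population * death_rate / 5` per year
#' (the 5-year-step rate spread over one year), so the downstream
#' `1 - 5 * deaths / population` estimator recovers survival exactly in the
#' noiseless case. Births (both sexes) are
#' `population * fertility_rate / 5 * (1 + sex_ratio_at_birth)` so that the
#' female-birth conversion recovers the configured daughter rates exactly.
#' With `noise = "poisson"` counts are Poisson draws with those expectations,
#' under the configured seed.
#'
#' @param config a [synthetic_config()].
#' @return a data.frame with columns `country`, `year`, `age` (character,
#'   "0".."84" and "85+"), `population`, `deaths`, `births`, ordered by
#'   country, year, age.
#' @export
simulate_country_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  out <- vector("list", config$n_countries * length(config$years))
  k <- 0L
  for (i in seq_len(config$n_countries)) {
    dr <- make_mortality_schedule(config, i)
    fr <- make_fertility_schedule(config, i)
    cname <- sprintf("C%02d", i)
    for (y in config$years) {
      pop <- pyramid_for_year(config, dr, y)
      deaths <- pop * dr / 5
      births <- pop * fr / 5 * (1 + config$sex_ratio_at_birth)
      if (config$noise == "poisson") {
        pop <- as.numeric(round(pop))
        deaths <- as.numeric(stats::rpois(length(deaths), deaths))
        births <- as.numeric(stats::rpois(length(births), births))
      }
      k <- k + 1L
      out[[k]] <- data.frame(country = cname, year = y, age = age_labels(),
                             population = pop, deaths = deaths,
                             births = births, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  if (!is.null(config$anomaly_spec)) df <- inject_anomalies(df, config$anomaly_spec)
  df
}

#' Inject data anomalies into a simulated table
#'
#' Reproduces the pathologies the cleaning filter must catch: runs of zero
#' recorded deaths across consecutive single-year classes, and implausibly
#' tiny populations. Each anomaly is a list with `country`, `year`, and either
#' `zero_death_run_length` (with optional `start_age`, default 20) or
#' `population_floor` (all population cells are capped at the floor).
#'
#' @param series data.frame as returned by [simulate_country_series()].
#' @param anomaly_spec list of anomaly lists.
#' @return the modified data.frame; cells outside the requested country--year
#'   and ages are untouched.
#' @export
inject_anomalies <- function(series, anomaly_spec) {
  if (is.null(anomaly_spec) || length(anomaly_spec) == 0) return(series)
  for (a in anomaly_spec) {
    sel <- series$country == a$country & series$year == a$year
    if (!any(sel))
      stop(errorCondition(
        sprintf("anomaly refers to unknown country-year %s/%s", a$country, a$year),
        class = c("transppm_lookup_error", "error")))
    if (!is.null(a$zero_death_run_length)) {
      start <- if (is.null(a$start_age)) 20L else as.integer(a$start_age)
      run_ages <- as.character(start:(start + a$zero_death_run_length - 1L))
      series$deaths[sel & series$age %in% run_ages] <- 0
    } else if (!is.null(a$population_floor)) {
      series$population[sel] <- pmin(series$population[sel], a$population_floor)
    } else {
      stop_config("anomaly must give zero_death_run_length or population_floor")
    }
  }
  series
}

#' Ground-truth projection matrix implied by a configuration
#'
#' Builds the 18x18 projection matrix directly from the configured schedules
#' and the deterministic age pyramid, without passing through simulated
#' counts: per-bin survival is `1 - ` the population-weighted mean death rate
#' of the bin's single-year ages, and the fertility row applies the birth-flow
#' approximation to the weighted-mean daughter rate. Used as the independent
#' truth for round-trip rate-recovery checks.
#'
#' @inheritParams make_mortality_schedule
#' @param year observation year (affects the pyramid's boom bulge).
#' @return an 18x18 `ppm` matrix (see [build_ppm()]).
#' @export
expected_projection_matrix <- function(config, country = 1L, year = config$years[1]) {
  dr <- make_mortality_schedule(config, country)
  fr <- make_fertility_schedule(config, country)
  pop <- pyramid_for_year(config, dr, year)
  bin <- c(pmin(floor(0:84 / 5), 16) + 1, 18)   # single-year age -> bin index
  wmean <- function(x) as.numeric(tapply(x * pop, bin, sum) / tapply(pop, bin, sum))
  q <- wmean(dr)                                # per-bin 5-year death rates
  s <- pmax(0, 1 - q)
  s0 <- max(0, 1 - dr[1])
  q14 <- sum(pop[2:5] * dr[2:5]) / sum(pop[2:5])
  s14 <- max(0, 1 - q14)
  s[1] <- combined_infant_child_survival(s0, s14)
  f <- wmean(fr) * sqrt(s) * sqrt(s[1])
  A <- matrix(0, 18, 18)
  A[1, ] <- f
  A[cbind(2:18, 1:17)] <- s[1:17]
  A[18, 18] <- s[18]
  new_ppm(A, country = sprintf("C%02d", country), year = year)
}

#' Write a demographic table to CSV
#'
#' One row per country/year/age; UTF-8, "." decimal separator; the open age
#' class is the literal token "85+".
#'
#' @param series data.frame from [simulate_country_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_demography_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
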