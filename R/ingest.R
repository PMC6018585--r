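#' Single country--year of single-year demographic counts
#'
#' Constructor and validator for the in-memory representation of one
#' country--year: vectors of length 86 (ages 0--84 plus the open 85+ class)
#' for female population, deaths, and births by maternal age.
#'
#' @param country label.
#' @param year integer year.
#' @param population,deaths,births_by_maternal_age numeric vectors, length 86,
#'   all entries >= 0.
#' @return an object of class `age_series`.
#' @export
age_series <- function(country, year, population, deaths, births_by_maternal_age) {
  n <- length(age_labels())
  vecs <- list(population = population, deaths = deaths,
               births_by_maternal_age = births_by_maternal_age)
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (length(v) != n)
      stop_validation(country, year, sprintf("%s must have length %d", nm, n))
    if (anyNA(v) || !all(is.finite(v)))
      stop_validation(country, year, sprintf("%s contains non-finite values", nm))
    if (any(v < 0))
      stop_validation(country, year, sprintf("%s contains negative counts", nm))
  }
  structure(list(country = country, year = as.integer(year),
                 population = as.numeric(population),
                 deaths = as.numeric(deaths),
                 births_by_maternal_age = as.numeric(births_by_maternal_age),
                 total_births = sum(births_by_maternal_age)),
            class = "age_series")
}

stop_validation <- function(country, year, msg) {
  stop(errorCondition(sprintf("[%s %s] %s", country, year, msg),
                      class = c("transppm_validation_error", "error")))
}

#' Convert a long-format demographic table to a list of age_series
#'
#' @param df data.frame with columns country, year, age, population, deaths,
#'   births (the shape written by [write_demography_csv()]).
#' @return named list of [age_series()] objects ("country:year").
#' @export
as_age_series_list <- function(df) {
  need <- c("country", "year", "age", "population", "deaths", "births")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop(errorCondition(paste("missing column(s):",
                              paste(missing_cols, collapse = ", ")),
                        class = c("transppm_parse_error", "error")))
  labs <- age_labels()
  keys <- unique(df[, c("country", "year")])
  out <- vector("list", nrow(keys))
  names(out) <- paste(keys$country, keys$year, sep = ":")
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$country == keys$country[i] & df$year == keys$year[i], ]
    idx <- match(labs, sub$age)
    if (anyNA(idx)) {
      miss <- labs[is.na(idx)]
      stop_validation(keys$country[i], keys$year[i],
                      paste("missing age row(s):", paste(utils::head(miss, 3),
                                                         collapse = ", "),
                            if ("85+" %in% miss) "(an open '85+' row is required)" else ""))
    }
    sub <- sub[idx, ]
    out[[i]] <- age_series(keys$country[i], keys$year[i],
                           sub$population, sub$deaths, sub$births)
  }
  out
}

#' Read a demographic CSV into age_series objects
#'
#' Expects the schema written by [write_demography_csv()]: columns country,
#' year, age ("0".."84" plus "85+"), population, deaths, births. Each
#' country--year must supply all 86 age rows including the open class;
#' negative or non-numeric counts are rejected with the offending line named.
#'
#' @param path CSV file path.
#' @return named list of [age_series()] objects.
#' @export
read_demography_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(age = "character"))
  for (col in c("year", "population", "deaths", "births")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0)
      stop(errorCondition(
        sprintf("malformed value in column '%s' at data line %d", col, bad[1]),
        class = c("transppm_parse_error", "error")))
    df[[col]] <- as.numeric(df[[col]])
  }
  as_age_series_list(df)
}

#' Longest run of consecutive zero death counts
#' @param deaths numeric vector of single-year death counts.
#' @return integer, the maximum run length of exact zeros.
#' @export
max_zero_run <- function(deaths) {
  r <- rle(deaths == 0)
  z <- r$lengths[r$values]
  if (length(z) == 0) 0L else as.integer(max(z))
}

#' Data-quality filter: runs of zero recorded deaths
#'
#' A country--year whose single-year deaths vector contains `run_length` or
#' more consecutive exact zeros is flagged for exclusion, as such runs
#' indicate inaccurate collection or impractically small populations. The run
#' is evaluated over the full vector including the open 85+ class.
#'
#' @param series an [age_series()].
#' @param run_length exclusion threshold (default 5).
#' @return `TRUE` to keep the country--year, `FALSE` to exclude it.
#' @export
zero_death_filter <- function(series, run_length = 5L) {
  max_zero_run(series$deaths) < run_length
}

#' Female births from total births via the sex ratio at birth
#'
#' With `ratio` male births per female birth, female births are
#' `total / (1 + ratio)`. Applied per maternal-age cell and to totals alike
#' (the conversion is linear).
#'
#' @param total_births total births (both sexes).
#' @param sex_ratio_at_birth male births per female birth (> 0), default 1.05.
#' @return female births.
#' @export
estimate_female_births <- function(total_births, sex_ratio_at_birth = 1.05) {
  if (sex_ratio_at_birth <= 0) stop_config("sex_ratio_at_birth must be > 0")
  total_births / (1 + sex_ratio_at_birth)
}

#' Aggregate single-year counts into 18 five-year bins
#'
#' Sums ages 0--4, 5--9, ..., 80--84 and the open 85+ class into 18 bins for
#' population, deaths, and female births (births converted through
#' [estimate_female_births()]). The age-0 versus ages-1--4 split of the first
#' bin is retained separately, because infant and child survival are combined
#' with fixed 0.2/0.8 weights during matrix construction.
#'
#' @param series an [age_series()].
#' @param sex_ratio_at_birth male births per female birth.
#' @return an object of class `binned_demography` with vectors of length 18
#'   and the infant/child split of bin 1.
#' @export
bin_to_five_year <- function(series, sex_ratio_at_birth = 1.05) {
  stopifnot(inherits(series, "age_series"))
  bin <- c(pmin(floor(0:84 / 5), 16) + 1, 18)
  sum_by_bin <- function(x) {
    out <- numeric(18)
    agg <- tapply(x, bin, sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  fb <- estimate_female_births(series$births_by_maternal_age, sex_ratio_at_birth)
  structure(list(
    country = series$country, year = series$year,
    population = sum_by_bin(series$population),
    deaths = sum_by_bin(series$deaths),
    female_births = sum_by_bin(fb),
    infant_population = series$population[1],
    infant_deaths = series$deaths[1],
    child_population = sum(series$population[2:5]),
    child_deaths = sum(series$deaths[2:5])
  ), class = "binned_demography")
}
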