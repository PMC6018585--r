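test_that("mortality schedule follows the Gompertz-Makeham law with clamping", {
  cfg0 <- small_config(makeham_a = 0, gompertz_b = 1e-15, infant_excess = 1)
  expect_equal(unname(make_mortality_schedule(cfg0)), rep(0, 86),
               tolerance = 1e-9)

  cfg1 <- small_config(makeham_a = 1, gompertz_b = 0.1, gompertz_c = 0.1)
  expect_equal(unname(make_mortality_schedule(cfg1)), rep(1, 86))

  # closed form a + b exp(c age) evaluated directly at three ages
  a <- 0.001; b <- 2e-5; cc <- 0.1
  cfg <- small_config(makeham_a = a, gompertz_b = b, gompertz_c = cc,
                      infant_excess = 1)
  r <- make_mortality_schedule(cfg)
  closed <- function(age) a + b * exp(cc * age)
  expect_equal(unname(r["80"]), closed(80), tolerance = 1e-12)
  expect_gt(r["80"], r["40"])
  expect_gt(r["40"], r["20"])

  # monotone non-decreasing over ages >= 30
  r30 <- r[as.character(30:84)]
  expect_true(all(diff(r30) >= 0))

  expect_error(synthetic_config(makeham_a = NaN), class = "transppm_config_error")
})

test_that("fertility schedule is hump-shaped, windowed, and normalised", {
  cfg <- small_config(fertility_peak_age = 28, fertility_width = 6,
                      tfr_scale = 1.0)
  f <- make_fertility_schedule(cfg)
  expect_equal(sum(f), 1.0, tolerance = 1e-9)
  expect_true(all(f[c(as.character(0:11), as.character(56:84), "85+")] == 0))
  expect_true(all(f["28"] >= f))

  expect_equal(sum(make_fertility_schedule(small_config(tfr_scale = 0))), 0)
  expect_error(synthetic_config(tfr_scale = -1), class = "transppm_config_error")
})

test_that("simulation is deterministic and emits nonnegative counts", {
  cfg <- small_config()
  d1 <- simulate_country_series(cfg)
  d2 <- simulate_country_series(cfg)
  expect_identical(d1, d2)
  expect_true(all(d1$population >= 0 & d1$deaths >= 0 & d1$births >= 0))
  expect_equal(nrow(d1), 2 * 5 * 86)

  cfgp <- small_config(noise = "poisson")
  p1 <- simulate_country_series(cfgp)
  p2 <- simulate_country_series(cfgp)
  expect_identical(p1, p2)
  expect_false(identical(d1$deaths, p1$deaths))
})

test_that("noiseless data round-trips to the configured rates exactly", {
  cfg <- small_config()
  df <- simulate_country_series(cfg)
  sl <- as_age_series_list(df)
  for (ci in 1:2) for (y in c(1960, 1964)) {
    s <- sl[[paste0(sprintf("C%02d", ci), ":", y)]]
    A <- build_ppm(bin_to_five_year(s, cfg$sex_ratio_at_birth))
    E <- expected_projection_matrix(cfg, ci, y)
    expect_equal(unclass(A), unclass(E), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("Poisson-noise survival estimates sit within 3 standard errors", {
  cfg <- synthetic_config(n_countries = 1, years = 1980,
                          base_population = 1e5, noise = "poisson", seed = 42)
  s <- as_age_series_list(simulate_country_series(cfg))[[1]]
  A <- build_ppm(bin_to_five_year(s, cfg$sex_ratio_at_birth))
  E <- expected_projection_matrix(cfg, 1, 1980)
  # subdiagonal: s_hat = 1 - 5 D / N, D ~ Pois(N q / 5) => se = 5 sqrt(N q / 5) / N
  dr <- make_mortality_schedule(cfg, 1)
  pop <- round(transppm:::pyramid_for_year(cfg, dr, 1980))
  bin <- c(pmin(floor(0:84 / 5), 16) + 1, 18)
  Nb <- as.numeric(tapply(pop, bin, sum))
  lam <- as.numeric(tapply(pop * dr / 5, bin, sum))
  se <- 5 * sqrt(lam) / Nb
  got <- unclass(A)[cbind(3:18, 2:17)]   # bins 2..17 (bin 1 uses the split)
  want <- unclass(E)[cbind(3:18, 2:17)]
  expect_true(all(abs(got - want) <= 3 * se[2:17] + 1e-12))
})

test_that("anomaly injection touches exactly the requested cells", {
  cfg <- small_config()
  df <- simulate_country_series(cfg)
  spec <- list(list(country = "C01", year = 1962,
                    zero_death_run_length = 5, start_age = 20))
  mod <- inject_anomalies(df, spec)
  hit <- mod$country == "C01" & mod$year == 1962 &
    mod$age %in% as.character(20:24)
  expect_true(all(mod$deaths[hit] == 0))
  expect_identical(mod[!hit, ], df[!hit, ])

  expect_identical(inject_anomalies(df, list()), df)
  expect_error(inject_anomalies(df, list(list(country = "XX", year = 1900,
                                              zero_death_run_length = 5))),
               class = "transppm_lookup_error")
})

test_that("a four-zero run survives the downstream exclusion filter", {
  cfg <- small_config(anomaly_spec = list(list(country = "C01", year = 1961,
                                               zero_death_run_length = 4)))
  sl <- as_age_series_list(simulate_country_series(cfg))
  expect_true(zero_death_filter(sl[["C01:1961"]], run_length = 5))
})
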