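test_that("spearman correlation handles monotone data and ties", {
  r <- spearman_rho(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r$rho_2dp, 1.00)
  expect_equal(spearman_rho(c(1, 2, 3), c(30, 20, 10))$rho_2dp, -1.00)

  # brute-force mid-rank oracle on a 6-point list with one tie
  x <- c(3, 1, 4, 1, 5, 9)       # the two 1s tie at mid-rank 1.5
  y <- c(2, 7, 1, 8, 2, 8)       # ties at ranks for 2,2 and 8,8
  midrank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  rx <- midrank(x); ry <- midrank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(x, y)$rho, oracle, tolerance = 1e-12)

  const <- spearman_rho(rep(1, 5), 1:5)
  expect_true(const$flagged)
  expect_true(is.na(const$rho))
})

test_that("spearman correlation is invariant under monotone transforms", {
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30) + 0.5 * x
    r0 <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(exp(x), y)$rho, r0, tolerance = 1e-12)
    expect_equal(spearman_rho(x, y^3)$rho, r0, tolerance = 1e-12)
    expect_equal(spearman_rho(rank(x), atan(y))$rho, r0, tolerance = 1e-12)
  }
})

test_that("parallel analysis retains nothing on pure noise", {
  set.seed(42)
  x <- matrix(rnorm(500 * 9), 500, 9)
  pa <- parallel_analysis(x, n_iter = 300, quantile = 0.95, seed = 7)
  expect_identical(pa$n_retained, 0L)
  expect_true(all(pa$bias >= -1))
  # retention is non-increasing in the quantile
  pa50 <- parallel_analysis(x, n_iter = 300, quantile = 0.50, seed = 7)
  expect_gte(pa50$n_retained, pa$n_retained)
})

test_that("parallel analysis finds a planted one-factor structure", {
  set.seed(43)
  n <- 500
  f <- rnorm(n)
  x <- cbind(sapply(1:4, function(i) 0.9 * f + sqrt(1 - 0.81) * rnorm(n)),
             matrix(rnorm(n * 5), n, 5))
  pa <- parallel_analysis(x, n_iter = 300, quantile = 0.95, seed = 7)
  expect_identical(pa$n_retained, 1L)

  # two perfectly correlated columns + noise: first adjusted exceeds second
  z <- rnorm(100)
  x2 <- cbind(z, z, matrix(rnorm(300), 100, 3))
  pa2 <- parallel_analysis(x2, n_iter = 200, quantile = 0.95, seed = 11)
  expect_gt(pa2$adjusted[1], pa2$adjusted[2])

  expect_error(parallel_analysis(matrix(rnorm(12), 3, 4), n_iter = 100, seed = 1),
               class = "transppm_validation_error")
  expect_identical(parallel_analysis(x, n_iter = 300, quantile = 0.95, seed = 7),
                   pa)  # deterministic given seed
})

test_that("PCA matches a dense eigendecomposition oracle", {
  set.seed(44)
  x <- matrix(rnorm(80), 20, 4) %*% matrix(runif(16, -1, 1), 4, 4)
  colnames(x) <- paste0("v", 1:4)
  pc <- pca_metrics(x, n_retained = 2)
  eo <- eigen(cor(x), symmetric = TRUE)
  expect_equal(pc$explained_variance_fraction, eo$values / 4, tolerance = 1e-9)
  for (k in 1:4) {
    # loadings match the eigenvector up to sign
    d <- min(sum(abs(pc$loadings[, k] - eo$vectors[, k])),
             sum(abs(pc$loadings[, k] + eo$vectors[, k])))
    expect_lt(d, 1e-8)
  }
  expect_equal(sum(pc$explained_variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$explained_variance_fraction) <= 1e-12))
})

test_that("PCA degenerate cases behave as the correlation model dictates", {
  z <- rnorm(30)
  two <- cbind(a = z, b = 2 * z + 1)
  pc <- pca_metrics(two, 1)
  expect_equal(pc$explained_variance_fraction[1], 1, tolerance = 1e-9)

  set.seed(45)
  iso <- matrix(rnorm(5000 * 4), 5000, 4)
  pciso <- pca_metrics(iso, 1)
  expect_equal(pciso$explained_variance_fraction,
               rep(0.25, 4), tolerance = 0.05)

  bad <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(pca_metrics(bad, 1), "b", class = "transppm_validation_error")
})

test_that("trend summaries aggregate by year and find the sub-one crossing", {
  m <- data.frame(country = "X", year = rep(2000:2004, each = 3),
                  lambda1 = rep(c(1.05, 1.02, 0.99, 0.97, 0.98), each = 3),
                  reactivity = 1:15)
  tr <- summarise_trends(m)
  expect_identical(tr$lambda1_below_1_year, 2002L)
  row <- tr$by_year[tr$by_year$metric == "reactivity" & tr$by_year$year == 2000, ]
  expect_equal(row$mean, 2)
  expect_equal(row$median, 2)

  one <- summarise_trends(m[m$year == 2000, ])
  r1 <- one$by_year[one$by_year$metric == "reactivity", ]
  expect_equal(r1$mean, mean(1:3))
  expect_equal(r1$q025, quantile(1:3, 0.025, names = FALSE))

  const <- summarise_trends(data.frame(year = 2000, lambda1 = rep(2, 4)))
  cr <- const$by_year
  expect_true(all(cr$mean == 2 & cr$q025 == 2 & cr$q975 == 2))
})

test_that("reactivity and inertia co-vary across a perturbed ensemble", {
  set.seed(46)
  cfg <- small_config()
  df <- simulate_country_series(cfg)
  sl <- as_age_series_list(df)
  recs <- do.call(rbind, lapply(sl, function(s) {
    b <- bin_to_five_year(s, cfg$sex_ratio_at_birth)
    transient_record(build_ppm(b), b$population)
  }))
  r <- spearman_rho(recs$reactivity, recs$inertia)
  expect_gt(r$rho, 0)
})
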