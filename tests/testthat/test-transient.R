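leslie2 <- matrix(c(0, 0.5, 2, 0), 2, 2)   # [[0,2],[0.5,0]]

test_that("eigendata sorts by magnitude and extracts a real dominant value", {
  ed <- eigendata(diag(c(2, 1, 0)))
  expect_equal(Re(ed$values), c(2, 1, 0))
  expect_equal(ed$lambda1, 2)

  # characteristic polynomial lambda^2 = 1 -> spectrum {+1, -1}
  ed2 <- eigendata(leslie2)
  expect_equal(sort(Re(ed2$values)), c(-1, 1), tolerance = 1e-12)
  expect_equal(ed2$lambda1, 1, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:100) {
    m <- Mod(eigendata(random_ppm())$values)
    expect_true(all(diff(m) <= 1e-12))
  }

  rot <- matrix(c(0, 1, -1, 0), 2, 2)  # spectrum {+i, -i}: no Perron root
  expect_error(eigendata(rot), class = "transppm_non_perron_error")
})

test_that("damping ratio is lambda1 over the subdominant magnitude", {
  expect_equal(damping_ratio(eigendata(diag(c(3, 1.5, 0)))), 2.0)
  expect_equal(damping_ratio(eigendata(leslie2)), 1.0, tolerance = 1e-12)
  expect_identical(damping_ratio(eigendata(diag(c(1, 0)))), Inf)

  set.seed(4)
  for (i in 1:50) expect_gte(damping_ratio(eigendata(random_ppm())), 1 - 1e-12)
})

test_that("standardisation fixes the dominant eigenvalue at one", {
  A <- diag(c(2, 1))
  expect_equal(scale_matrix(A, 1), A)
  expect_equal(scale_matrix(2 * diag(3), 2), diag(3))

  set.seed(5)
  for (i in 1:100) {
    A <- random_ppm()
    Ahat <- scale_matrix(A)
    expect_equal(eigendata(Ahat)$lambda1, 1, tolerance = 1e-9)
  }
  expect_error(scale_matrix(diag(2), 0), class = "transppm_degenerate_matrix")
})

test_that("structure normalisation yields proportions summing to one", {
  expect_equal(normalize_structure(c(2, 2, 0)), c(0.5, 0.5, 0))
  v <- c(0.25, 0.25, 0.5)
  expect_equal(normalize_structure(v), v)
  set.seed(6)
  for (i in 1:20)
    expect_equal(sum(normalize_structure(runif(18))), 1, tolerance = 1e-12)
  expect_error(normalize_structure(rep(0, 5)), class = "transppm_validation_error")
})

test_that("reactivity and inertia anchor at one for the stable structure", {
  set.seed(8)
  for (i in 1:20) {
    A <- random_ppm()
    ed <- eigendata(A)
    Ahat <- scale_matrix(A, ed$lambda1)
    w <- ed$stable_structure
    expect_equal(reactivity(Ahat, w), 1, tolerance = 1e-9)
    expect_equal(inertia(Ahat, w), 1, tolerance = 1e-6)
  }
})

test_that("the 2x2 triangular worked example matches the closed form", {
  Ahat <- matrix(c(1, 0, 1, 0.5), 2, 2)   # [[1,1],[0,0.5]], lambda1 = 1
  n0 <- c(0, 1)
  expect_equal(reactivity(Ahat, n0), 1.5)
  # Ahat^k = [[1, 2(1-0.5^k)],[0, 0.5^k]] => one-norm at k=100: 2 - 0.5^100
  expect_equal(inertia(Ahat, n0, 100), 2 - 0.5^100, tolerance = 1e-12)
  expect_equal(inertia(Ahat, n0, 1), reactivity(Ahat, n0))
})

test_that("a column-stochastic standardised matrix conserves the one-norm", {
  M <- matrix(c(0.3, 0.7, 0.6, 0.4), 2, 2)  # columns sum to 1
  set.seed(9)
  for (i in 1:10) {
    n0 <- normalize_structure(runif(2))
    expect_equal(reactivity(M, n0), 1, tolerance = 1e-12)
  }
})

test_that("transient indices are invariant to positive rescaling of A", {
  set.seed(10)
  for (i in 1:10) {
    A <- random_ppm()
    n0 <- normalize_structure(runif(18))
    r1 <- transient_record(A, n0)
    r2 <- transient_record(unclass(A) * 3, n0)
    expect_equal(r2$reactivity, r1$reactivity, tolerance = 1e-9)
    expect_equal(r2$inertia, r1$inertia, tolerance = 1e-7)
    expect_equal(r2$damping_ratio, r1$damping_ratio, tolerance = 1e-9)
    expect_equal(r2$lambda1, 3 * r1$lambda1, tolerance = 1e-9)
  }
})

test_that("inertia has converged by the default 100-step horizon", {
  set.seed(12)
  for (i in 1:10) {
    A <- random_ppm()
    ed <- eigendata(A)
    if (damping_ratio(ed) < 1.05) next   # converge only for decisive dominance
    Ahat <- scale_matrix(A, ed$lambda1)
    n0 <- normalize_structure(runif(18))
    expect_equal(inertia(Ahat, n0, 200), inertia(Ahat, n0, 100),
                 tolerance = 1e-4)
  }
})

test_that("reactivity and inertia equal brute-force powered one-norms", {
  set.seed(13)
  A <- random_ppm()
  Ahat <- scale_matrix(A)
  n0 <- normalize_structure(runif(18))
  pow <- function(M, k) { P <- diag(nrow(M)); for (i in seq_len(k)) P <- P %*% M; P }
  expect_equal(reactivity(Ahat, n0), sum(abs(pow(Ahat, 1) %*% n0)),
               tolerance = 1e-12)
  expect_equal(inertia(Ahat, n0, 100), sum(abs(pow(Ahat, 100) %*% n0)),
               tolerance = 1e-9)
})
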