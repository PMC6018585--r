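# shared fixtures: all test data is generated in code

small_config <- function(...) {
  synthetic_config(n_countries = 2, years = 1960:1964, ...)
}

# random Leslie-structured 18x18 matrix (valid ppm): fertility in the
# reproductive bins, survival on the subdiagonal, small stasis
random_ppm <- function() {
  A <- matrix(0, 18, 18)
  A[1, 4:10] <- runif(7, 0, 0.6)
  A[cbind(2:18, 1:17)] <- runif(17, 0.3, 0.999)
  A[18, 18] <- runif(1, 0, 0.3)
  new_ppm(A)
}

random_symmetric <- function(n = 6) {
  M <- matrix(rnorm(n * n), n, n)
  (M + t(M)) / 2
}

random_orthogonal <- function(n = 6) {
  qr.Q(qr(matrix(rnorm(n * n), n, n)))
}

jordan2 <- matrix(c(0, 0, 1, 0), 2, 2)  # [[0,1],[0,0]]
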