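#' Spearman rank correlation with mid-rank ties
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided p-value from the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. A constant input yields a flagged
#' undefined correlation rather than an error.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param digits rounding applied to the reported `rho_2dp` convenience field
#'   (summaries quote correlations to 2 decimal places).
#' @return list with `rho`, `p_value`, `n`, `rho_2dp`, and `flagged`
#'   (TRUE when either input is constant; `rho` is then `NA`).
#' @export
spearman_rho <- function(x, y, digits = 2) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                rho_2dp = NA_real_, flagged = TRUE))
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, rho_2dp = round(rho, digits),
       flagged = FALSE)
}

#' Spearman correlation matrix over a metrics table
#'
#' @param x numeric data.frame or matrix.
#' @return list with `rho` and `p_value` matrices.
#' @export
spearman_matrix <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  rho <- pval <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    r <- spearman_rho(x[, i], x[, j])
    rho[i, j] <- r$rho
    pval[i, j] <- r$p_value
  }
  list(rho = rho, p_value = pval)
}

#' Horn's parallel analysis with conservative percentile correction
#'
#' Compares the eigenvalues of the observed correlation matrix to those of
#' size-matched uncorrelated standard-normal data: over `n_iter` iterations,
#' the `quantile` (default 95th) percentile of the simulated k-th eigenvalue
#' defines the sampling bias at rank k as `percentile - 1`; the adjusted
#' observed eigenvalue is the observed value minus that bias, and components
#' are retained while the adjusted eigenvalue exceeds 1. The percentile
#' (rather than mean) correction is the conservative variant.
#'
#' @param x numeric data.frame or matrix (rows = cases, columns = variables;
#'   more rows than columns required).
#' @param n_iter simulation iterations (>= 100), default 1000.
#' @param quantile percentile used for the bias, default 0.95.
#' @param seed integer seed for the simulated data (mandatory, for
#'   reproducibility).
#' @return list with `observed`, `bias`, `adjusted` eigenvalue vectors and
#'   `n_retained`.
#' @export
parallel_analysis <- function(x, n_iter = 1000L, quantile = 0.95, seed) {
  x <- as.matrix(x)
  if (!all(is.finite(x)))
    stop(errorCondition("parallel analysis requires a complete table",
                        class = c("transppm_validation_error", "error")))
  n <- nrow(x); p <- ncol(x)
  if (n <= p)
    stop(errorCondition("need more rows than columns for parallel analysis",
                        class = c("transppm_validation_error", "error")))
  stopifnot(n_iter >= 100)
  if (missing(seed)) stop_config("parallel_analysis requires an explicit seed")
  observed <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  sims <- matrix(NA_real_, n_iter, p)
  for (b in seq_len(n_iter)) {
    r <- matrix(stats::rnorm(n * p), n, p)
    sims[b, ] <- eigen(stats::cor(r), symmetric = TRUE, only.values = TRUE)$values
  }
  qk <- apply(sims, 2, stats::quantile, probs = quantile, names = FALSE)
  bias <- qk - 1
  adjusted <- observed - bias
  # sequential retention: keep leading components while adjusted > 1
  keep <- adjusted > 1
  n_retained <- match(FALSE, keep, nomatch = length(keep) + 1L) - 1L
  list(observed = observed, bias = bias, adjusted = adjusted,
       n_retained = n_retained)
}

#' Principal component analysis on scaled and centred variables
#'
#' Standardises each column to zero mean and unit variance and
#' eigendecomposes the correlation matrix (via [stats::prcomp()]). Loading
#' lists per retained axis report the variables whose squared loading exceeds
#' 10% of the axis, in order of decreasing importance.
#'
#' @param x numeric data.frame or matrix.
#' @param n_retained number of components to keep scores for (>= 1),
#'   typically from [parallel_analysis()].
#' @return list with `loadings` (variables x components),
#'   `explained_variance_fraction`, `scores` (rows x retained), `n_retained`,
#'   and `top_loadings` (list of named loading vectors per retained axis).
#' @export
pca_metrics <- function(x, n_retained = 2L) {
  x <- as.matrix(x)
  stopifnot(n_retained >= 1)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop(errorCondition(paste("zero-variance column(s):",
                              paste(colnames(x)[sds == 0], collapse = ", ")),
                        class = c("transppm_validation_error", "error")))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  n_retained <- min(n_retained, ncol(pc$rotation))
  top <- lapply(seq_len(n_retained), function(k) {
    l <- pc$rotation[, k]
    keep <- l[l^2 > 0.10]
    keep[order(-abs(keep))]
  })
  list(loadings = pc$rotation, explained_variance_fraction = evf,
       scores = pc$x[, seq_len(n_retained), drop = FALSE],
       n_retained = n_retained, top_loadings = top)
}

#' Per-year trend summaries of every metric
#'
#' Mean, median, and 2.5%/97.5% quantiles of each metric by calendar year,
#' plus the first year in which the annual mean asymptotic growth rate drops
#' below 1 (NA if it never does). A plain replacement for smoothed trend
#' curves.
#'
#' @param metrics data.frame with a `year` column and numeric metric columns.
#' @return list with `by_year` (long data.frame: year, metric, mean, median,
#'   q025, q975) and `lambda1_below_1_year`.
#' @export
summarise_trends <- function(metrics) {
  stopifnot(nrow(metrics) > 0, "year" %in% names(metrics))
  cols <- setdiff(names(metrics), c("country", "year"))
  cols <- cols[vapply(metrics[cols], is.numeric, logical(1))]
  years <- sort(unique(metrics$year))
  rows <- list()
  for (m in cols) for (y in years) {
    v <- metrics[[m]][metrics$year == y]
    v <- v[is.finite(v)]
    if (length(v) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      year = y, metric = m, mean = mean(v), median = stats::median(v),
      q025 = stats::quantile(v, 0.025, names = FALSE),
      q975 = stats::quantile(v, 0.975, names = FALSE))
  }
  by_year <- do.call(rbind, rows)
  cross <- NA_integer_
  if ("lambda1" %in% cols) {
    lm <- by_year[by_year$metric == "lambda1", ]
    below <- lm$year[lm$mean < 1]
    if (length(below) > 0) cross <- min(below)
  }
  list(by_year = by_year, lambda1_below_1_year = cross)
}

#' Columns of the metrics table entering the multivariate analyses
#'
#' The analysis variables: year, asymptotic growth rate, damping ratio,
#' reactivity, inertia, and the three non-normality metrics (raw or scaled).
#' Rows with non-finite entries are excluded listwise.
#'
#' @param metrics full metrics data.frame (see [transient_record()]).
#' @param scaled use the standardised-matrix non-normality columns (default)
#'   or the raw ones.
#' @return list with `data` (complete-case numeric data.frame) and
#'   `n_excluded`.
#' @export
analysis_variables <- function(metrics, scaled = TRUE) {
  suffix <- if (scaled) "_scaled" else "_raw"
  cols <- c("year", "lambda1", "damping_ratio", "reactivity", "inertia",
            paste0("nn_", c("frobenius", "henrici", "ruhe"), suffix))
  x <- metrics[, cols]
  ok <- apply(x, 1, function(r) all(is.finite(as.numeric(r))))
  list(data = x[ok, ], n_excluded = sum(!ok))
}
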