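#' End-to-end run configuration
#'
#' Resolves the knobs of a full pipeline run: data source (synthetic
#' generator or a user-supplied CSV), the sex ratio at birth, the
#' zero-death-run exclusion threshold, the inertia horizon, optional
#' pseudospectra requests, and the parallel-analysis settings. The resolved
#' configuration is echoed (as YAML) next to the outputs of every run.
#'
#' @param synthetic a [synthetic_config()], used when `input_path` is NULL.
#' @param input_path optional CSV of user-supplied demography (schema of
#'   [write_demography_csv()]).
#' @param sex_ratio_at_birth male births per female birth, default 1.05.
#' @param run_length zero-death-run exclusion threshold, default 5.
#' @param horizon inertia horizon in 5-year timesteps, default 100.
#' @param pseudospectra NULL, or a list with `country_years` (data.frame of
#'   country, year), `resolution`, `margin`.
#' @param parallel list with `n_iter` and `quantile` for component retention.
#' @param scaled_pca use scaled non-normality metrics in the PCA.
#' @param out_dir output directory (created); NULL for an in-memory run.
#' @param seed top-level seed; sub-stage seeds are derived from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       input_path = NULL,
                       sex_ratio_at_birth = 1.05,
                       run_length = 5L,
                       horizon = 100L,
                       pseudospectra = NULL,
                       parallel = list(n_iter = 1000L, quantile = 0.95),
                       scaled_pca = TRUE,
                       out_dir = NULL,
                       seed = 1L) {
  structure(list(synthetic = synthetic, input_path = input_path,
                 sex_ratio_at_birth = sex_ratio_at_birth,
                 run_length = as.integer(run_length),
                 horizon = as.integer(horizon),
                 pseudospectra = pseudospectra, parallel = parallel,
                 scaled_pca = scaled_pca, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "transppm_stage_error")) stop(e)
    stop(errorCondition(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                        class = c("transppm_stage_error", class(e))))
  })
}

#' Run the full analysis pipeline
#'
#' Generate (or read) single-year demographic tables, apply the zero-death-run
#' exclusion filter, aggregate into 18 five-year bins, build the projection
#' matrices, compute the transient and non-normality metrics per retained
#' country--year, optionally compute pseudospectra grids, and run the
#' comparative layer (Spearman correlation matrix, parallel analysis + PCA,
#' per-year trend summaries). Country--years with degenerate bins (zero
#' population) are dropped and audited, mirroring the exclusion of
#' implausible data.
#'
#' Identical configurations (including seed) produce identical outputs. When
#' `out_dir` is set, writes: `metrics.csv`, `audit.csv`, `matrices.csv`
#' (long format), `correlations.csv`, `pca_loadings.csv`, `pca_scores.csv`,
#' `trends.csv`, `config.yaml`, and `pseudospectrum_<country>_<year>.csv` for
#' any requested grids.
#'
#' @param config a [run_config()].
#' @return (invisibly when writing) a list with `metrics`, `audit`, `ppms`,
#'   `correlations`, `parallel`, `pca`, `trends`, `pseudospectra`, and the
#'   resolved `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  series_list <- stage("ingest", {
    if (!is.null(config$input_path)) read_demography_table(config$input_path)
    else as_age_series_list(simulate_country_series(config$synthetic))
  })

  audit <- data.frame(country = character(), year = integer(),
                      rule = character(), detail = character(),
                      stringsAsFactors = FALSE)
  keep <- list()
  for (s in series_list) {
    if (!zero_death_filter(s, config$run_length)) {
      audit <- rbind(audit, data.frame(
        country = s$country, year = s$year, rule = "zero_death_run",
        detail = sprintf("longest zero-death run %d >= %d",
                         max_zero_run(s$deaths), config$run_length)))
    } else keep[[length(keep) + 1L]] <- s
  }

  ppms <- list()
  n0s <- list()
  for (s in keep) {
    res <- tryCatch({
      b <- stage("binning", bin_to_five_year(s, config$sex_ratio_at_birth))
      A <- build_ppm(b)
      list(A = A, n0 = b$population)
    }, transppm_degenerate_bin = function(e) e)
    if (inherits(res, "error")) {
      audit <- rbind(audit, data.frame(country = s$country, year = s$year,
                                       rule = "degenerate_bin",
                                       detail = conditionMessage(res)))
    } else {
      key <- paste(s$country, s$year, sep = ":")
      ppms[[key]] <- res$A
      n0s[[key]] <- res$n0
    }
  }

  metrics <- stage("metrics", do.call(rbind, lapply(names(ppms), function(k)
    transient_record(ppms[[k]], n0s[[k]], config$horizon))))

  grids <- list()
  if (!is.null(config$pseudospectra)) {
    ps <- config$pseudospectra
    req <- ps$country_years
    for (i in seq_len(nrow(req))) {
      key <- paste(req$country[i], req$year[i], sep = ":")
      if (is.null(ppms[[key]]))
        stop(errorCondition(sprintf("stage 'pseudospectra': no matrix for %s", key),
                            class = c("transppm_stage_error", "error")))
      box <- grid_bounds(eigen(unclass(ppms[[key]]), only.values = TRUE)$values,
                         margin = ps$margin %||% 0.2)
      grids[[key]] <- sigma_min_grid(ppms[[key]], box,
                                     resolution = ps$resolution %||% 201L)
    }
  }

  stats_out <- stage("comparative", {
    av <- analysis_variables(metrics, scaled = config$scaled_pca)
    if (nrow(av$data) > ncol(av$data)) {
      pa <- parallel_analysis(av$data, n_iter = config$parallel$n_iter,
                              quantile = config$parallel$quantile,
                              seed = config$seed + 1L)
      pc <- pca_metrics(av$data, n_retained = max(1L, pa$n_retained))
    } else {
      pa <- NULL; pc <- NULL
    }
    list(correlations = spearman_matrix(av$data), parallel = pa, pca = pc,
         n_excluded = av$n_excluded)
  })
  trends <- summarise_trends(metrics)

  out <- list(metrics = metrics, audit = audit, ppms = ppms,
              correlations = stats_out$correlations,
              parallel = stats_out$parallel, pca = stats_out$pca,
              trends = trends, pseudospectra = grids, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(x, f) utils::write.csv(x, file.path(config$out_dir, f),
                                          row.names = FALSE, quote = FALSE)
    wp(metrics, "metrics.csv")
    wp(audit, "audit.csv")
    write_ppm_stack(ppms, file.path(config$out_dir, "matrices.csv"))
    utils::write.csv(out$correlations$rho,
                     file.path(config$out_dir, "correlations.csv"), quote = FALSE)
    if (!is.null(out$pca)) {
      utils::write.csv(out$pca$loadings,
                       file.path(config$out_dir, "pca_loadings.csv"), quote = FALSE)
      utils::write.csv(out$pca$scores,
                       file.path(config$out_dir, "pca_scores.csv"), quote = FALSE)
    }
    wp(trends$by_year, "trends.csv")
    for (key in names(grids))
      write_pseudospectrum_csv(grids[[key]], file.path(
        config$out_dir, sprintf("pseudospectrum_%s.csv", gsub(":", "_", key))))
    cfg <- config
    cfg$synthetic <- unclass(cfg$synthetic)
    yaml::write_yaml(unclass(cfg), file.path(config$out_dir, "config.yaml"))
    return(invisible(out))
  }
  out
}
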