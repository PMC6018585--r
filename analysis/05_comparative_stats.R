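#!/usr/bin/env Rscript
# The multivariate comparison layer: Spearman correlations among the metrics,
# PCA (scaled and centred) with Horn's parallel analysis deciding how many
# components to keep (95th-percentile conservative correction), and per-year
# trend summaries in place of smoothed curves.

library(transppm)

metrics <- read.csv("results/metrics.csv")

av <- analysis_variables(metrics, scaled = TRUE)
cat(sprintf("analysis table: %d rows x %d variables (%d excluded as non-finite)\n",
            nrow(av$data), ncol(av$data), av$n_excluded))

cors <- spearman_matrix(av$data)
write.csv(round(cors$rho, 2), "results/correlations.csv")
cat(sprintf("spearman(reactivity, inertia) = %.2f\n",
            cors$rho["reactivity", "inertia"]))
cat(sprintf("spearman(damping_ratio, reactivity) = %.2f\n",
            cors$rho["damping_ratio", "reactivity"]))

pa <- parallel_analysis(av$data, n_iter = 1000, quantile = 0.95, seed = 20)
cat(sprintf("parallel analysis retains %d component(s); adjusted eigenvalues: %s\n",
            pa$n_retained, paste(round(pa$adjusted, 2), collapse = ", ")))

pc <- pca_metrics(av$data, n_retained = max(1, pa$n_retained))
write.csv(round(pc$loadings, 3), "results/pca_loadings.csv")
write.csv(round(pc$scores, 3), "results/pca_scores.csv")
cat(sprintf("retained components explain %.0f%% of the variance\n",
            100 * sum(pc$explained_variance_fraction[seq_len(pc$n_retained)])))
for (k in seq_len(pc$n_retained)) {
  l <- pc$top_loadings[[k]]
  cat(sprintf("  PC%d loads on: %s\n", k,
              paste(sprintf("%s (%.2f)", names(l), l), collapse = ", ")))
}

tr <- summarise_trends(metrics)
write.csv(tr$by_year, "results/trends.csv", row.names = FALSE)
cat(sprintf("annual mean lambda1 first drops below 1 in: %s\n",
            tr$lambda1_below_1_year))
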