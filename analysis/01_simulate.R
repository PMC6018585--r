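#!/usr/bin/env Rscript
# Generate the synthetic Eurostat-shaped study data: 3 countries observed
# 1960-1989, single-year female population, deaths and births by maternal
# age, with a 1955-1965 baby-boom cohort so the populations are away from
# their stable age structures. Two country-years carry injected anomalies
# (a 5-zero death run, and a 4-zero run that must survive the filter).

library(transppm)

dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(
  anomaly_spec = list(
    list(country = "C02", year = 1975, zero_death_run_length = 5, start_age = 30),
    list(country = "C03", year = 1980, zero_death_run_length = 4, start_age = 30)))

series <- simulate_country_series(cfg)
write_demography_csv(series, "results/demography.csv")

cat(sprintf("wrote results/demography.csv: %d rows, %d country-years\n",
            nrow(series), nrow(unique(series[, c("country", "year")]))))
cat(sprintf("injected anomalies: C02/1975 (run of 5 -> should be excluded), "))
cat(sprintf("C03/1980 (run of 4 -> should be retained)\n"))
saveRDS(cfg, "results/01_config.rds")  # handed to the later stages
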