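# transppm

Transient dynamics and non-normality of age-structured population
projection matrices.

## What this is for

Demographers and population ecologists project age-structured populations
with Leslie-type population projection matrices (PPMs):
**n**(t+5) = **A n**(t), where **A** carries age-specific survival on its
subdiagonal, fertility on its top row, and a stasis term letting the open
85+ class persist. The dominant eigenvalue λ₁ gives the asymptotic growth
rate — but real populations are never at their stable age structure, and
the short-term ("transient") booms and busts caused by structures like a
baby-boom bulge can matter more than the asymptotic trend.

Whether a matrix *can* amplify such deviations is governed by its
**non-normality** (the failure of **A**\***A** = **AA**\*), a property the
eigenvalues alone do not reveal. `transppm` implements the full analysis
chain:

- build 18×18 PPMs from single-year, Eurostat-shaped tables of female
  population, deaths and births by maternal age, with the standard
  cleaning rules (exclusion of country–years with ≥ 5 consecutive zero
  death counts; female births from the sex ratio at birth; negative
  survivals clamped to 0; infant/child survival combined as
  0.2·s(0) + 0.8·s(1–4); birth-flow fertility
  (5B/N)·√s(maternal)·√s(0–4));
- compute the damping ratio λ₁/|λ₂| and the case-specific transient
  indices on the standardised matrix **Â** = **A**/λ₁: reactivity
  ‖**Â n₀**‖₁ and inertia ‖**Â**¹⁰⁰ **n₀**‖₁;
- compute three scalar non-normality metrics on raw and standardised
  matrices — Frobenius √‖**A**\***A** − **AA**\*‖_F, Henrici
  √(‖**A**‖_F² − Σ|λ|²), Ruhe maxₖ|σₖ − |λₖ||;
- compute ε-pseudospectra, σ_min(z**I** − **A**) over a complex-plane
  grid, with an eigenvalue-encapsulation summary;
- compare everything across country–years: Spearman correlations, PCA
  with Horn's parallel analysis (95th-percentile conservative correction)
  for component retention, per-year trend summaries;
- generate synthetic demographic tables with *known* vital rates
  (Gompertz–Makeham mortality, Gaussian fertility, a moving baby-boom
  cohort), so the whole chain is validated by exact rate recovery without
  any external data.

## Worked example

```r
library(transppm)

cfg    <- synthetic_config(n_countries = 1, years = 1980)
series <- as_age_series_list(simulate_country_series(cfg))
b      <- bin_to_five_year(series[[1]], cfg$sex_ratio_at_birth)
A      <- build_ppm(b)
A
#> 18x18 population projection matrix (C01, 1980); 5-year timestep
#>   fertility bins: 3-12; subdiagonal survival range [0.288, 0.998]; stasis 0.035

round(transient_record(A, b$population)[, -(1:2)], 4)
#>   lambda1 damping_ratio reactivity inertia nn_frobenius_raw nn_henrici_raw
#> 1  0.9881        1.1227     1.0112  1.1029           1.0493         3.1819
#>   nn_ruhe_raw nn_frobenius_scaled nn_henrici_scaled nn_ruhe_scaled
#> 1      0.8961              1.0619            3.2202         0.9069
```

Read: λ₁ < 1, the population is asymptotically declining — yet reactivity
and inertia exceed 1, so its boom-distorted age structure amplifies
population size both immediately (+1.1% in the first step) and lastingly
(+10.3% after the transient period), relative to the asymptotic trajectory.
Each scaled non-normality value is the raw value divided by λ₁ exactly
(the metrics are homogeneous), so standardisation raises non-normality for
declining populations.

The complete workflow — simulate, clean and bin, build matrices, metrics,
pseudospectra, comparative statistics — is laid out as numbered drivers in
`analysis/01_simulate.R` … `analysis/05_comparative_stats.R`, each writing
its tables under `results/`. `run_pipeline()` does the same end-to-end in
one call. The methods vignette
(`vignettes/transient-nonnormality.Rmd`) documents the model, the
numerical choices and the generator's scope.

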