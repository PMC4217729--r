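# esrdmap

Small-area disease mapping of end-stage renal disease (ESRD) incidence, for
renal epidemiologists and registry analysts who need to turn area-level case
and population tables into smoothed incidence maps and ecological
deprivation effects.

Raw standardized incidence ratios (SIR = O/E) over small areas are noisy:
with a few dozen cases per area, the extremes of the raw SIR map are mostly
Poisson noise. `esrdmap` implements the standard hierarchical Bayesian
remedy end-to-end:

* **Standardization** — stratum-pooled (internal) or external reference
  rates, expected counts E_i by indirect standardization, crude and
  direct-standardized rates, raw SIRs with exact Poisson (gamma-quantile)
  95% intervals.
* **Deprivation** — the Townsend index from four census components
  (non-ownership, unemployment, overcrowding, no car), quintile
  classification and Q2–Q5 dummy covariates (Q1 = least deprived is the
  reference).
* **BYM smoothing** — a from-scratch Metropolis-within-Gibbs sampler for
  the Besag–York–Mollié model

  O_i ~ Poisson(E_i θ_i),  log θ_i = α + u_i + v_i + x_iᵀβ,

  with i.i.d. heterogeneity u_i ~ N(0, σ_u²), an intrinsic CAR spatial
  effect (v_i | v_−i ~ N(mean of neighbours, σ_v²/n_i), sum-to-zero
  constrained) and Gamma(0.5, 0.0005) hyperpriors on both precisions.
  Outputs: smoothed SIRs (posterior means of θ_i), 95% credible intervals,
  exceedance probabilities P(θ_i > 1), and covariate relative risks
  exp(β) with credible intervals. The sweep loop is compiled (Rcpp); a
  pure-R reference engine and a grid-quadrature oracle cross-check it.
* **Ecological associations** — area medians of case attributes (e.g. eGFR
  at dialysis initiation), Pearson correlation of log-SIR with area
  covariates, cause-of-disease proportions, deprivation vs late-referral
  (Spearman).
* **Synthetic registries** — a generator with known ground truth (lattice
  geography, age-sex-structured populations, an exactly-sampled intrinsic
  CAR risk field, a deprivation gradient driving risk through its
  quintiles) for parameter-recovery and calibration studies.
* **Pipeline** — `run_pipeline()` chains the stages from CSV/GAL inputs to
  CSV/GeoJSON outputs with a deterministic, hash-carrying run manifest; a
  thin CLI lives at `inst/cli/esrdmap.R`.

## Worked example

```r
library(esrdmap)

# a 169-area synthetic region: 7 years, overall crude rate calibrated to
# 163 cases per million person-years, quintile RRs 1.18/1.28/1.30/1.44
reg <- simulate_region(generator_spec(seed = 42))

rates <- internal_reference_rates(reg$population, years = 7)
E <- expected_counts(reg$population, rates, years = 7)
O <- observed_counts(reg$population)
raw <- sir_table(O, E)                      # raw SIRs span 0.41-2.06

fit <- fit_bym(model_data(O, E, reg$adjacency,
                          quintile_dummies(reg$townsend)),
               bym_config(seed = 1))
fit
#> BYM fit: 169 units, 25000 kept draws
#> Smoothed SIR range: 0.54-1.63
#> Covariate relative risks:
#>  term   rr rr_low rr_high
#>    Q2 1.28   1.12    1.45
#>    Q3 1.37   1.21    1.55
#>    Q4 1.35   1.19    1.53
#>    Q5 1.54   1.35    1.74
```

Smoothing pulls the raw SIR spread (0.41–2.06) in to 0.54–1.63: low-count
areas shrink toward their neighbourhood level, while well-supported
extremes survive. The quintile relative risks read as risk multipliers
versus the least-deprived fifth of areas — here a 28%–54% excess with
intervals excluding 1, a recovery of the generator's deprivation gradient
(true RRs 1.18–1.44) within posterior uncertainty. Per-area results
(`fit$summary`) carry the smoothed SIR, credible bounds, exceedance
probability and a significance flag (interval excludes 1).

Area-level association of log smoothed SIR with median eGFR at initiation:

```r
med <- area_median(reg$cases$unit_id, reg$cases$egfr,
                   units = fit$summary$unit_id)
pearson_log_sir(fit$summary$smoothed_sir, med$value)
#> $r [1] 0.036   $p [1] 0.64   $n [1] 169
```

The generator draws eGFR independently of area risk, so the near-zero
correlation is the correct answer here.

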