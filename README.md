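# cortexeval

Statistical evaluation framework for regional cortical thickness
measurement pipelines.

## The problem

Regional mean cortical thickness — one value in mm per region of the
62-region Desikan–Killiany–Tourville (DKT) parcellation — is a standard
derived phenotype in structural MRI. Competing measurement pipelines
produce systematically different values from the same scans, and no
voxel-level ground truth exists to rank them. `cortexeval` ranks pipelines
by the *usefulness* of their numbers as biomarkers, entirely at the level
of tidy per-region tables. It is aimed at methods developers and imaging
statisticians who need a reproducible, testable harness for such
comparisons.

Four criteria are implemented, plus repeatability:

- **Age prediction** (cross-sectional): Monte-Carlo cross-validated RMSE
  of a random-forest regression
  `AGE ~ VOLUME + GENDER + T(DKT_1) + ... + T(DKT_62)`
  over repeated stratified 80/20 resplits.
- **Lifespan profiles**: per-region OLS `T(DKT_i) ~ GENDER + AGE`,
  predictions at 25/50/75 years per gender, normalized by the single
  maximum predicted cell (radar values), with a paired t-test between
  pipelines.
- **Variance ratio** (longitudinal, unsupervised): per region a Bayesian
  hierarchical linear mixed-effects model

      Y_ij ~ N(a_i + b_i t_ij, sigma^2)
      a_i ~ N(alpha_0, tau^2)      b_i ~ N(beta_0, rho^2)
      alpha_0, beta_0 ~ N(0, 10^2)   sigma, tau, rho ~ Cauchy+(0, 5)

  fitted by a conditionally conjugate Gibbs sampler (half-Cauchy priors
  via inverse-gamma parameter expansion; slice-sampling fallback), and the
  ratio `r = tau/sigma` of between-subject to residual variability,
  summarized by its posterior median and 95% credible interval. Larger `r`
  means the measurement separates individuals better from noise.
- **Diagnostic contrasts** (longitudinal, supervised): per region a REML
  mixed model of change from baseline on baseline covariates with
  diagnosis-specific trajectory slopes and crossed subject/site random
  intercepts; Tukey (studentized-range) p-values for the LMCI−CN, AD−LMCI
  and AD−CN trajectory contrasts, Benjamini–Hochberg FDR across regions.
- **Scan–rescan ICC**: two-way random-effects, average-measures ICC(2,2)
  from the subject × acquisition ANOVA mean squares.

Because the multi-site cohorts such analyses are usually run on cannot be
redistributed, the package includes a first-class synthetic-data module
(`cohort_config()`, `generate_cross_sectional()`,
`generate_longitudinal()`, `generate_scan_rescan()`,
`emulate_pipeline_pair()`) that emulates their statistical structure,
including a three-group longitudinal cohort (197 CN / 324 LMCI / 142 AD,
visits every 6 months to 36 months) and paired "pipeline A vs pipeline B"
measurement variants. See `vignettes/cortexeval-methods.Rmd` for the full
model documentation.

## Worked example

```r
library(cortexeval)

cfg  <- cohort_config(age_range = c(55, 90), n_sites = 10, seed = 42)
long <- generate_longitudinal(cfg)
pair <- emulate_pipeline_pair(long$table, cfg)

mc   <- mcmc_config(n_chains = 2, n_iterations = 1200, n_warmup = 400,
                    seed = 42)
fit  <- fit_region_lme(region_observations(pair$A, "lh_ENT"), mcmc = mc,
                       region = "lh_ENT")
print(fit)
#> <region_posterior lh_ENT> 663 subjects, 4641 obs, 1600 draws
#>   r = 3.003 [2.820, 3.195]   max R-hat = 1.003
```

The left entorhinal variance ratio is ~3: between-subject spread is about
three times the residual noise, so this (synthetic) pipeline separates
individuals well. Running all 62 regions for both emulated pipelines
(`analysis/05_variance_ratio.R`) prints:

```
median r: A = 2.98, B = 2.68; A higher in 62/62 regions
```

— pipeline B is pipeline A plus extra measurement noise, which inflates
`sigma` only, so its ratio is lower in every region, exactly the behavior
the criterion is designed to detect. The supervised criterion
(`analysis/06_longitudinal_contrasts.R`) on the same cohort prints, for
pipeline A:

```
LMCI-CN : 59/62 regions FDR-significant, median log10 p = -5.23
AD-LMCI : 60/62 regions FDR-significant, median log10 p = -4.57
AD-CN   : 62/62 regions FDR-significant, median log10 p = -300.00
```

reflecting the generated atrophy ordering CN > LMCI > AD, and the
scan–rescan stage (`analysis/04_icc.R`) gives `median ICC 0.945` for
pipeline A at the default generator settings.

## The analysis workflow

The numbered scripts under `analysis/` run the full evaluation as a
narrative sequence, writing all tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R      # cohorts + pipeline pair
Rscript analysis/02_age_prediction.R        # MC-CV age RMSE per pipeline
Rscript analysis/03_lifespan_radar.R        # lifespan models, radar table
Rscript analysis/04_icc.R                   # scan-rescan ICC
Rscript analysis/05_variance_ratio.R        # Bayesian LME, r per region
Rscript analysis/06_longitudinal_contrasts.R# Tukey contrasts + FDR
```

`run_full_evaluation(run_manifest(...))` performs the same pipeline from a
single seeded manifest and records md5 checksums of every output.

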