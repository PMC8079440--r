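---
title: "Evaluating cortical thickness pipelines with cortexeval: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cortical thickness pipelines with cortexeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexeval)
```

## The evaluation problem

Cortical thickness — the distance in mm between the gray/white interface
and the pial surface, averaged within each of the 62 regions of the
Desikan–Killiany–Tourville (DKT) parcellation — is a widely used imaging
biomarker of development, aging and neurodegeneration. Different
measurement pipelines (classical registration-based streams, deep-learning
streams, cross-sectional versus longitudinally tailored variants) produce
systematically different regional values from the same scans, and there is
no voxel-level ground truth to arbitrate between them. The practical
question is therefore not "which pipeline is *correct*" but "which
pipeline's numbers are more *useful* as a biomarker".

`cortexeval` implements a statistical evaluation framework built around
that question. It operates entirely at the level of tidy per-region tables
(one row per subject and visit, 62 thickness columns) and provides four
complementary criteria:

1. **Age prediction** (cross-sectional): how well do the regional values
   predict chronological age out of sample?
2. **Lifespan profiles**: are the regional thickness profiles predicted
   across the lifespan anatomically sensible and comparable between
   pipelines?
3. **Variance ratio** (longitudinal, unsupervised): how large is
   between-subject variability relative to residual (within-subject)
   variability?
4. **Diagnostic contrasts** (longitudinal, supervised): how well do
   trajectories separate CN, LMCI and AD groups?

plus scan–rescan repeatability (ICC). Because the original multi-site
cohorts cannot be redistributed, the package ships a synthetic-data module
that emulates their *statistical structure*, so every criterion can be
exercised, tested, and calibrated end to end.

## The synthetic-data generators

All generators share a `cohort_config()` object and draw their random
streams from seeds derived by stable hashing (`derive_seed()`), so results
are bit-reproducible and adding one generator call never perturbs another.

**Cross-sectional.** One visit per subject, ages uniform on a configured
range (default 4–94 years, emulating pooled lifespan cohorts), sites as
uniform labels. Per region $k$:
$$Y_{ik} = \alpha_0^k + \gamma^k\,\mathrm{age}_i + g\,\mathrm{gender}_i
          + u_i\,\tau_k + \varepsilon_{ik},$$
with a subject factor $u_i \sim N(0,1)$ shared across regions (so one
subject is globally thick or thin) and residual sd $\sigma_k$. Age enters
linearly with region-specific slope $\gamma^k$ (default $-0.01$ mm/year);
nonlinear lifespan trajectories are deliberately omitted because the
downstream lifespan models are linear.

**Longitudinal.** Three diagnosis groups with default sizes 197 CN /
324 LMCI / 142 AD and visits every 6 months up to 36 months. Per subject
and region,
$$a_{ik} \sim N(\alpha_0^k, \tau_k^2), \quad
  b_{ik} \sim N(\beta_0^k + \delta_{d(i)}, \rho_k^2), \quad
  Y_{ikj} = a_{ik} + s_{\mathrm{site}(i),k} + b_{ik} t_j
            + \varepsilon_{ikj},$$
with $\varepsilon \sim N(0, \sigma_k^2)$. **Time is in months and all
slopes are mm/month** — a unit convention stated here prominently because
month-labelled visit schedules make months the natural clock; the
diagnosis offsets default to $0 / {-0.002} / {-0.004}$ mm/month for
CN/LMCI/AD, i.e. accelerating atrophy with disease severity, at the scale
of reported entorhinal atrophy rates. A site random intercept
($sd = 0.02$ mm by default) makes the site term of the supervised model
identifiable. Optional dropout truncates each subject's schedule at the
first missed visit with per-visit retention probability (default 1).

**Scan–rescan.** Two same-day acquisitions sharing a subject's true value
$\,\alpha_0^k + N(0,\tau_k^2)$ with independent residuals of sd
$\sigma_k$.

**Two pipelines.** Pipeline B adds a constant bias (default 0.02 mm) and
independent cell-wise Gaussian noise (default 0.05 mm) to pipeline A's
table: a minimal model of two software pipelines measuring the same scans,
which is all the downstream comparisons require.

Default variance scales are $\tau_k = 0.30$, $\sigma_k = 0.10$,
$\rho_k = 0.005$ — values at which regional thickness has the
between-subject spread, measurement noise and slow atrophy rates typical
of real regional tables. Default region means are anatomically plausible
(entorhinal thickest at 3.6 mm, pericalcarine thinnest at 1.7 mm) with the
entorhinal maximum guaranteeing that lifespan profiles normalize against
an entorhinal reference cell at the youngest age. The right-hemisphere
(+0.005 mm) and male (+0.02 mm) margins are smaller than OLS estimation
noise at desk-scale cohort sizes, so which hemisphere/gender wins the
reference cell is not a stable property — only region and age are.

What the generators do **not** emulate: realistic nonlinear lifespan
curvature, region-specific covariance structure beyond the single shared
subject factor, site effects on cross-sectional means, age/diagnosis
dependence of ICV, missing-not-at-random dropout, and any imaging-level
artifact (motion, segmentation failure). Passing tests therefore
demonstrate that the *statistical machinery* is correct and calibrated
under its assumed model — not that any particular real pipeline is good.

## The hierarchical model and the variance ratio

The unsupervised longitudinal criterion fits, per region,
$$Y_{ij} \sim N(a_i + b_i t_{ij},\ \sigma^2), \quad
  a_i \sim N(\alpha_0, \tau^2), \quad
  b_i \sim N(\beta_0, \rho^2),$$
$$\alpha_0, \beta_0 \sim N(0, 10^2), \qquad
  \sigma, \tau, \rho \sim \mathrm{Cauchy}^+(0, 5),$$
and summarizes the posterior of the **variance ratio** $r = \tau/\sigma$
by its median and central 95% credible interval. A region with large $r$
separates individuals from measurement noise; comparing $r$ across
pipelines region by region is the criterion.

Two notational choices deserve a note. The $N(0,10)$ prior on the
population mean and slope is interpreted with 10 as a *standard deviation*
(the convention of mainstream Bayesian sampling software); it is wide at
mm scale either way and the choice is configurable via `prior_config()`.
And although the interval is often loosely called a confidence interval in
this context, what the model produces — and what `r_ci_95` is — is a
central 95% *credible* interval from empirical posterior percentiles.

### The Gibbs sampler

`fit_region_lme()` samples the joint posterior with a Gibbs scheme in
which every update is conditionally conjugate. The half-Cauchy priors are
represented by the inverse-gamma mixture
$$s^2 \mid \psi \sim \mathrm{IG}(\tfrac12, 1/\psi), \qquad
  \psi \sim \mathrm{IG}(\tfrac12, 1/A^2),$$
whose marginal for $s$ is exactly $\mathrm{Cauchy}^+(0, A)$; both $s^2$
and $\psi$ then have inverse-gamma full conditionals. Subject intercepts
and slopes are updated from their Normal full conditionals in a single
vectorized pass. A direct **slice-sampling** update of the scales
(`method = "slice"`) is provided as an independent route; the two must
agree, and the test suite checks that they do on a toy instance.

Convergence is monitored with split-$\widehat R$ and an
autocorrelation-based effective sample size per parameter; $\widehat R >
1.1$ sets a `converged = FALSE` flag on the result (a warning flag, never
an exception, so a long multi-region run is not aborted by one sticky
region). Defaults are 4 chains × 2000 iterations with 1000 warmup;
summaries pool post-warmup draws across chains. Posterior quantiles use
the inverse-ECDF (type-1) empirical percentile, which makes summaries
exactly reproducible by a sort-based recomputation.

Three independent cross-checks validate the sampler: (i) with the scales
held fixed, the posterior of $\alpha_0$ has a Gaussian closed form (GLS
after integrating the random effects), matched to ~3 decimals; (ii) on an
intercept-only toy instance the random effects and $\alpha_0$ can be
integrated analytically and the 2-D posterior of $(\tau,\sigma)$ evaluated
by brute-force grid integration (`grid_posterior_tau_sigma()`), matched
within 5%; (iii) parameter recovery and ~95% credible-interval coverage
over replicated simulated cohorts. Thickness values are not centered or
scaled internally — the ratio is scale-free and the priors are wide at mm
scale — and the test suite verifies ×10-rescale and +1 mm-shift
invariance of $r$ empirically.

Per-region fits use seeds derived as `hash(master seed, region code)`, so
`fit_all_regions()` results are independent of execution order.

## The age-prediction harness

`run_age_prediction()` estimates out-of-sample age-prediction RMSE of
$$\mathrm{AGE} \sim \mathrm{VOLUME} + \mathrm{GENDER}
  + \sum_{i=1}^{62} T(\mathrm{DKT}_i)$$
by Monte-Carlo cross-validation: 500 (configurable) independent random
80/20 train/test resplits, stratified by dataset/site label, with a
random-forest regression refitted on each training fold. "Permutations"
here means *resplits*, not label permutations. Splits are keyed to sorted
subject ids, so row order is irrelevant.

Forest hyperparameters are fixed and logged: 500 trees and — deliberately
— `mtry` equal to **all** 64 features, i.e. bagged regression trees.
With the conventional $p/3$ feature subsampling, a single strongly
informative region among 61 uninformative ones is selected in only a third
of the splits along any tree path, and a perfectly age-coding region
yields a mean RMSE of ~7 years; with bagging the same fixture achieves
~0.3 years. Since the harness exists to detect differences in
age-relevant signal between pipelines, the sensitive choice is the right
default, and it is configurable. Calibration is tested both ways:
pure-noise features must give mean RMSE within 15% of the best-constant
benchmark $(b-a)/\sqrt{12}$ for ages uniform on $(a,b)$, and the
perfect-signal fixture must come in under 2 years.

## Lifespan models, radar values, ICC

Per region, `fit_lifespan_models()` runs OLS of thickness on gender (0/1
numeric) and age; `predict_relative_thickness()` evaluates all pipelines'
models at 25/50/75 years for both genders and divides by the single
maximum predicted cell (flagged `is_reference`), giving radar-style
relative profiles in $(0, 1]$. Requesting an age outside the fitted range
warns but proceeds — extrapolating to 75 years is exactly what one does
with cohorts that stop earlier. `paired_region_ttest()` compares two
pipelines' matched predicted cells with a two-sided paired t-test; a
zero-variance nonzero difference is reported as the $p \to 0$ limit with a
warning rather than dividing by zero.

Scan–rescan repeatability uses the two-way random-effects,
*average-measures* intraclass correlation — ICC(2,k) with $k = 2$, the
"average random rater" reading — computed from the subject × acquisition
ANOVA mean squares. Among the ICC variants this is the one that treats
acquisitions as random and scores the average of the repeats, which
matches how scan–rescan tables are used; the estimator choice is a
documented interpretation since "average random rater" admits exactly this
reading. ICC is affine-invariant and equals 1 exactly for identical
acquisitions.

## The supervised longitudinal model

`run_longitudinal_evaluation()` implements, per region,
$$\Delta Y \sim Y_{bl} + \mathrm{AGE}_{bl} + \mathrm{ICV}_{bl}
  + \mathrm{APOE}_{bl} + \mathrm{GENDER} + \mathrm{DIAGNOSIS}_{bl}
  + \mathrm{VISIT}{:}\mathrm{DIAGNOSIS}_{bl} + (1 \mid \mathrm{ID})
  + (1 \mid \mathrm{SITE}),$$
fitted by REML (`lme4`). Design choices:

- $\Delta Y$ is computed for **every** follow-up visit (not last visit
  only): the model contains VISIT, which implies repeated change rows per
  subject.
- VISIT is continuous in months, so the interaction (with no VISIT main
  effect) parameterizes one trajectory slope per diagnosis group; the
  three contrasts LMCI−CN, AD−LMCI, AD−CN are differences of those terms
  and are invariant to factor coding. A categorical-visit option exists.
- APOE enters as an allele count (the generator emits 0/1/2; a carrier
  collapse is a one-liner upstream if desired).
- ICV is rescaled to $10^6$ mm³ internally so the fixed-effects columns
  are comparable in magnitude.
- A singular fit (typically the site variance at the zero boundary) sets
  `boundary_fit_flag` rather than failing: zero is a legitimate REML
  estimate for a small variance component.
- Tukey handling: each contrast's p-value uses the studentized-range
  distribution with 3 means; degrees of freedom are containment-style
  (observations − fixed-effect rank − subjects), a conservative and
  transparent choice at these sample sizes (where `ptukey` is essentially
  flat in df).
- FDR: Benjamini–Hochberg across the 62 regions **within each contrast**
  (matching per-contrast reporting); a global-family option exists.
  Reported $\log_{10} p$ values are floored at $10^{-300}$ to avoid
  $-\infty$ in output files.

## Numerical and reproducibility choices

- Seeds: one master seed; per-stage, per-region, per-permutation and
  per-chain seeds derived by a stable polynomial string hash modulo
  $2^{31}-1$.
- Generated thickness is clipped at $10^{-3}$ mm to preserve the
  positivity invariant; clipping events are counted and reported as an
  attribute (they are rare at default settings, a few cells per hundred
  thousand).
- Tables round-trip exactly through CSV: numeric cells are written with 17
  significant digits.
- Degenerate inputs have explicit contracts: single-visit-only data is a
  non-identifiability error; fewer than 2 chains, empty schedules and
  negative variance scales are configuration errors; a missing region
  column is reported by name.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run at
deliberately modest sizes chosen to exercise every code path with
comfortable Monte-Carlo margins: recovery studies use 20 replicates of a
200-subject × 7-visit design; invariance checks one 100-subject cohort;
the harness calibration 300 subjects × 50 resplits; the null-FDR study a
150-subject three-group cohort over all 62 regions; full per-region fits
use 2 chains × 1200 iterations after verifying that defaults (4 × 2000)
give indistinguishable summaries on this data.

## Known limitations

- The sampler is specific to this hierarchical model (no general
  probabilistic-programming layer), and intercept–slope correlation is
  assumed zero, as written in the model.
- The generators are structural emulators; none of the numerical results
  here transfer to any real pipeline's absolute performance.
- Containment df for the Tukey contrasts is an approximation (exact
  finite-sample df for mixed models is itself an open choice);
  alternatives like Satterthwaite would change p-values negligibly at
  these sizes.
- The BH procedure controls FDR under independence/PRDS; regions are
  independent under the generator but positively correlated in real data,
  where BH remains valid but conservative interpretations should follow.
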