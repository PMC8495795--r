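---
title: "Models and methods behind evotraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evotraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

evotraj analyses growth-rate trajectories from serial-transfer evolution
experiments. This vignette explains the models and estimators, the
parameters that matter, what the simulator does and does not emulate, and
the numerical and design choices made where more than one defensible
option existed.

## Growth rates from optical-density curves

A kinetic plate reader yields, per well, optical density over 24–72 h at a
few-minute cadence. `estimate_max_growth_rate()` implements the classical
max-slope estimator: subtract the blank, floor the corrected OD at a small
positive epsilon, take log2, slide a window of `window_points` consecutive
readings, fit an OLS line of log2(OD) on time in each window, and return
the steepest slope — in doublings per hour, since the log is base 2 —
among windows whose raw OD span exceeds `min_od_delta`.

Assumptions: the culture passes through a quasi-exponential phase long
enough to contain at least one full window; OD is proportional to cell
density over the fitted range (checked in practice with a count
calibration, `calibrate_od()`); noise is roughly multiplicative.

Tunable parameters:

* `window_points` (readings; default 13, i.e. one hour at a 5-minute
  cadence). The window is the estimator's only smoothing. Because the
  estimate is a **maximum** over many overlapping windows, per-window
  slope noise converts into upward bias; the variance of a window slope
  scales as 1/(w · span²), so noisy data need long windows. Guidance: for
  slow growers measured at a fine cadence, size the window to about one
  doubling time of the expected rate (e.g. 81 readings for ~0.15
  doublings/h at 5-minute cadence). The validation studies in the test
  suite use that rule; the short default suits fast growers and
  low-noise readers.
* `min_od_delta` (absorbance; default 0.02): minimum raw OD span a window
  must cover. It excludes lag- and noise-only windows, at the cost of
  ignoring the earliest exponential readings; with saturating curves this
  trades a small downward bias (windows sit slightly into the logistic
  bend) against robustness to baseline noise.
* `blank`: an explicit per-well baseline when available; otherwise the
  median of the first three readings. The floor epsilon (1e-4 absorbance)
  merely prevents log of non-positive values; it is far below any signal.

A curve in which no window passes the span filter is reported as
`NA_real_` — a no-growth signal, deliberately distinct from an estimate
of zero.

## Trajectory models and AICc comparison

Per-plate population rates `R_P` are modelled over cumulative generations
`N` by three mean curves: linear `R0 + th1*N`, power `R0 + th2*N^th1`
(exponent constrained to (0, 1.5)), and hyperbolic `R0 + th1*N/(th2+N)`
(half-saturation `th2 > 0`). The hyperbolic asymptote `R0 + th1` encodes a
growth-rate optimum; the power law encodes unbounded decelerating gains.

Numerics: for a fixed nonlinear constant both remaining parameters are
linear, so fitting is a one-dimensional profiled optimisation — exact,
fast, and free of starting-value pathologies in the linear directions.
The 1-D search runs L-BFGS-B from a deterministic start grid
(half-saturation starts {0.1, 0.5, 1, 2, 5} x median N on the log scale;
exponent starts {0.1, 0.3, 0.5, 0.7, 0.9}), ties broken by lower SSE then
lower `th2`, followed by a golden-section polish (`tol = 1e-12`) around
the incumbent. On noiseless hyperbolic data the parameters are recovered
to better than 1e-6 relative error, and the test suite checks the
optimised SSE against a 200x200 grid-search oracle.

AICc uses the Gaussian least-squares form `n*ln(SSE/n) + 2k +
2k(k+1)/(n-k-1)` with `k` counting the residual variance (so linear k=3,
power/hyperbolic k=4). Only AICc differences matter for evidence ratios
`ER = exp(0.5*dAICc)`; the orientation implemented is candidate minus
reference, so ER > 1 reads "evidence against the candidate". A perfect
fit (SSE = 0) is reported as -Inf, ordering below every finite value, and
exact ties go to the model with fewer parameters.

The three-model comparison pools both evolution temperatures by default
(records assayed at the home temperature); fitting per temperature is a
matter of subsetting the records first, and both views are legitimate —
pooling was chosen as the default because the decelerating shape, not the
arm-specific constants, is the hypothesis under test.

The factorial model `R_P ~ N + G + ET + interactions` is fit as a
fixed-basis regression-spline surrogate: a cubic B-spline in `N` with 8
evenly spaced interior knots over the observed generation range, factors
as indicator contrasts, interactions as basis-by-indicator products, all
by OLS. No penalisation, no smoothing-parameter or basis-dimension
selection: every candidate term set faces the same fixed basis, so AICc
comparisons isolate which interactions the data support. Generations are
min-max scaled to [0, 1] (and indicators are 0/1) before fitting, so
coefficients read as scaled effects. This is deliberately simpler than a
penalised additive model: it keeps the estimator fully specified and
reproducible, at the cost of some smoothness adaptivity.

## Binning, variance components, repeatability

Bins are centred on multiples of the width and half-open `[low, high)`
(width 250: bin 0 = [0, 125), bin 250 = [125, 375), ...; width 1000:
bin 0 = [0, 500)). The printed ranges such bins are usually reported with
share endpoints, so a convention was required: boundary values go to the
upper bin.

Within a bin, the nested model `R_P ~ G + S(G)` (optionally
`+ ET + G:ET`) treats replicate population as a random effect and
estimates its variance component by expected mean squares:
`vc = (MS_S(G) - MS_E)/n0`, with `n0` the standard unequal-group-size
coefficient (the per-replicate count when balanced). Moment estimation
was chosen over REML because the surrounding analysis is ANOVA-based and
the balanced-design estimate has a closed form a reader can verify by
hand; negative estimates are truncated to zero and flagged. "Scaled to
the mean" is implemented as VC/(grand mean)^2 — a squared
coefficient-of-variation analogue, making arms with different mean rates
comparable — and repeatability is its reciprocal, reported as `Inf` when
the component is exactly zero rather than capped at an arbitrary number.
Raw components are always reported alongside. The analysis unit is the
plate-level rate `R_P` (plates weighted equally, not wells).

Inferential machinery: factorial ANOVAs use sequential sums of squares
for balanced data (where all SS types coincide) and Type-II otherwise;
Levene's test is the classic mean-centred one-way ANOVA on absolute
deviations (a median-centred variant is available); pairwise genotype
tests are pooled-variance Student t tests, matching the ANOVA framework;
Tukey–Kramer comparisons use the studentized-range distribution with the
unequal-n correction. Bonferroni thresholds always take the comparison
count `m` from the caller — the family size is a property of the study
design (42 pairwise genotype comparisons, 24 trade-off tests, 7 ANOVA
terms in the emulated design), never something to infer from the data at
hand.

## Correlated responses and demography

Trade-off classification compares each population's endpoint rates at the
alternate assay temperature with the same lineage's earliest-window rates
at that temperature — a real-time comparison contract, reflecting designs
where ancestors are assayed alongside rather than revived from frozen
stock. The default endpoint is the 6,000-generation bin. Classification
is three-way (increase / no-change / trade-off) against the Bonferroni
threshold.

The temperature-specificity scan runs the full factorial ANOVA on the
per-population bin means at both assay temperatures and extracts the
evolution-by-assay temperature interaction per bin; within each assay
temperature the evolution-temperature effect size is reported as its
R-squared share, SS_ET/SS_total of that stratum. Cross-temperature
coupling is the per-bin Pearson correlation of paired population means,
with the 95% confidence ellipse derived from the eigendecomposition of
the 2x2 covariance (semi-axes = sqrt(eigenvalue x chi-square 0.95
quantile, 2 df)).

Demography is closed-form: generations/day = log2(end/start density), and
the effective population size is the harmonic mean of sizes at the
discrete generations of the daily growth cycle — for a doubling series
from the bottleneck, a geometric sum.

## What the simulator emulates, and what it does not

`simulate_evolution_experiment()` draws the full design: 3 genotypes x 4
replicates x 2 evolution temperatures, assayed at both temperatures.
Defaults encode the emulated study's conditions: ancestral rates
0.021–0.045 doublings/h with one clearly slower genotype; hyperbolic
gains with half-saturation around 400–700 generations; asymptotic gains
near 0.05–0.09 doublings/h built by a convergence rule (initially slower
genotypes gain more, fully so at the hot temperature, partially at the
cold one); assays every 25 generations to 6,500; plate-level noise SD
0.008 doublings/h and replicate-divergence SD 0.012 (cold) / 0.006 (hot)
doublings/h, the cold arm diverging more.

Replicate divergence is a Gaussian random walk across assay occasions
with per-step variance proportional to the generation increment,
normalised so the cumulative SD at the final generation equals
`sigma_replicate`. A walk, not a static offset, because divergence
accumulates: it produces variance-component trajectories that grow over
time and — combined with genotype convergence — a total among-population
variance that peaks at intermediate generations, which is exactly the
behaviour the repeatability analysis is designed to resolve.
Temperature-specific adaptation is a configurable deficit ramped in at
the alternate assay temperature after an onset generation (default 2,500,
null amplitude), letting null and late-onset-specificity scenarios share
one generator. Within-plate well noise defaults to half the plate-level
SD (the instrument's within-plate repeatability is rarely reported
separately; the parameter is exposed) and is centred so the plate rate is
exactly the well mean. OD noise is multiplicative log-normal on the
density signal with an additive baseline, matching absorbance-reader
behaviour.

Not emulated: mutation, selection and drift at the genetic level (the
simulator works directly on the phenotype), conjugation or ploidy
effects, plate spatial artefacts, batch effects between assay days, and
any drift in the instrument blank. Passing recovery tests on these
simulations therefore demonstrates that the estimators are correct and
calibrated for data with this statistical structure — not that real
plate-reader data meet that structure; the count-calibration and
residual-diagnostic outputs exist to check the latter.

## Validation study sizes

The test suite and `scripts/acceptance.R` validate at these scales,
chosen to give comfortable Monte-Carlo margins at desk-scale runtimes:
noiseless recovery across rates 0.05–1.0 doublings/h; 100 noisy curves
(5% multiplicative noise); 100 simulated experiments for model
identification (assays every 50 generations); 500 nested designs (3 x 4 x
10) for variance-component recovery; 2,000 null simulations each for
ANOVA, Levene and Tukey–Kramer calibration; 200 simulated experiments
each for the repeatability contrast and the late-onset specificity scan.

## Known limitations

* The max-slope estimator is biased upward on very noisy data when the
  window is short (a max over noisy slopes), and biased downward when the
  qualifying windows sit into the logistic bend; the window rule above
  manages, but does not remove, this trade-off.
* Lag time and carrying capacity — fitness components in their own right —
  are not estimated.
* Moment-based variance components can be noisy in small bins; truncation
  at zero makes per-bin estimates slightly positively biased near zero
  even though the untruncated estimator is unbiased.
* The spline surrogate fixes its basis; trajectories with structure much
  sharper than the knot spacing would be under-fit relative to a
  penalised additive model.
* Evidence-ratio model choice inherits AICc's assumptions (Gaussian
  residuals, independent errors); autocorrelated assay noise within a
  population would overstate evidence.
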