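# evotraj

Analysis of fitness trajectories from long-term serial-transfer evolution
experiments, for experimental evolutionists who track microbial growth
rates on kinetic plate readers: estimating maximum growth rates from
optical-density curves, fitting decelerating trajectory models, measuring
the *repeatability* of evolution through variance components, and
quantifying how temperature-specific adaptation is.

The package emulates a study design of 24 populations — 3 founding
genotypes x 4 replicate populations x 2 evolution temperatures (24 and
37 °C) — propagated by daily transfer for 6,500 generations and assayed at
both temperatures throughout, and implements the statistics such a design
calls for.

## The models and statistics at the core

**Growth rate.** Each well's kinetic OD trace is reduced to the maximum
growth rate in doublings per hour: the steepest ordinary-least-squares
slope of log2(OD − blank) over a sliding window of consecutive readings,
restricted to windows whose raw OD span exceeds a threshold (which
excludes lag- and noise-only stretches). Well rates average to the
per-plate population rate *R*<sub>P</sub>.

**Trajectory models.** *R*<sub>P</sub> as a function of cumulative
generations *N* is fit by least squares under three candidates:

- linear: *R*<sub>0</sub> + Θ<sub>1</sub>·*N*
- power law: *R*<sub>0</sub> + Θ<sub>2</sub>·*N*<sup>Θ1</sup>, 0 < Θ<sub>1</sub> < 1.5
- hyperbolic: *R*<sub>0</sub> + Θ<sub>1</sub>·*N* / (Θ<sub>2</sub> + *N*)

compared by small-sample corrected AIC, AICc = *n*·ln(SSE/*n*) + 2*k* +
2*k*(*k*+1)/(*n*−*k*−1), and evidence ratios ER = e^(0.5·ΔAICc). A
fixed-basis regression-spline surrogate of the factorial model
*R*<sub>P</sub> ~ *N* + *G* + *ET* + interactions tests whether genotypes
(*G*) change differently at the two evolution temperatures (*ET*).

**Repeatability.** Plate rates are binned into 250- or 1,000-generation
windows; nested ANOVA (*R*<sub>P</sub> ~ *G* + *S*(*G*), replicate *S*
random) yields the replicate-within-genotype variance component by
expected mean squares, VC = (MS<sub>S(G)</sub> − MS<sub>E</sub>)/*n*<sub>0</sub>.
The VC scaled by the squared grand mean is a squared-CV analogue;
its reciprocal is the repeatability statistic — large when independent
replicates of a genotype stay similar.

**Correlated responses.** Per-population t tests against the lineage's own
earliest-window rates classify increase / no-change / trade-off at the
alternate temperature (Bonferroni-controlled with an explicit comparison
count); per-bin factorial ANOVAs extract the evolution-by-assay
temperature interaction; Pearson correlations with 95% confidence-ellipse
geometry track the coupling of performance across temperatures. Serial-
transfer demography: generations/day = log2(end/start density), and the
effective population size as the harmonic mean of sizes across the
discrete generations of the daily cycle.

A fully seedable simulator generates every input with known ground truth —
lagged-logistic OD curves, and whole experiments with genotype-specific
hyperbolic gain curves, random-walk replicate divergence, plate- and
well-level noise, and a configurable temperature-specificity deficit — so
every stage is validated by parameter recovery.

## Worked example

```r
library(evotraj)

cfg <- simulation_config(seed = 7)        # 3 genotypes x 4 reps x 2 temps
ds  <- simulate_evolution_experiment(cfg)
ds
#> evolution_dataset: 24 populations, 12528 plate records (simulated)
#>   generations 0-6500; assay temps: 24, 37

home <- subset(ds$records, assay_temp == evolution_temp)
compare_trajectory_models(home)
#> Trajectory model comparison (best first):
#> # A tibble: 3 x 6
#>   model          k   sse    aicc delta_aicc evidence_ratio
#>   <chr>      <int> <dbl>   <dbl>      <dbl>          <dbl>
#> 1 hyperbolic     4  1.63 -51679.         0        1   e  0
#> 2 power          4  1.69 -51487.       192.       4.32e 41
#> 3 linear         3  1.92 -50664.      1015.       2.89e220
#> best: hyperbolic
```

The hyperbolic model wins decisively (ΔAICc ≥ 192, so the evidence ratio
against the power law is ~10^41): growth rates rise fast early and
plateau, as decelerating adaptation predicts. The fitted curve

```r
attr(compare_trajectory_models(home), "fits")$hyperbolic
#> trajectory_fit [hyperbolic]: R0 = 0.03896, theta1 = 0.065709, theta2 = 583.65
#>   n = 6264, k = 4, SSE = 1.634, AICc = -51678.84
```

says the pooled ancestral rate is ~0.039 doublings/h, the asymptotic gain
~0.066 doublings/h, with half the gain realised by generation ~584.
Repeatability in one 250-generation bin (centre 2,000; populations evolved
and assayed at 24 °C):

```r
b24 <- subset(ds$records, generation >= 1875 & generation < 2125 &
              evolution_temp == "24" & assay_temp == "24")
nested_anova_vc(b24)
#> Variance components (expected mean squares):
#>   genotype: 1.784e-05   replicate-within-genotype: 7.628e-05   residual: 6.816e-05
#>   mean-scaled replicate VC: 0.01295   repeatability: 77.21
```

Replicates of the same genotype have diverged measurably (VC 7.6e-05
squared doublings/h — here more than the genotype component), giving a
repeatability of ~77. Demography of the transfer regime:

```r
generations_per_day(2500, 275000)       # hot-arm daily doublings
#> [1] 6.78136
effective_population_size(25000 * 2^(0:6))
#> [1] 88188.98
```

`run_pipeline(pipeline_config(seed = 1))` chains all stages (records →
bins → model comparison → variance components → pairwise tests →
trade-offs → interaction scan → cross-temperature correlation) and writes
stamped delimited-text tables.

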