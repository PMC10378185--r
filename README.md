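# clonesteer

Density-dependent selection between co-existing clones of cultured cell
lines — growth-law fitting, transcriptomic biomarkers of growth parameters,
r/K trade-off detection, and serial-passage simulations that predict how
culture schedules steer clonal composition.

## What it does, and for whom

Cancer cell lines typically harbor several karyotypically distinct clones.
In the r/K framework of life-history theory, a clone can trade a high
maximum growth rate *r* (wins while the flask is sparse) against a high
carrying capacity *K* (wins near confluence). For experimentalists and
modelers working with heterogeneous lines, `clonesteer` answers three
questions:

1. **What are a line's growth parameters?** Cell-count time series are fit
   with the Verhulst (logistic), Richards, or Gompertz law,

   dN/dt = r·N·(1 − (N/K)^v)   (Richards; v = 1 gives Verhulst),

   compared by adjusted R² and AIC, and checked for practical
   identifiability by likelihood profiling (is the 95% profile CI for a
   parameter bounded, given the noise?). A stopping rule declares the
   experiment finishable once the inferred K changes by < 4% when the last
   20% of time points are truncated.

2. **Which clones trade r against K?** Per-cell gene-set activity is scored
   with a rank-based AUC statistic (area under the recovery curve of set
   members within the top 5% of ranked genes), linear biomarkers
   δ = a·p + c map activity p to r or K (trained on a subset of lines,
   FDR-validated on the full panel), and clone pairs are tested with
   Student's t-tests plus the ratio criterion
   (τ_r < 1 ∧ τ_K > 1) ∨ (τ_r > 1 ∧ τ_K < 1).

3. **Can the composition be steered?** A multi-clone competition ODE with a
   shared occupancy term Σ N_j/K_j is integrated across serial passages
   (seed → grow → harvest → dilute), and the outcome metric
   sgn(N_K − N_r)·log10 max(N_r, N_K) is mapped over seeding-density ×
   splitting-interval grids.

A first-class synthetic-data generator emulates all inputs (noisy sigmoid
growth curves in the experimentally observed parameter ranges,
clone-structured negative-binomial expression with planted driver gene
sets), so every stage is testable end-to-end with known ground truth.

## Worked example

```r
library(clonesteer)

## fit a growth law to a (here: simulated) daily count series
p     <- growth_params(r = 0.8, K = 1e6, N0 = 2e4)
curve <- generate_growth_curve(p, 0:18, noise_cv = 0.05, seed = 11,
                               population_id = "NCI-demo")
fit <- fit_growth(curve, "verhulst")
fit
#> verhulst growth fit (NCI-demo)
#> Growth parameters: r = 0.8705 /day, K = 9.745e+05, v = 1, N0 = 1.552e+04
#>   n = 19, RSS = 1.42638e+10, adj-R2 = 0.9932, AIC = 450.2

## which law do the data support?
fits <- lapply(c("verhulst", "richards", "gompertz"), fit_growth,
               curve = curve)
rank_growth_models(fits)
#>      model k         rss    adj_r2      aic
#> 1 verhulst 3 14263804734 0.9932238 450.2142
#> 2 richards 4 14174167927 0.9927854 452.0944
#> 3 gompertz 3 21220936183 0.9899187 457.7622

## is K practically identifiable from this curve?
profile(fit, "K")
#> Profile likelihood for K (estimate 9.745e+05)
#>   95% CI: [9.626e+05, 9.901e+05] — practically identifiable

## serial passages: an r-specialist vs a K-specialist, seeded sparse and
## split weekly — the fast clone overtakes immediately and fixes
sys <- clone_system(c("fast", "dense"), r = c(1.0, 0.6), K = c(1e6, 3e6))
out <- run_passage_series(sys, passage_schedule(2e3, 7, 10), c(0.2, 0.8))
out
#> Passage series: 2 clones, 10 passage(s), 2000 cells/cm^2 every 7 d
#>   final harvest frequencies:
#>     fast    dense
#> 0.999988 0.000012
crossing_passage(out, "fast", "dense")
#> [1] 1
```

The fit recovers the generating parameters within the 5% counting noise
(r̂ = 0.87 vs 0.8; K̂ = 0.97×10⁶ vs 10⁶), the parsimony penalty ranks the
true 3-parameter law above Richards, and the profile shows a bounded K
interval — for a curve truncated to its exponential phase the upper bound
escapes to infinity instead. In the passage simulation, sparse weekly
splitting realizes the fast clone's advantage: its harvest frequency
exceeds the dense clone's from the first passage and approaches fixation by
passage 10; near-confluent daily splitting would freeze the starting
composition instead (see `steering_heatmap()`).

The full pipeline — files in, artifacts out — is `run_pipeline()` over a
`pipeline_config()` (counts CSV, expression MTX/CSV, annotation TSV,
gene-set GMT); `run_synthetic_pipeline()` chains the same stages in memory
on a `synthetic_scenario()`. The vignette
(`vignettes/density-dependent-selection.Rmd`) documents the models,
defaults, and design choices.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline analysis from scratch at the given seed:
it builds the default synthetic scenario, fits all eight growth curves,
scores activity, trains and validates the biomarker models, scans every
cell line for r/K trade-offs, and runs the steering simulation for the
flagged clone pair, logging each stage's outcome before writing the JSON
report to `--out`.
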