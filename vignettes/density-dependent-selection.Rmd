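---
title: "Modeling density-dependent selection between co-existing clones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling density-dependent selection between co-existing clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesteer)
```

## The problem

Cultured cancer cell lines are rarely homogeneous: several karyotypically
distinct clones usually co-exist in the same flask. Life-history theory
predicts that such clones can trade off a high maximum growth rate *r*
(advantageous while the culture is sparse) against a high carrying capacity
*K* (advantageous near confluence). If such r/K trade-offs exist, routine
culture decisions — how densely to seed, how often to split — become
selection pressures that shift the clonal composition, deliberately or not.

`clonesteer` implements the full chain needed to study this in vitro:

1. fit growth laws to cell-count time series and decide which law the data
   support (`fit_growth()`, `rank_growth_models()`, `profile()`);
2. score per-cell gene-set activity from single-cell RNA expression with a
   rank-based AUC statistic (`aucell_scores()`);
3. learn linear biomarkers that map pathway activity to *r* and *K*
   (`fit_biomarker()`, `validate_biomarkers()`);
4. predict per-cell growth parameters, compare clones, and flag r/K
   trade-offs (`clone_predictions()`, `scan_cell_line()`);
5. simulate clonal competition across serial passages to find culture
   schedules that steer the composition (`run_passage_series()`,
   `steering_heatmap()`).

A synthetic-data generator (`synthetic_scenario()`,
`generate_population()`, `generate_scenario_curves()`) emulates every input
with known ground truth, so the whole chain is testable without external
data.

## Growth laws

Three standard laws are supported, written so that *r* (1/day) and *K*
(cells) keep the same meaning in each:

* **Verhulst (logistic)**: $dN/dt = r N (1 - N/K)$, with closed form
  $N(t) = K / (1 + ((K - N_0)/N_0) e^{-rt})$.
* **Richards (generalized logistic)**: $dN/dt = r N (1 - (N/K)^v)$. The
  exponent $v > 0$ — the *loss of contact inhibition* — controls how
  abruptly growth shuts down near capacity; $v = 1$ recovers Verhulst.
  Closed form $N(t) = K (1 + Q e^{-rvt})^{-1/v}$, $Q = (K/N_0)^v - 1$.
* **Gompertz**: $dN/dt = r N \ln(K/N)$ (0 at $N = 0$, its limit), closed
  form $N(t) = K (N_0/K)^{\exp(-rt)}$. The literature contains several
  Gompertz parameterizations; this one is chosen because it preserves the
  $(r, K)$ reading shared with the other two laws.

Internal state is an absolute cell count. Experimental work reports surface
densities (cells/cm²); `density_to_count()`/`count_to_density()` convert at
the boundary, with a default surface of 25 cm² (a T25 flask).

## Fitting and model choice

`fit_growth()` minimizes the residual sum of squares between observed
counts and the closed-form trajectory over $(r, K, N_0)$ — plus $v$ for
Richards — with parameters optimized on the log scale. The error model is
i.i.d. Gaussian noise on counts, the default of least-squares growth-curve
fitting; the log-likelihood, AIC, and profile likelihoods all derive from
the RSS under this model. Logistic-type fits are initialization-sensitive,
so optimization is multi-started from a small heuristic grid ($K_0 \in \{1,
2, 5\}\times$ max count; $r_0$ from a log-linear fit of the sub-half-maximum
counts; $N_{0,0}$ = first count; $v_0 \in \{0.5, 1, 2\}$). Failure from
every start yields a flagged, non-converged result rather than an error;
zero-variance counts are flagged degenerate.

`AIC` is exposed through the standard `logLik`/`AIC` generics (full
Gaussian likelihood, `df` = growth parameters + noise variance). This
differs from the dropped-constant form $n\ln(\mathrm{RSS}/n) + 2k$ by the
additive constant $n(1 + \ln 2\pi)$, which cancels in every comparison on
the same curve — and comparisons are AIC's only use here. Ties are broken
toward fewer parameters. An RSS of exactly zero (interpolation) is floored
at a machine-epsilon multiple of the total sum of squares so the likelihood
stays finite; fits at the floor should be read as "interpolating", not
compared by likelihood.

**Practical identifiability.** `profile()` fixes one parameter on a grid,
re-optimizes the rest (walking outward from the estimate, warm-starting
each point at its neighbor's solution), and reports the 95% region where
the profile log-likelihood is within $\chi^2_1(0.95)/2 \approx 1.92$ of the
maximum. A parameter is practically identifiable when that region is
bounded inside the grid. Default grids are 41 points, log-spaced over
$[\hat\theta/100,\ 100\,\hat\theta]$ for $K$, $v$ and $N_0$; for $r$ a
linear grid over $[\hat\theta/3,\ 3\,\hat\theta]$ is used instead, because
a linear grid over the four-decade bracket would place almost no points
near the estimate. Counts still in the exponential phase are the canonical
failure: they constrain only $r$, so the upper confidence bound for $K$
(and for Richards' $v$) escapes any finite grid.

**Stopping criterion.** `stopping_criterion()` declares a growth experiment
finishable when the inferred $K$ is stable: refitting with each contiguous
truncation of the last 20% of time points must change $\hat K$ by less than
4%. "Any subset" of trailing points is read as the contiguous truncations
(drop the last 1, 2, …, m points), not the $2^m$ power set: the criterion
probes stability of $\hat K$ as the experiment ends, and non-contiguous
deletions inside the tail add cost without adding information.

## Rank-based gene-set activity

`aucell_scores()` re-implements the area-under-the-recovery-curve activity
statistic. Within each cell, genes are ranked by decreasing expression; the
recovery curve counts gene-set members among the top $x$ genes for $x = 1,
\dots, \lceil 0.05\,G\rceil$ (top 5% of all $G$ genes in the matrix — the
threshold is over the whole matrix, not per-cell detected genes, and is
configurable). The score is the area under this curve divided by the area
of the ideal curve for the same set size and threshold, hence exactly in
$[0, 1]$, with 1 meaning the whole set occupies the top ranks and 0 meaning
no member is in the top fraction. Because only ranks enter, scores are
invariant to depth normalization, log transforms, or unit changes.

Count data are full of ties; tie order is implementation-defined in rank
statistics, so ties are broken by a random permutation drawn once per cell
from a fixed seed (default 42), making scores reproducible. Cells with
fewer than 200 detected genes are removed first (`filter_cells()`, boundary
inclusive). All cell lines are scored jointly in one matrix; no further
batch correction is applied.

## Biomarker models

For every (pathway, cell-cycle grouping, target) combination,
`fit_biomarker()` regresses the per-cell-line fitted parameter on the cell
line's median pathway activity, $\delta = a\,p + c$, by ordinary least
squares — one observation per cell line, medians taken over G0G1, S, G2M,
or all cells (`median_activity_by_group()`). Cell-cycle grouping matters
because cycle phase is among the strongest modulators of pathway activity.
Models are ranked by adjusted R² (ties: smaller p, then name) and the top
five per target are carried into validation: a refit on the full cell-line
panel (training + validation lines — the refit uses all lines, which is the
stricter reading of "repeated to include the remaining lines" and is
configurable), with Benjamini–Hochberg FDR across the tested models
*within each target parameter* — the narrowest defensible family —
and confirmation at adjusted p < 0.05.

## Clone-level inference and trade-off detection

`predict(biomarker, activity)` maps each cell's activity to a predicted *r*
or *K*; `clone_predictions()` groups predictions by clone, using only the
cells of the phase grouping each biomarker was fitted on, and drops clones
with fewer than 2 usable cells (mirroring the exclusion of clones with
insufficient phase representation). For every unordered clone pair,
`tradeoff_test()` runs two-sided *equal-variance* Student t-tests — the
classic test, not Welch, configurable — on the per-cell *r* and *K*
predictions and computes the mean ratios $\tau_r = \bar r_x/\bar r_y$,
$\tau_K = \bar K_x/\bar K_y$ (arithmetic means; medians are a config
option). A trade-off requires both $p \le 0.1$ *and* opposing ratios:
$(\tau_r < 1 \wedge \tau_K > 1) \vee (\tau_r > 1 \wedge \tau_K < 1)$. No
multiplicity correction is applied across clone pairs at this step,
matching the procedure being reproduced; with two independent tests at
$\alpha = 0.1$ plus the direction constraint, the null flag rate is below
$\alpha^2$.

## Clonal competition and steering

Clones of one cell line compete through shared space:

$$\frac{dN_i}{dt} = N_i\, r_i \left(1 - \Big(\sum_j N_j/K_j\Big)^{v}\right),$$

with one occupancy term $\sum_j N_j/K_j$ damping every clone (shared $v$,
default 1 for clone simulations). Below the capacity surface
($\sum_j N_j(0)/K_j < 1$) the occupancy rises monotonically toward 1 and
never crosses it, so **no clone ever shrinks** — the package treats this
nonnegativity as a numerically tested invariant under that precondition
(the analytic statement is not reproduced here), and `run_passage_series()`
refuses seedings on or above the surface.

An important consequence: whenever growth is positive, every clone's log
size grows at $r_i$ times the same shared factor, so the *frequency* of the
fastest clone is non-decreasing between splits. Density-dependent selection
therefore acts through *how much* of the r-clone's advantage each schedule
lets it realize: sparse seeding and long intervals give long bursts of
near-exponential growth (r selection), while near-confluent seeding and
daily splitting compress growth to almost nothing and freeze the
composition (K selection = delaying, possibly beyond any practical horizon,
the decline of the K-clone). The heat-map metric
$\mathrm{sgn}(N_K - N_r)\,\log_{10}\max(N_r, N_K)$ at the final harvest is
positive where the K-clone is still ahead and negative once the r-clone has
overtaken; with both clones seeded equally the r-clone is never behind, so
schedules are compared from the harvest frequencies of an initially
K-dominant culture.

Each passage seeds `density × area` cells at the current frequencies,
integrates the ODE for `interval` days, and records harvest sizes and
frequencies; dilution is deterministic (no stochastic bottleneck — a known
limitation at very low clone frequencies), harvest happens exactly at the
splitting interval, and no extinction floor is applied, so arbitrarily
small frequencies remain exact.

## Numerical choices

* ODE integration uses a built-in adaptive Dormand–Prince 5(4) pair
  (`rtol = 1e-8`, `atol = 1e-6`, the `ode45` contract); Verhulst
  trajectories agree with the closed form to better than $10^{-6}$
  relative, and a fixed-step RK4 oracle cross-checks the rest in the test
  suite.
* Single-population fitting never integrates: all three laws have closed
  forms.
* Profile re-optimizations inherit warm starts; the profile maximum is
  required (and tested) to match the unconstrained maximum within $10^{-6}$
  log-likelihood units.

## The synthetic world

`synthetic_scenario()` states the world once; generators only add noise, so
changing a seed changes realizations, never structure.

* **Panel**: 8 cell lines (5 training, 3 validation). Growth rates span
  0.35–1.0/day (doubling times ~17–48 h, typical of gastric cancer lines);
  seeding densities span the observed 4.98–38.64×10³ cells/cm² and
  carrying capacities 1.92–15.32×10⁵ cells/cm² on 25 cm². Capacities are
  assigned by a fixed permutation so *r* and *K* are essentially
  uncorrelated across lines (Pearson ≈ −0.24), as observed experimentally.
* **Sampling**: daily counts with 5% multiplicative log-normal noise, for
  as long as it takes the line to just pass its plateau, capped to the
  observed 6–21-day window — emulating the stop-at-stable-K rule.
* **Clones**: two per line. Line 1 carries the planted trade-off (±25% in
  *r* against ∓25% in *K*); every other line's clones differ by ±15% in
  both parameters *in the same direction* — significantly different but
  not a trade-off, so exactly one pair in the whole panel should be
  flagged.
* **Expression**: negative-binomial counts (mean 2, size 2 — ~25% dropout
  per gene, realistic sparsity for droplet data), 1000 genes, 40 cells per
  clone, phases drawn at (0.6, 0.2, 0.2) for G0G1/S/G2M. Two disjoint
  20-gene driver sets are scaled by $1 + 4z$ where $z$ is the clone's *r*
  (resp. *K*) normalized to $[0,1]$; 23 equally sized decoy sets carry no
  signal. The ×5 maximal boost keeps driver activity approximately linear
  in the parameter while leaving per-cell scores visibly noisy.

What a green test establishes: the estimators recover the parameters that
generated data *of this structure* — monotone rank signal, independent
cells, correct clone labels, no batch effects, no library-size confounds.
What it cannot establish: robustness to mislabeled clones, to copy-number
driven co-expression structure, to batch effects between cell lines, or to
the biomarker relation being nonlinear — on real data those remain the
user's responsibility to check.

## Known limitations

* The biomarker step is univariate per pathway; correlated pathways can
  shadow each other in the top-5 ranking.
* Frequencies below the detection limit of any real assay are still
  propagated exactly; interpreting them literally over many passages
  ignores demographic stochasticity.
* The equal-variance t-test is as specified, but clones with very unequal
  cell counts and variances would be better served by Welch
  (`var_equal = FALSE`).
* Growth-curve noise is treated as i.i.d. Gaussian on counts; counting
  error on dense images is more plausibly multiplicative, which makes the
  late (large-count) points dominate the RSS. The profile-likelihood
  verdicts inherit this choice.
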