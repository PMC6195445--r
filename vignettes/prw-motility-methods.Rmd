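---
title: "Persistent random walk analysis of cell motility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent random walk analysis of cell motility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prwfit)
```

## The model

The persistent random walk describes a cell whose velocity
$\mathbf{v}(t)$ is a stationary two-dimensional Ornstein–Uhlenbeck
process: mean zero, per-axis variance $S^2/2$ (so the root-mean-square
speed is $S$), and exponential autocorrelation
$\langle \mathbf{v}(t)\cdot\mathbf{v}(t+\tau)\rangle = S^2 e^{-\tau/P}$
with persistence time $P$. Integrating the velocity gives the Fürth
mean-squared displacement

$$\langle D^2(t) \rangle \;=\; 2 S^2 P \left[\, t - P\left(1 -
e^{-t/P}\right) \right],$$

which is ballistic ($S^2 t^2$) for $t \ll P$ and diffusive with slope
$2S^2P = 4\mu$ for $t \gg P$, where $\mu = \tfrac12 S^2 P$ is the random
motility coefficient (`motility_coefficient()`), the 2D case of
$\mu = S^2P/n_\mathrm{dim}$.

A caution on notation: the variant $2S^2[t - P(1 - e^{-t/P})]$ appears in
print but has units of µm²/min, not µm². The form implemented in
`prw_msd()` is the standard, dimensionally consistent one, and it is the
only form whose diffusive limit reproduces $4\mu t$ with
$\mu = \tfrac12 S^2P$. Similarly, "$\mu = 12 S^2 P$"-looking renderings of
the coefficient definition are read here as $\mu = \tfrac12 S^2 P$.

Model assumptions worth keeping in mind: motion is unbiased (no
chemotactic drift), homogeneous across the population being pooled,
stationary over the observation window, and two-dimensional. None of
these is checked automatically.

## MSD estimation by non-overlapping intervals

`squared_displacements()` partitions the frame range of a track into
disjoint segments of $k$ steps anchored at the first frame, returning one
squared net displacement per segment and discarding the trailing
remainder; a track of $n$ frames yields $\lfloor (n-1)/k \rfloor$ values.
This is the simplest deterministic reading of "non-overlapping
intervals" — no averaging over segment phase — and it is exactly
reproducible by brute-force enumeration, which the test suite exploits as
an oracle over hundreds of random tracks.

`msd_curve()` averages these values per lag. For a population, the
default `pooling = "pooled"` concatenates all intervals from all cells
before averaging (the *cumulative* curve over 45–60 cells that motility
figures typically show); `"per_cell_mean"` instead gives every cell equal
weight. The two differ only when track lengths (or per-cell variances)
differ; which one published analyses used is rarely stated, so both are
provided and the choice is recorded in the curve's attributes. The pooled
curve equals the interval-count-weighted mean of the per-cell table — an
identity the tests assert exactly.

Two defaults matter:

* `max_lag_fraction = 0.5` — lags are reported up to half the track
  length, so every full-length cell contributes at least two
  non-overlapping intervals per lag; beyond that the estimator variance
  explodes. The full range is available by option.
* the lag-0 point (0, 0) is stored for plotting but excluded from
  fitting.

## Fitting: `fit_prw()`

Estimation is bounded nonlinear least squares (Levenberg–Marquardt via
minpack.lm) of $(S, P)$ on the positive-lag points, $S > 0$,
$P \in [\Delta t/10,\; 10\,T]$ with $\Delta t$ the first lag and $T$ the
longest. The objective can be bimodal near the ballistic boundary (a
nearly quadratic curve is explained equally by large $P$ or large $S$), so
three deterministic starts are tried — $S_0 = \sqrt{\mathrm{msd}_1}/t_1$,
the short-lag ballistic estimate, with $P_0 \in \{\Delta t, T/10, T\}$ —
plus any user start, and the lowest residual sum of squares wins. Standard
errors come from the local quadratic model at the optimum; $\mu$ is
computed from the fitted parameters, so $\mu = \tfrac12\hat S^2\hat P$
holds by construction on every fit.

Degeneracy is flagged, not hidden: $\hat P < \Delta t$ means persistence
is unresolvable at the sampling rate, and $\hat P$ at the upper bound
means the window never left the ballistic regime. An all-zero MSD
(immotile population) is an error; a solver failure returns
`converged = FALSE` rather than throwing.

**Weighting.** The default is ordinary (unweighted) least squares,
matching the bare "nonlinear least squares regression" description of the
field's standard analysis, and it is entirely adequate for short
acquisitions (a 15-minute window has at most a handful of lags with
similar interval counts). For long, many-lag curves the picture changes:
the long lags have few intervals, large values and variance growing
roughly with the squared MSD, so an unweighted fit is dominated by its
noisiest points. For such curves `weighting = "interval_count"` is
recommended and is what the package's own validation sweep uses (20
configurations spanning $S \in [2, 20]$ µm/min, $P \in [0.5, 5]$ min at
60 cells × 200 frames); the acceptance suite documents the achieved
median relative errors. An inverse-variance scheme would be better still
but requires a variance model; interval counts are available exactly.

**Speed has two meanings.** The fitted $S$ is the root-mean-square speed
of the model; `empirical_speed()` returns the model-free path length over
time of a track. They coincide in expectation for a finely sampled PRW
but diverge under coarse sampling (path length is underestimated between
frames) and under localization noise (inflated). Reported "speeds" in the
literature may be either, so both are emitted.

**Localization error.** No static-offset term is included in the fitted
model by default, matching the standard analysis. Simulated noise of
standard deviation $\sigma$ adds a $4\sigma^2$ offset to every lag of the
2D MSD (both endpoints, both axes), a prediction the simulator tests
verify; for data with substantial centroid error the offset shows up as a
non-zero intercept in residuals.

## The simulator

`simulate_prw()` exists so that every estimator in the package can be
validated against known truth. Its two non-obvious design points:

* **Exact discretization.** Per axis and per step, the position increment
  and end-of-step velocity are drawn jointly from the exact Gaussian
  transition density of the integrated OU process (conditional moments
  $E[\Delta x \mid v] = vP(1-a)$,
  $\mathrm{Var}[\Delta x \mid v] = \sigma^2(2P\Delta - P^2(3-4a+a^2))$,
  $\mathrm{Cov}[\Delta x, v' \mid v] = \sigma^2 P (1-a)^2$ with
  $a = e^{-\Delta/P}$, $\sigma^2 = S^2/2$), with the initial velocity
  stationary. Recorded positions therefore obey the Fürth MSD *exactly at
  any step size* — an Euler scheme would bias the oracle by
  $O(\Delta/P)$. A `substeps` option simulates finer than the frame
  interval and subsamples, which lets tests confirm the recorded
  statistics are discretization-invariant.
* **Seeding.** One master seed; each cell's stream is derived
  deterministically from the seed and the cell index, so track sets are
  bit-reproducible and a given cell's track does not depend on how many
  cells are requested.

Default acquisition settings emulate the motivating experiments: 1.5-min
frames over a 15-minute window (11 positions), 50 cells per group, no
localization noise. Time-lapse setups that acquire every 30 s are covered
by `frame_interval = 0.5`; since published methods mention both intervals,
the coarser one is the default and either can be set explicitly.

What the simulator does *not* emulate: chemotactic bias, cell–cell
interactions and collisions, population heterogeneity in $(S, P)$,
track fragmentation/mislinking, drift, and out-of-focus loss. Passing
tests therefore demonstrate correctness of the estimators under the PRW
model, not robustness of the model itself to real-data pathologies.

The assay fixtures are deliberately minimal: Transwell hemocytometer
counts are Poisson with mean `concentration × 1e-4` ml (the chamber
volume behind the conventional $n \times 10^4$ cells/ml reading), and
competitive-transfer tissue counts are binomial with CD45.1 odds equal to
`injected_ratio × tissue_enrichment`.

## Assay quantification

`quantify_migrated()` implements $N = n \times 10^4 \times V/1000$; with
the standard $V = 29$ µl this is the familiar $N = n \times 10^4 \times
0.029$. The volume is a parameter because the 0.029 is derived, not
magic. `competitive_ratio()` normalizes the tissue CD45.1/CD45.2 ratio by
the injected-mix ratio, so the injected composition defines baseline 1
exactly, whatever the actual mixing ratio was. Normalization is per
experiment; when replicate wells exist the package's convention is to
average within experiment before normalizing.

## Group statistics

`ttest_unpaired()` is the classical pooled-variance Student's test
(Welch by option); `msd_anova()` runs the conventional "two-way ANOVA
with Bonferroni" analysis of MSD curves: an overall group × lag ANOVA
with cells as replicates, plus per-lag two-group comparisons adjusted by
$m =$ number of lags (the family-size rule is configurable to
lags × pairs, but multiplying families is not assumed by default). Two
caveats are documented rather than silently accepted: cells contribute to
every lag, so treating them as independent replicates within the ANOVA is
anticonservative for the lag factor; and missing lags are handled by
listwise deletion per lag, never imputation. `type1_error_suite()` exists
to demonstrate the null calibration of the stack by simulation, and the
acceptance suite runs it at 1000 replicates.

## Validation scales and numerical choices

The test suite validates at sizes chosen to balance statistical
resolution against a desk-scale run (the full suite runs in well under a
minute): oracle equivalence on ~850 random tracks up to 12 frames;
Fürth-curve agreement at 500 cells × 200 frames with per-cell-mean
standard errors (cells are independent, within-cell segments are not);
parameter recovery at 60 cells × 200 frames, single config and a
20-config sweep; and the short-window regime at 50 cells × 10 frames,
where speed remains estimable to ~20% but persistence is weakly
identified — there the fit is accepted if flagged degenerate or within a
factor of 2.

Remaining numerics: `prw_msd()` switches to a three-term Taylor series
below $t/P < 10^{-4}$ (cancellation error of the direct form
$\approx 2\epsilon P^2/t^2$ crosses the series truncation error
$\approx (t/P)^3/60$ near there); track coordinates are serialized at 6
decimal places (sub-nanometre, far below localization error) so
write→read round-trips are exact at the written precision; and pipeline
outputs contain no timestamps, making reruns byte-identical under a fixed
seed.

## Known limitations

* The PRW fit assumes a homogeneous population; strongly bimodal motility
  (e.g. a mix of arrested and motile cells) biases both parameters and is
  better handled by per-cell fits (`per_cell_msd_table()` + `fit_prw()`
  per cell) than by the pooled curve.
* $S$ and $P$ are separately identified only by lags near and below $P$;
  with 10-frame tracks at 1.5 min, expect reliable $\mu$ and $S$ but not
  $P$.
* No velocity-autocorrelation estimator of $P$, no anisotropic or biased
  walks, no mixture or Bayesian fitting; the scope is the standard
  MSD-based analysis.
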