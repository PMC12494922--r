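---
title: "Brain clocks and creative experience: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain clocks and creative experience: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model behind the synthetic cohorts, the brain-clock estimator, the graph
and whole-brain-model analyses, the spatial surrogate test, and the design
decisions taken where the methods left genuine freedom. Nothing here
states an empirical result that the test suite or the analysis scripts do
not themselves compute.

## The whole-brain model

Each of the `n` regions is a Stuart–Landau oscillator — the normal form of
a supercritical Hopf bifurcation — with state `(x_i, y_i)`:

```
dx_i = [ (a_i − x_i² − y_i²) x_i − w_i y_i + G Σ_j M_ij (x_j − x_i) ] dt + β dW
dy_i = [ (a_i − x_i² − y_i²) y_i + w_i x_i + G Σ_j M_ij (y_j − y_i) ] dt + β dW
```

with bifurcation parameter `a_i` (default 0.01), natural frequency
`f_i = w_i/2π` (default 10 Hz), additive Gaussian noise of sd `β = 0.1`
on both components, and diffusive coupling through a nonnegative symmetric
connectome `M` scaled by the global coupling `G`. Weights are rescaled to
unit maximum row sum so `G` is comparable across connectomes. Two
conventions deserve note, because variants circulate in print:

* **Cubic saturation.** We use the standard normal-form amplitude
  `(x² + y²)`; the variant `(x² − y²)` sometimes printed does not
  saturate (its "radial" term changes sign), so it cannot produce the
  intended limit cycle.
* **Rotation sign.** One consistent rotation (`−w y` in `dx`, `+w x` in
  `dy`) is used; flipping both signs only reverses the rotation sense and
  leaves every spectral and correlation property unchanged.

Integration is Euler–Maruyama with `dt` defaulting to 1 ms and a guard
that aborts with advice to reduce `dt` if any state exceeds ±1000. A
precondition enforces `dt ≤ 1/(20 f)`. Euler integration of a fast
oscillation adds numerical *anti-damping* of order `w² dt/2` per unit
time; at 10 Hz and `dt = 1/512` this exceeds weak physical damping, which
matters only when quantitative agreement with the linear theory is the
question — the consistency tests therefore run at `f = 1` Hz where the
discretization bias is negligible, and the qualitative 10 Hz behaviour
(spectral peak, coupling-dependent correlations) is tested at the
default parameters.

### The linearized (Lyapunov) connectivity prediction

Linearizing at the origin gives the block drift matrix with per-node
blocks `[[a_i − G s_i, −w_i], [w_i, a_i − G s_i]]` (`s_i = Σ_j M_ij`) and
couplings `G M_ij I₂`. The stationary covariance `Σ` solves
`AΣ + ΣAᵀ + β²I = 0`, solved here by complex eigendecomposition (residuals
are asserted below 1e−8 in the tests); functional connectivity is the
correlation among the x-components.

A structural point shapes the whole package: with *diffusive* coupling,
`A`'s x-block is `aI − G·L` with `L` the graph Laplacian, whose zero mode
(the uniform pattern) is never damped by coupling. The stability margin is
therefore bounded below by `a`, and the linearization is **only valid for
`a < 0`** — the noise-driven regime — at any coupling strength. The
simulation path remains available at `a = 0.01` (self-sustained
oscillation); the analytic path refuses unstable drifts with an explicit
error rather than returning a silently invalid covariance. Consequently
the synthetic-data generator and the coupling-fitting default to
`a = −0.05`, and fitted couplings are interpreted within that regime.

### Fitting the global coupling

`fit_global_coupling` sweeps `G` over 0–3 in steps of 0.1, scores each
stable grid value by the structural similarity index (SSIM) between the
analytic prediction and the observed matrix, and returns the argmax (ties
to the smallest `G`; unstable values carry `NA`). SSIM uses the standard
7×7 uniform window with constants `K1 = 0.01`, `K2 = 0.03`, sample
covariances, and the joint data range of the two matrices; it equals 1
exactly on identical inputs, and the implementation is pinned in tests to
a reference value computed with an independent image-processing library.
Recovery tests show exact grid recovery on noiseless inputs and recovery
within one grid step (0.1) under Fisher-z observation noise of sd 0.03.

## The synthetic-data generator

The generator emulates the study conditions the analyses assume, not any
particular dataset:

* **Connectome.** 78 regions by default, 20% hubs placed as one spatial
  cluster (so spatial autocorrelation is nontrivial and the surrogate
  test has something to control), edge density 0.3 with a random spanning
  tree guaranteeing connectedness, and log-normal weights boosted on
  hub-incident edges.
* **Cohorts.** Ages uniform over the arm's range (17–91 y for the
  training arm; the narrower, matched ranges of the five study arms
  follow the demographic table's group sizes: 23/29/15/31 expert pairs
  plus a paired n = 24 learning arm). Each subject's latent coupling is
  `g = g0 − g_age·(age_rel) + g_exp·z(expertise) + ε`,
  with `g0 = 0.6`, `g_age = 0.3`, `g_exp = 0.08`, `sd(ε) = 0.02`; the
  connectivity matrix is the linearized model's prediction at that `g`.
  Expertise scores live on domain-specific scales (months of instruction,
  years of practice, hours per week) and are only compared after
  z-scoring. Measurement noise (sd 0.05) is added on the Fisher-z scale
  of the off-diagonals and back-transformed, keeping entries in [−1, 1].
  Paired designs reuse the subject's noise draws pre and post.
* **Term maps.** Gaussian random fields smoothed at a chosen length-scale
  over the connectome coordinates, standardized — stand-ins for
  meta-analytic association maps (89 by default).

What the generator does **not** emulate: sensor-space physics, artifacts,
volume conduction, site effects, non-Gaussian expertise distributions, or
any empirical magnitude calibration. The latent effect sizes were fixed
once for clear directional structure; the resulting group differences
(≈ −15 to −25 y of centered brain-age gap at the defaults in
`analysis/`) are deliberately strong relative to empirical reports of a
few years, so passing tests certify *directions, calibration, and
machinery*, not effect magnitudes on real recordings.

## The brain clock

A linear-kernel ε-SVR is the estimator because the analysis needs
per-edge importances, defined as the mean absolute weight across all
fold-by-repetition models — only linear kernels have per-feature weights.
Training uses 5-fold cross-validation with up to 15 repetitions (a fixed
repetition count; the scripts use 2–3 for speed), an inner 3-fold grid
search over cost {0.1, 1, 10} and tube width {0.1, 1} when the grid has
more than one combination, and optional in-fold augmentation: each
training row is replicated with zero-mean Gaussian feature noise
(default sd = 0.1 × the pooled feature sd), never touching held-out
folds. The leakage guard in the tests exploits an exact equivalence:
noiseless k-fold duplication equals multiplying the SVR cost by k + 1, so
augmented out-of-fold performance must match the reweighted un-augmented
model to optimizer tolerance.

Performance is MAE and Pearson r on each repetition's pooled out-of-fold
predictions, averaged over repetitions — never resubstitution, and never
after bias correction (which would flatter it). The age-bias line is the
OLS fit of out-of-fold raw gap on age, estimated once on the training
cohort and applied everywhere: `corrected = raw − (intercept + slope·age)`
removes the regression-to-the-mean artifact (tests assert
|r(corrected gap, age)| < 0.05 on the training set). Centered gaps
subtract the mean corrected gap within each domain batch, experts and
controls pooled.

## Graph efficiency

Matrices are binarized at proportional thresholds 0.02–0.10 in steps of
0.01 — exactly `round(ρ·n(n−1)/2)` edges kept, ranked on signed
correlation (the "highest" values; magnitude ranking is available as an
option), ties broken by a fixed index order so results are reproducible —
and metrics averaged across the range. Global efficiency is the mean
inverse shortest-path length (1/∞ = 0 across components); local
efficiency restricts paths to the subgraph *induced* by each node's
neighborhood (the stricter reading of "within this neighborhood") and
assigns 0 to nodes of degree < 2, avoiding 0/0. Both formulas are
verified against an independent algebraic-path oracle exhaustively on all
labelled graphs up to 5 nodes and on sampled 6-node graphs.

## Spatial surrogate testing

Map–map correlations are tested against nulls that preserve spatial
autocorrelation. Although such procedures are often called "spin tests",
the implementation is a variogram-matching generator, which needs only
region coordinates (no spherical surface): each surrogate permutes the
source map, smooths it with Gaussian distance kernels at log-spaced
candidate length-scales, refits the target variogram affinely (the offset
acting as a white-noise nugget), selects the best-matching scale, and
rank-remaps onto the source values — so every surrogate preserves the
value multiset exactly. The variogram is fitted on equal-count distance
bins up to the 70th percentile of pair distances; sparse long-range bins
reflect trend, not autocorrelation, and are excluded from the fit.
P-values use the add-one permutation convention
`(1 + #{|r_null| ≥ |r|})/(n + 1)`, two-sided, never exactly zero;
surrogates are generated from the first map argument (the vulnerability
map in the scripts). Calibration and power are established by simulation
in the test suite: null rejection within [0.02, 0.09] at α = 0.05 (300
replicates) and ≥ 80% power at a true map correlation of 0.5 (150
replicates, 78 regions, matched smoothness 12).

## Statistics

Independent and paired t-tests (two-sided, pooled-sd and
difference-sd Cohen's D respectively), one-sided Mann–Whitney U for small
samples (the direction must be supplied explicitly — it encodes the
hypothesis), chi-square for categorical tables, Pearson correlations with
`f² = r²/(1 − r²)`, Benjamini–Hochberg FDR, ANCOVA (indicator-coded
factors; partial f² = t²/df), and the 35th/65th percentile split with
strict inequalities and interpolated quantiles. One numerical caveat the
tests encode: a published f² computed from an unrounded correlation can
differ in the third decimal from the value recomputed from the rounded r,
so agreement is asserted at the precision the rounded input supports.

## Problem sizes and numerical choices

Test and script problem sizes are the package's own choices for a
desk-scale study: 20-region connectomes for cohort-level machinery,
78 regions wherever spatial structure matters (maps, surrogates,
dimensionality contracts), 120 training subjects, and simulation lengths
(3 × 700 s at 1 Hz) chosen so that sampling noise — not bias — limits the
linear-vs-simulated agreement, which is asserted at edgewise r ≥ 0.95
against the average of independent runs. Degenerate inputs fail loudly
and early: constant maps, zero-variance regions (named), unstable drifts,
non-symmetric connectomes, densities too low for connectedness, and
percentile splits of constant vectors are all explicit errors rather than
silent NaNs.

## Known limitations

* The analytic connectivity route requires the noise-driven regime
  (`a < 0`); self-sustained dynamics (`a > 0`) are available only through
  simulation, where Euler discretization limits quantitative fidelity at
  high frequency unless `dt` is reduced well below the formal bound.
* Synthetic effect magnitudes are not calibrated to empirical effect
  sizes; only directions and calibration properties transfer.
* Surrogate maps control stationary isotropic autocorrelation; strongly
  non-stationary layouts (e.g., the clustered hub geometry at extreme
  smoothness) are matched only approximately at the shortest distances.
* No sensor-space modelling, no alternative connectivity metrics, no
  nonlinear-kernel or deep brain clocks, and no heterogeneous per-region
  frequency fitting.
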