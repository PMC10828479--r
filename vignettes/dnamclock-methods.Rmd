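---
title: "Methods: elastic-net methylation clocks, rejuvenation statistics, and EWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elastic-net methylation clocks, rejuvenation statistics, and EWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

An epigenetic clock is a sparse linear predictor of age from DNA
methylation. Given a CpG-by-sample matrix of beta values $\beta_{ij} \in
[0,1]$ and per-sample chronological ages $y_j$ (years), the clock is the
elastic-net solution

$$
\min_{b_0, b}\; \frac{1}{2n}\sum_j\Big(y_j - b_0 - \textstyle\sum_i
\beta_{ij} b_i\Big)^2 + \lambda\Big(\alpha \lVert b\rVert_1 +
\tfrac{1-\alpha}{2}\lVert b\rVert_2^2\Big),
$$

with the mixing parameter fixed at $\alpha = 0.5$ — the midpoint between
ridge and lasso, deliberately not tuned — and $\lambda$ chosen by a seeded
internal 10-fold cross-validation over a descending log-spaced path of 100
values from $\lambda_{max} = \max_i |\langle x_i, y - \bar y\rangle| /
(n\alpha)$ down to $0.01\,\lambda_{max}$.

Two response scales are supported. *Absolute* clocks regress age in years.
*Relative* clocks regress relative age, age divided by the species maximum
lifespan (3.8 years for the rat, 122.5 for the human), which places species
of very different lifespans on a common $[0,1]$ scale; a single coefficient
vector then applies to both species, and years are recovered per sample via
the species lifespan.

## Solver

The solver (`enet_fit()`) is cyclic coordinate descent with exact
soft-threshold updates, written against standardized features (column mean
0, population-SD scale, so each coordinate has unit curvature). Per
$\lambda$ it alternates candidate-set sweeps with full-gradient checks (one
BLAS matrix–vector product), and declares convergence only after a full
check finds no subgradient violator — so the KKT conditions hold for every
coordinate, not just the active set. `enet_kkt_check()` exposes the
certificate. Numerical choices:

* convergence = largest absolute coefficient update in a sweep `< tol`;
  defaults: `1e-8` for standalone fits, `1e-4` inside the penalty-selection
  CV and `1e-5` for the final training fit (both far below the
  beta-measurement noise scale);
* warm starts along the descending path; `max_iter` exhaustion flags
  `converged = FALSE` rather than erroring;
* zero-variance (constant) features are flagged at standardization and can
  never enter the model;
* ties in the CV error are broken toward the larger (sparser) $\lambda$;
  the error-minimizing rule is the default, the one-SE rule is available
  (`lambda_rule = "one_se"`) since the literature uses both and the
  original analyses do not say which was used;
* the response is regressed untransformed; some clock work log-transforms
  juvenile ages, but nothing in the source analyses indicates one, so
  identity is the default and the design keeps the response construction in
  one place (`train_clock()`) should that change.

Missing beta values are mean-imputed per CpG from the training samples;
those means are stored in the clock so that prediction on partial panels
imputes consistently. Prediction requires 80% of the clock's CpGs to be
present and never clips negative estimates.

## Evaluation

`crossval_predict()` re-runs the *entire* training pipeline — imputation,
standardization, internal penalty selection, final fit — inside every
external fold (LOOCV or k-fold, optionally stratified by species or
tissue), so no information from a held-out sample can leak into its own
prediction. Accuracy is summarized as the Pearson correlation R between
DNAm age and chronological age and the median absolute error (MAE, years),
overall and per tissue/species; strata under 3 samples or with constant age
report MAE only. Relative clocks are evaluated in years after
back-transformation so MAE is comparable across clock types.

# Treatment statistics

For a three-arm design (young control, old control, old treated) the
package reports per-group mean ± SE, one-way fixed-effects ANOVA across the
arms, the pooled-variance Student's t of old control versus old treated
(young controls omitted; Welch available behind a flag), and Kruskal-Wallis
with average-rank ties and the standard tie correction, with the chi-square
upper-tail p.

The rejuvenation percentage is defined control-relative:

$$
100 \times \frac{\overline{\mathrm{DNAmAge}}_{old\,ctrl} -
\overline{\mathrm{DNAmAge}}_{old\,treated}}
{\overline{\mathrm{DNAmAge}}_{old\,ctrl}},
$$

chosen because a grand average of ~67% under this definition is what "more
than halved the epigenetic age" describes; the alternative gap-based
definition (relative to the old-minus-young difference) is available via
the `young_ages` argument and flagged in reports. The percentage is
invariant to rescaling the age unit.

# Epigenome-wide association

Per CpG, beta values are fit by ordinary least squares against a means
model: condition one-hot without intercept, batch one-hots (chip and array
column) with first levels dropped, plus optional unwanted-variation
factors. Rank deficiency (e.g. a chip perfectly confounded with condition)
is an error at design-build time, naming the aliased columns.

Unwanted-variation factors are the first $k$ right-singular vectors of the
row-centered control-CpG submatrix, the simplest faithful variant of
control-feature factor analysis; the default control set is the 10% of
CpGs with the smallest age association in a batch-only preliminary pass
(explicit control lists override). Factor signs are fixed (largest-magnitude
entry positive) so repeated runs are bitwise identical.

Variance moderation fits a scaled inverse-chi-square prior $(d_0, s_0^2)$
across CpGs by matching the first two moments of $\log s^2$
(digamma/trigamma inversion; Newton's method on the trigamma). The
posterior variance $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ replaces
$s^2$ in the t statistic, which gains $d_0$ prior degrees of freedom. When
the log-variance spread is no wider than chance, $d_0 = \infty$ and all
CpGs share $s_0^2$. Contrasts (effect $c^\top b$, SE from the design's
unscaled covariance) default to the age contrast (old control − young
control) and the treatment contrast (old treated − old control); p values
are Benjamini-Hochberg adjusted per contrast and flagged at adjusted
p < 0.05. The reversal summary counts doubly-significant CpGs whose two
effects have opposite signs.

# The synthetic methylome generator

`simulate_dataset()` draws beta values from a logit-normal model:

$$
\mathrm{logit}(\beta_{ic}) = b_i + m_i\,\rho\text{-adjusted relative
age}_c + t_{i,\mathrm{tissue}(c)} + u_{i,\mathrm{species}(c)} +
g_{\mathrm{chip}(c)} + \varepsilon_{ic}.
$$

The logistic link keeps values in $(0,1)$ with no clipping artifacts.
Defaults are the study conditions the package targets: 36,000 conserved
CpGs, thirteen rat tissues, lifespans 3.8/122.5 years, rat ages
0.0384–2.3 years, and three treatment arms of six animals (young controls
30 weeks = 0.577 y; old arms 109 weeks = 2.096 y). A fraction
`frac_age_related` (default 10%) of CpGs get a non-zero slope, uniform on
±4 logit units per unit relative age; baselines are N(0, 2); tissue
offsets N(0, 0.5); chip batch offsets N(0, 0.1) shared by all CpGs of a
chip; residual noise N(0, 0.3). These scales were fixed once as plausible
mammalian-array magnitudes and are not tuned per analysis.

Treatment is encoded as multiplicative shrinkage of *effective* relative
age: an old treated sample with chronological age $a$ behaves as
$(1-\rho)\,a/L$ while its annotated age stays at $a$. The generative
$\rho$ (default 0.6) is therefore directly comparable to the rejuvenation
percentage estimated downstream, which is what makes end-to-end recovery
tests possible.

Both species share the same aging archetypes evaluated at their own
relative ages — the in-silico analogue of a conserved-CpG mammalian array —
*plus* a per-CpG per-species baseline offset (N(0, 1) logit units). The
offset matters: if species were perfectly indistinguishable from features,
an absolute-age dual-species clock's predictions would be a function of
relative age alone, and its pooled R would necessarily fall *below* the
short-lived species' R — the opposite of what real conserved-probe data
show. Species-level mean differences are what let the absolute clock
resolve species, fit the long-lived species' year scale, and leave the
short-lived species' correlation degraded by year-scale prediction noise
over a 2.3-year range; the relative-age clock is immune to this by
construction. That contrast is exactly the property the dual-species tests
assert.

What the generator does *not* emulate: probe chemistry and detection
noise, the bimodal marginal distribution of real beta values, CpG–CpG
correlation (each CpG's noise is independent), nonlinear/saturating aging
trajectories, and cohort structure beyond a single chip-level batch
factor. Passing tests therefore demonstrate correctness of the estimation
machinery under a known generative law, not performance on real arrays.

# Pipeline and reproducibility

`run_pipeline()` chains simulate → train → cross-validate → predict →
rejuvenation table → EWAS, writing every artifact in documented CSV/JSON
formats plus a manifest of MD5 checksums. Every stage seed is a stable
arithmetic hash of (master seed, stage name), so stages can be re-run in
isolation and two runs with the same config are bitwise identical. Clocks
are trained only on the `none`-group (reference cohort) samples; the
treatment arms are held out entirely, mirroring the practice of developing
clocks independently of the experimental samples they judge.

## Problem sizes

The bundled checks run at desk scale, chosen to exercise each property
with comfortable margins: solver certificates on 200 random problems
(n ≤ 50, p ≤ 20); LOOCV signal recovery at n = 200 samples × 2,000 CpGs;
dual-species runs with 60 rats and 150 humans (the ~2.5:1 imbalance of the
original training sets) × 1,500–2,000 CpGs; null-calibration EWAS at
10,000 CpGs; and a demonstration pipeline at 4,000 CpGs with all six
clocks. The acceptance script reports the same quantities at slightly
smaller sizes.

# Known limitations

* The solver is dense; it does not exploit sparsity in X and is not
  intended for full 450k/EPIC-scale panels in one fit.
* Relative-age clocks need a lifespan entry for every species at both
  training and prediction time; unseen species are an error, not an
  extrapolation.
* The EWAS models beta values on their natural scale by default (matching
  the source analyses); a logit transform must be applied upstream if
  variance stabilization is wanted.
* `rejuvenation_percent()` is undefined when the old-control mean DNAm age
  is not positive, which can occur for very poor clocks; the gap-based
  mode is the fallback there.
* Kruskal-Wallis p values use the chi-square approximation; at N ≤ 8 it
  deviates from the exact permutation distribution by up to ~0.1, which
  the tests quantify against full enumeration.
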