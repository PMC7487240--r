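---
title: "Methods: comparative analysis of molt evolution and seasonal dichromatism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of molt evolution and seasonal dichromatism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltpath)
```

## The scientific question

Many birds molt twice a year.  The second (prealternate) molt produces the
breeding (alternate) plumage, and in seasonally dichromatic species that
plumage looks different from the nonbreeding one.  Two explanations compete:
either the biannual molt evolved *for* the color change (variable selective
pressures on plumage through the year), or it evolved to replace feathers
worn by solar exposure — a burden that falls hardest on long-distance
migrants, which experience more daylight over the year — and was later
co-opted for color change.  The two accounts make different comparative
predictions: under the feather-wear account, molt extent should track
migration distance and day length, dichromatism should track molt (plus
social-selection correlates such as foraging stratum), and molt should
precede dichromatism on the tree.

`moltpath` implements the full comparative toolkit needed to test this on a
clade of ~48 species: trait scoring, evolutionary-model selection,
ancestral reconstruction, correlated-evolution tests, phylogenetic
regression with information-theoretic model ranking, simulation-based
phylogenetic ANOVA, and d-separation path analysis — together with a
synthetic-data generator that reproduces the causal and phylogenetic
structure the analysis assumes, so every stage is testable with no external
data.

## Trait model

Molt and dichromatism are scored per feather region (default 11 regions,
head → alula) on \{0, 0.5, 1\}: complete, partial/intraspecifically
variable, absent.  Two derived variables drive the comparative analyses:

* **extent** — the row sum of region scores (half scores count 0.5), a
  continuous character on `[0, 11]`;
* **presence** — 1 if any region score is positive (a 0.5 in a single
  region counts), a binary character.

The region list is data, not code: `succession_index()` takes any ordered
list and reports whether each species' replaced regions form a prefix of it
(the stereotyped head-to-alula succession) plus per-region inclusion
frequencies.  An integer-rounding variant of extent (`round_half = TRUE`)
is provided; the half-sum is the default because it preserves the
monotonicity property that adding 0.5 to any cell raises extent by exactly
0.5.

## Continuous models of evolution

For a trait `x` over `n` species and a tree-derived covariance `C` (shared
root-to-MRCA path lengths), all continuous fits are Gaussian:
`x ~ Normal(z0 * 1, sigma2 * V(theta))`, where `V` is

* **BM** — `V = C`;
* **Pagel's lambda** — off-diagonals of `C` scaled by `lambda`;
* **OU** — fixed-root form
  `V[i,j] = exp(-alpha d[i,j]) (1 - exp(-2 alpha T[i,j])) / (2 alpha)` with
  `T` shared time and `d` patristic distance.  On an ultrametric tree this
  reduces to the familiar stationary form; on non-ultrametric trees it
  remains a proper covariance (a warning notes the case);
* **EB** — every branch spanning ages `t1 → t2` replaced by
  `(exp(r t2) - exp(r t1)) / r`, `r ≤ 0`.

`z0` and `sigma2` are profiled in closed form by GLS for each candidate
structural parameter, and the structural parameter is maximized by bounded
search over five subintervals of its range (a deterministic multi-start).
The boundary value that collapses each model to BM is always evaluated, so
the nesting inequalities `lnL(OU|EB|lambda) ≥ lnL(BM)` hold up to optimizer
tolerance (`1e-6`).  `sigma2` uses the ML (`n`) denominator so AICc
comparisons are consistent across models; `AICc = -2 lnL + 2k +
2k(k+1)/(n-k-1)` with `k = 2` (BM) or 3 (others).

Default structural-parameter ranges, with `depth` the tree height:
`alpha ∈ [0, 50/depth]`, `r ∈ [-10/depth, 0]`,
`lambda ∈ [0, lambda_max]` where `lambda_max` is the largest value keeping
the transformed matrix positive semi-definite (pair bound refined by
eigenvalue bisection; at least 1 on ultrametric trees, capped at 1.5 for
fitting).  These are wide relative to identifiable values at n ≈ 48 and are
user-overridable.

Binary presence characters may be passed to these Gaussian fits — model
weights for presence characters are part of the analysis design — and the
fit is flagged `binary_response` in its output.

Ancestral states of continuous characters (`asr_continuous`) are the
conditional means of the joint Gaussian implied by the BM fit; the root
estimate equals the fitted `z0` by construction.

## Discrete models

Mk likelihoods use Felsenstein pruning with a flat root prior by default
(a stationary-distribution prior is available).  Transition matrices
`P(t) = exp(Qt)` are computed from one eigendecomposition of `Q` shared by
all branches and assembled in a single matrix product; validity (row sums
within `1e-8` of 1, no negative entries) is checked on every call and a
scaling-and-squaring fallback (`Matrix::expm`) handles defective `Q`.  The
postorder sweep itself is compiled (C++), with per-node log rescaling
against underflow.

* `fit_mk` fits ER (one rate) and ARD (all rates different) by bounded
  search on the log-rate scale, ARD seeded from the ER optimum so the
  nesting inequality holds.
* `marginal_asr` computes true marginal node probabilities by the two-pass
  (downward partials / upward flow) algorithm, equivalent to re-rooting.
  MAP ties are broken toward the first (absence) state and flagged —
  conservative for gain counting.
* `count_transitions` counts a gain (0→1) or loss (1→0) on every branch
  whose parent and child MAP states differ.
* `pagel_dependence_test` compares two binary chains evolving independently
  (4-state composite chain, 4 free rates) against a dependent chain whose
  gain/loss rates for each trait depend on the state of the other (8 free
  rates); dual transitions are structurally zero in both.  AIC
  (`-2 lnL + 2k`) is the headline statistic for this comparison, with AICc
  also emitted, and a likelihood-ratio test on 4 df.  The dependent search
  is seeded at the independent optimum, guaranteeing the nesting.

## Phylogenetic regression and model ranking

`pgls_fit` estimates `beta = (X' V^-1 X)^-1 X' V^-1 y` after Cholesky
whitening.  R², the overall F test (`df = (p, n - p - 1)`) and coefficient
t tests are computed in the whitened space against the GLS intercept-only
model under the *same* `V`, so `R²` retains its proportion-of-variance
meaning under the tree.  Three correlation structures: Brownian
(`lambda = 1`, the default — the reference behavior for this analysis),
fixed `lambda`, and ML `lambda` (profiled jointly; `k` then counts the
extra parameter).  `k = p + 2` counts slopes, intercept, and the residual
variance, so BM and ML-lambda models are compared fairly by AICc.
`rank_model_set` fits a list of predictor subsets for one response and
tabulates adjusted R², model p, AICc, ΔAICc, and Akaike weights, sorted
ascending (ties keep input order).

## Simulation-based phylogenetic ANOVA

`phylo_anova` refers the classical one-way F statistic to a null
distribution of F values from Brownian simulations on the tree (rate
estimated from the response by ML), with
`p = (1 + #{F_sim ≥ F_obs}) / (1 + n_sim)` — bounded below by
`1/(n_sim + 1)`, never exactly zero.  Default `n_sim = 1000`.  A zero
within-group sum of squares yields infinite F, flagged degenerate.  The
package wires the analysis as response = migration distance, groups =
per-region molt presence, and corrects across regions with Holm's
sequential Bonferroni (`holm_adjust`, a validated wrapper over
`stats::p.adjust`).

## d-separation path analysis

Candidate causal hypotheses are DAGs over migration distance, day length,
molt extent, foraging stratum, and dichromatism extent.  For each
non-adjacent vertex pair one conditional-independence claim is formed: the
topologically later vertex is regressed on the earlier, conditioning on the
union of both vertices' parents; the claim p-value is the two-sided
coefficient p-value from `pgls_fit`.  Claims combine into Fisher's
`C = -2 Σ ln p` (chi-square, `2k` df), and models are ranked by
`CICc = C + 2qn/(n - 1 - q)` with `q` = edges + vertices (each variable
contributes one free variance — the common convention of the d-sep
literature; configurable since conventions differ).  Models with
`C`-statistic `p ≤ alpha` are flagged rejected and excluded from the rank
column; the full CICc-sorted table is always returned.  Zero p-values are
clamped to `1e-300` with a warning.

The shipped candidate set (`inst/extdata/path_models.txt`) is a
**reconstruction**: twelve sparse hypotheses honoring the constraints the
original account states for its favored models (molt and stratum as direct
parents of dichromatism; migration as a direct parent of day length; the
two top models differing only in whether migration or day length parents
molt; a runner-up in which molt is conditionally independent).  Supergraph
models combining several parent hypotheses at once are deliberately
excluded: they are observationally compatible with the same data as their
sparse submodels, and a set containing them could not produce the reported
pattern of two equivalent sparse winners.  The file is data: edit it to
test other sets.

## The synthetic-data generator

`generate_warbler_like_dataset` emulates the structure of the empirical
dataset, not any of its measured values:

* an ultrametric pure-birth tree, depth rescaled to 1; default 48 species
  (the size implied by F statistics on 1 and 46 df);
* **migration distance**: a latent BM character determines both which
  species are residents (the lowest third — zero-inflation fraction 1/3,
  reflecting that a substantial minority of the clade is sedentary) and the
  rank of migrant distances, mapped onto lognormal quantiles
  (`meanlog = log(20)`, `sdlog = 0.6` degrees latitude — typical
  temperate–tropical distances);
* **day length** = 12 + 0.8·(standardized migration) + BM noise (tip SD
  0.4 h): migrants gain on the order of an hour of mean daylight, matching
  the magnitude the solar-exposure argument needs;
* **molt extent (latent)** = 0.6·(standardized day length) + BM noise
  (SD 0.6).  The default graph deliberately has *no* direct
  migration → molt edge, so the generating model is the chain
  migration → day length → molt (model m3 of the shipped set); the
  coefficient for a direct migration edge exists in the configuration and
  defaults to 0;
* the latent molt extent is discretized through its normal score onto
  `[0, 11]` in half-steps and filled along the canonical region order (full
  scores first, a half score at the moving front), so succession holds by
  construction;
* **dichromatism (latent)** = 0.7·(standardized molt extent) +
  0.45·(standardized foraging stratum) + iid noise (SD 0.55), discretized
  the same way and then capped cell-wise by the molt score — dichromatism
  is a subset of molted regions, always;
* ordinal habitat/stratum/nest codes and lognormal body mass are drawn
  within their documented ranges.

Everything is driven by one seed; two runs with the same configuration are
file-identical.  What the generator does **not** emulate: measurement error
in museum scoring, non-ultrametric trees, geographic realism (polygons used
to exercise the range-predictor module are synthetic rectangles), or
correlation between stratum and habitat.  Passing tests on these data show
the estimators and tests are correct and calibrated under the assumed
model; they cannot show the assumed model is right for real warblers.

## Numerical choices

* PSD and ultrametry tolerances scale with the tree: `1e-8·trace` and
  `1e-6·depth`.
* Optimizers: 1-D problems use `optimize` over 5 subintervals
  (`tol = 1e-6`); multi-rate Mk problems use L-BFGS-B on log rates
  (`factr = 1e8`, bounds `[1e-8/depth, 1e3/depth]`) with multiple seeds and
  a fall-back to the nested optimum whenever the richer model lands below
  it.
* Gaussian likelihood failures on singular `sigma2·C` raise an error
  suggesting PSD repair rather than silently regularizing.
* MAP ties in ancestral states break toward absence and are flagged.
* `aicc_weights` is shift-invariant and refuses NaN inputs by position.

## Problem sizes used in verification

The test suite verifies exact oracles at 2–6 tips (dense vs. peeling
Gaussian likelihoods, Mk pruning vs. state enumeration, marginal ASR vs.
brute-force conditionals, all at `1e-10`) and statistical behavior at the
study's conditions: rate recovery at 200 tips × 100 reps, signal recovery
at 100 tips × 100 reps, ER recovery at 500 tips, null calibration of the
ER/ARD and dependence LRTs and of the phylogenetic ANOVA at 100–200 tips ×
100 reps, and recovery of the generating path model over 100 synthetic
datasets of 100 species.  The acceptance script repeats these with 50–100
replicates per quantity.  Cross-checks against independent implementations
(`phytools::fitMk`, `phytools::phylosig`, `nlme::gls` with a Brownian
correlation, `stats::lm`/`anova`) pin the likelihood conventions.

## Known limitations

* OU fitting uses the fixed-root covariance with a single optimum; no
  multi-regime or multi-rate models.
* The Pagel test's flat root prior follows the common default; results can
  shift slightly under a stationary prior (available via `root_prior`).
* d-sep claim p-values inherit any misspecification of the PGLS correlation
  structure; with discretized, zero-inflated traits the C statistic runs
  slightly hot, so the true model itself is occasionally rejected at
  `alpha = 0.05`.
* Range predictors assume geographic coordinates and planar polygon
  geometry except for the haversine centroid distance; no reprojection.
* No stochastic character mapping; transition counts come from MAP
  reconstructions and are sensitive to ties near 0.5.
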