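---
title: "Methods: community fractions in functional trait space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community fractions in functional trait space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`traitedge` asks, plot by plot, whether the naturalized and invasive species
of a plant community sit where a random set of resident species would sit in
the community's functional trait space, or whether they cluster around the
native trait centroid (environmental filtering) or push toward its edge
(niche-margin insertion). This vignette documents the model, the tunable
parameters, the synthetic-data generator, the numerical conventions, and the
design decisions taken where the methodology left genuine freedom.

## 1. Trait space

Eight species-level traits span the space: maximum height (m), seed mass
(mg), leaf area (mm²), specific leaf area (mm² mg⁻¹), leaf dry matter
content (mg g⁻¹), flowering midpoint (month, 1–12), flowering length
(months, 1–12) and 2C genome size (Mbp). All traits except the flowering
midpoint are log10-transformed (they are right-skewed, ratio-scale
quantities; the flowering midpoint is a circular-ish calendar position
treated as ordinal), then each trait is z-scored to zero mean and unit
variance. Conventions:

- **Scaling population.** Means and SDs are computed once over *all* species
  of the analysis dataset and reused everywhere (`standardize_traits()`
  records them). Per-plot scaling would make centroids incomparable across
  plots.
- **Sample SD** (n−1 denominator), the convention of standard statistics
  stacks; recorded in the scaling record.
- Missing trait values are rejected at validation, not imputed: imputation
  quality is a data-preparation concern (missForest-class tools) outside
  this package's scope.
- Excluded species (sensitivity analyses that remove a dominant invader)
  are dropped from plots, registry and pools but *kept in the scaling
  population*, so results for plots not containing them are bit-identical —
  without this, removing one species would perturb every coordinate in the
  dataset.

As an alternative geometry, `gower_podani()` computes the Gower coefficient
with Podani's tie-corrected rank extension for the ordinal flowering
midpoint, and `pcoa_axes()` embeds it by principal coordinates. Axes with
eigenvalue ≤ 1e-10 × the largest are dropped; no Cailliez/Lingoes
correction is applied (the default behavior of the functional-dispersion
methodology this mirrors). For a Euclidean-embeddable matrix the embedding
is exact, so D and E computed on PCoA axes of the Euclidean distance matrix
equal the direct computation to rigid motion (tested at 1e-6).

## 2. D, E and their cover-weighted forms

With fraction X of size $n_X$ and native centroid $\mu$: $D_X$ is the mean
Euclidean distance of X's members from $\mu$, and $E_{XY}$ the two-sample
energy distance (see README for formulas; self-distances are zero, E ≥ 0,
E = 0 iff the two weighted empirical distributions coincide). The centroid
for alien fractions is *always the native centroid of the same plot* — D
measures position relative to the resident community, not internal spread.

The weighted forms use $w_i = \sqrt{\text{cover}_i}$ normalized within each
fraction: weighted D is the weighted mean of distances, and weighted E
replaces every uniform average (including the within-group terms) by the
corresponding weighted average. This is the standard weighted
energy-distance form; under equal covers it reduces exactly to the
unweighted statistics, which the tests assert. Whether weights should
instead be normalized globally across fractions is not determinable from
the methodology; within-fraction normalization keeps each term a proper
average and is the recorded choice.

Precision note: cross-distance matrices are computed by direct coordinate
differences, not the $\lVert x\rVert^2 + \lVert y\rVert^2 - 2x\cdot y$
expansion, which cancels catastrophically for nearby points and fails
1e-9-level oracle comparisons. The null-model inner loop uses a compiled
(Rcpp) kernel; the pure-R `dispersion_d()` / `e_distance()` are the
reference implementations and the tests compare the two routes replicate by
replicate.

## 3. Null models

For each plot and each comparison (native vs naturalized, native vs
invasive — drawing from the habitat's *native* pool; naturalized vs
invasive — drawing from the habitat's *naturalized* pool), both fractions
are redrawn jointly and disjointly: a replacement of the same life form is
drawn without replacement for every observed member, the two simulated
fractions never share a species (a species cannot hold two invasion
statuses), and each replacement inherits the cover of the member it
replaces. Fraction sizes, per-life-form counts and cover multisets are
preserved exactly in every replicate (asserted in tests over 10,000
replicates). Three selection weightings: uniform; proportional to habitat
occurrence frequency; proportional to the plot's Beals smoothing value.

- **Beals convention.** The reference matrix is built from all plots of the
  habitat (presence/absence); the target species is excluded from its own
  prediction (both from the co-occurrence sum and from the denominator
  count), avoiding circularity. Zero-probability candidates receive a 1e-6
  floor before normalization so sparse synthetic data never produce an
  all-zero weight vector; a fully zero Beals row falls back to uniform.
- **Weighted sampling without replacement** is sequential (weights
  renormalized after each removal) — R's native `sample.int(prob =)`
  process — and is checked against enumeration-based inclusion
  probabilities on a 5-species stratum.
- **Simulated natives define the null centroid**: the null asks what D and
  E would look like in a same-sized community carrying only native-pool
  traits, which includes centroid variability. For the naturalized vs
  invasive comparison, the simulated first fraction (the naturalized
  analog) plays that role, and the *observed* D is referenced to the
  observed naturalized centroid so that observed and simulated
  constructions stay exchangeable under the null. The source methodology
  does not pin this down; it is recorded as an open choice.
- **Seeding.** One master seed; each plot × comparison derives a child seed
  from (seed, plot id, comparison) via a string hash, so results are
  independent of plot processing order and fully reproducible.
- Plots lacking one of the compared fractions, or whose life-form needs
  exceed a pool stratum (e.g. epiphytes absent from a pool), are skipped
  for that comparison with a logged reason.
- Simulated draws may coincide with species present in the observed plot
  (draws are from the full pool); excluding them is not clearly warranted
  and would shrink small strata further.

Reductions: ΔD = observed D − mean simulated D (the paper-standard
deviation measure; SES is deliberately *not* computed because it is
sensitive to fraction size), and p_E = (#\{simulated E ≥ observed E\} + 1) /
(n_sim + 1), supported on \{1/(n+1), …, 1\}. The default n_sim is 999;
tests scale down to 199 (criteria 5–6) or less, with Monte-Carlo error
terms that account for it.

## 4. Habitat-level inference

Within each habitat and comparison, plots where both fractions occur
contribute a pair (ΔD_ref, ΔD_cmp). The paired Wilcoxon signed-rank test
uses differences ΔD_cmp − ΔD_ref, so **z > 0 means the alien fraction lies
farther from the native center** — matching the sign convention of the
reported statistics this package mirrors. Conventions: zero differences
dropped (Wilcoxon's convention), N = retained pairs, tie-corrected
variance, *no* continuity correction (a z statistic is needed for
r = z/√N), two-sided p from the normal approximation, minimum N of 6 with a
warning below 20. At N = 10 the no-continuity-correction approximation sits
within 0.02 of the exact enumeration p in the inferentially relevant tail,
but can deviate by ~0.05 mid-range (the exact two-sided p includes the
observed atom on both sides); the oracle tests document this.

All habitat × comparison p-values from one run form a single
Benjamini–Hochberg family. Effect sizes classify as small (|r| < 0.3),
medium (0.3 ≤ |r| < 0.5), large (|r| ≥ 0.5).

## 5. Driver trees

`fit_regression_tree()` is a from-scratch CART: greedy SSE-reduction
splits with thresholds at midpoints between consecutive observed values
(ties broken by lower variable index, then lower threshold — determinism),
`min_split = 20`, `min_leaf = 7`, cost-complexity pruning, 10-fold
cross-validation (fold assignment seeded), and the 1-SE rule: the smallest
subtree whose CV error is within one standard error (per-observation SE of
the mean squared error) of the minimum. Per-split percentage variance is
the split's SSE reduction over the root's total SSE, so the percentages sum
to the tree's total variance explained. Surrogates are, per node, the other
predictors whose best threshold/direction sends ≥ 90% (inclusive) of the
node's cases to the same child as the primary splitter; the raw agreement
fraction is used, with no "go with the majority" baseline subtraction,
matching the verbal definition rather than a particular implementation.

The response is ΔD pooled across habitats, one row per plot × fraction;
predictors are the fraction's per-trait means of standardized trait values.
The naturalized-fraction tree is restricted to herbs and dwarf shrubs
(chamaephytes), mirroring the reference analysis; the invasive-fraction
tree uses all life forms.

## 6. The synthetic generator: what it emulates, and what not

`scenario_config()` + `simulate_dataset()` produce a habitat species pool
(native/naturalized/invasive counts; default 150/40/12, roughly the
proportions of a well-sampled temperate flora scaled to desk size), life
forms assigned by a mix dominated by herbs (85%, with 5% each of
chamaephytes, nano- and macrophanerophytes — epiphytes are a negligible
class and excluded by default), per-species trait vectors, and `n_plots`
invaded plots: Poisson richness truncated at ≥ 2 (default mean 12, a
typical invaded-plot richness), at least one native plus one alien species
per plot, status mix 75/18/7%, and log-normal percentage covers truncated
to (0, 100] (meanlog 1, sdlog 1.1 — right-skewed, median cover ~3%).

Traits are generated on the standardized scale — natives multivariate
normal around the origin with *identity covariance* (downstream z-scoring
makes correlations irrelevant to every formula being exercised) — and
back-transformed to raw units (10^x with per-trait location/scale; calendar
traits rounded to integer months 1–12, exercising the ordinal/no-log
pathway). Scenarios:

- `neutral`: aliens drawn from the native trait distribution;
- `filtering`: alien species means at the native centroid with reduced
  scatter (`trait_noise_sd`, default 0.5) — clustering;
- `eots`: naturalized species as in `filtering`; invasive species means
  displaced by `alien_displacement` pooled-SD units along uniformly random
  directions, with **unit** scatter retained. The unit scatter is
  deliberate: in p = 8 dimensions a native point sits at expected radius
  E[χ₈] ≈ 2.79, so a mean displaced 2 SD with shrunken scatter would land
  *inside* the native shell (√(4 + 0.25·8) ≈ 2.45) and invert the intended
  edge-of-trait-space signature, whereas unit scatter gives expected radius
  √(d² + 8) ≈ 3.46 > 2.79 for any displacement d > 0.

The `truth` record stores every species' generated mean displacement, so
tests can recover configured parameters. Plot assembly draws species from
the status pool with weights `lifeform_mix[g]/|stratum g|` rather than
fixed per-stratum counts: expected life-form composition follows the mix,
small strata are never exhausted, and species within a stratum remain
exchangeable — the property the stratified null model relies on.

**What a green test establishes, and what it does not.** The generator has
identity trait covariance, no intraspecific variation, no spatial or
environmental structure, one habitat by default, and species-level status
labels reused across plots. Passing tests demonstrate the statistical
machinery is correct and self-consistent, not that any ecological effect
size is realistic. One consequence surfaced by the acceptance work: because
alien pools are finite and shared across plots, plot-level ΔD values for
alien fractions are *correlated and conditionally biased given one pool
realization* — the null draws natives, the observed aliens are a fixed
small sample. The null self-consistency criterion therefore draws the
"observed" fractions from the habitat native pool by the very process the
null uses (the construction its own definition suggests), which makes p_E
exactly rank-uniform per plot and plots conditionally independent. The
full-pipeline neutral run remains covered qualitatively by the scenario
tests.

## 7. Degenerate inputs and numerical edges

- Singleton fractions are valid: D of a singleton reference fraction about
  its own centroid is 0; E of singletons reduces to twice the point
  distance. Rows involving a singleton pair are flagged
  (`singleton_pair`) in the output.
- A constant trait contributes 0 to the Gower coefficient with a warning;
  a trait constant over the scaling population is an error (no z-score
  exists).
- E values are clipped at 0 against negative rounding residue; identical
  multisets give exactly 0.
- Pool strata exactly equal to the required count give a deterministic
  forced draw.
- All statistics are double precision; per-plot cost is O(n²) in plot
  richness, trivial at realistic n.

## 8. Known limitations

No trait imputation, no habitat classification, no spatially explicit
structure, no SES standardization (deliberate), classification trees and
forest-type ensembles out of scope. The Wilcoxon normal approximation is
used at all N ≥ 6 (no exact small-sample switch), because the effect size
r = z/√N requires a z statistic.
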