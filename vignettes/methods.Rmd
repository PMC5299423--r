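---
title: "Methods: niche estimation, habitat nulls and phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche estimation, habitat nulls and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichesignal)
```

`nichesignal` asks a comparative question of mapped forest-plot data: do
closely related tree species prefer similar local environments? This
vignette documents the models and procedures the package implements, the
parameters that matter, the design choices made where the method left room,
and what the synthetic validation does — and does not — establish.

## 1. Data model

Three inputs, all plain text:

* a rooted, branch-lengthed phylogeny over the species labels (Newick);
* a stem map — one record per mapped stem with tag, species, x/y in
  meters and life stage (`seedling` or `adult`);
* a quadrat environment table on a complete rectangular lattice, carrying
  four topographic variables (aspect in degrees, convexity, elevation,
  slope) and nine soil-nutrient variables.

Conventions fixed once and used everywhere, including the torus shifts:
coordinates are 0-based; a stem belongs to quadrat
`(row, col) = (floor(y/q), floor(x/q))` with half-open intervals, so a stem
at exactly the plot extent is an error, and quadrat assignment is a
partition. Aspect is circular and is consumed on every analysis path as
northness, `cos(aspect * pi / 180)`; the raw angle never enters a linear
computation.

## 2. Niche estimation

For a species E and axis x, the conditional occurrence probability is
estimated by binning: the axis range over quadrats is split into `n_bins`
(default 20) equal-width bins and

> p(E | x in bin b) = occupied quadrats in b / quadrats in b.

The species' *niche value* on the axis is the midpoint of the maximizing
bin. Defaults and their rationale:

* `n_bins = 20` — on a 1000-quadrat grid this leaves ~50 quadrats per
  central bin, enough for a stable occupancy fraction while resolving the
  axis to ~0.3 standard deviations.
* `min_bin_quadrats = 5` — bins in the sparse tails of the axis
  distribution are excluded from the argmax; a fraction estimated from
  fewer than 5 quadrats is dominated by sampling noise.
* Ties are broken toward the bin with more occupied quadrats, then toward
  smaller x; the estimator is fully deterministic.
* Occupancy, not abundance, defines E: duplicating stems inside a quadrat
  changes nothing (this is asserted as a property test).

The estimator is deliberately the transparent histogram form. A Gaussian
kernel smoother over bin midpoints (`smooth_bw`) is available but off by
default: the underlying literature for p(E|x) does not pin down a kernel or
bandwidth, and the binned form is the one whose behaviour we can verify
against ground truth. Soil chemistry enters through PCA on the standardized
nine nutrients, with each loading vector oriented so its largest-magnitude
element is positive (a pure sign convention that makes runs reproducible);
the three leading score columns become the `soil_pc1..3` axes.

## 3. Habitat classification and torus-translation tests

The habitat layer is *derived* from topography: quadrats are clustered on
standardized {northness, convexity, elevation, slope} with Ward linkage and
the tree is cut at `k = 3`. Classes are named by physiography: lowest mean
elevation is `valley`; of the remainder, the class with higher mean
convexity is `ridge`, the other `slope`. Ward was chosen over k-means
because it is deterministic without seed bookkeeping; the classification
method itself is a stand-in, configurable by `k`, since the underlying
field protocol is not part of the data model.

The association statistic is relative density: stems of the focal species
per quadrat of the habitat. Its null distribution comes from torus
translation: the habitat map is shifted by every whole-quadrat offset
(width x height shifts, identity included) and, by default, the same is
done to the map's 180° rotation and its two mirror images (4 variants).
Shifting the habitat rather than the stems preserves both the species'
spatial aggregation and the habitat's spatial structure — exactly the two
features a random-labels null would destroy.

The observed value is ranked within the full null set (it is itself a
member, via the identity shift), with mean ranks for ties, and the quantile
is `mean rank / n_null`. Verdicts are two-tailed at `alpha = 0.025` per
tail: `positive` above `1 - alpha`, `negative` below `alpha`. Habitats are
tested separately with no multiplicity correction (a Holm option would be a
trivial wrapper, but the default mirrors standard practice for these
tests).

Numerical detail that matters: null statistics are accumulated as integer
stem totals and divided by the (shift-invariant) habitat quadrat counts in
one step, so that genuinely equal null values compare exactly equal.
Mean-rank tie handling is fragile under floating-point summation-order
noise; a translation-covariance property test failed until totals were made
exact.

A structural fact about this null worth knowing: if the habitat map is
invariant under some translation (a vertical stripe, for instance, is
unchanged by any row shift), the corresponding null values tie with the
observed one, and the quantile cannot reach 1.0 no matter how extreme the
association. For a 2-column stripe on a 5x5 grid the best attainable
quantile is (20 + 3)/25 = 0.92. Real habitat maps are essentially never
translation-invariant, but perfectly regular toy maps are — verdicts on
such maps are conservative by construction.

## 4. Phylogenetic signal

**Blomberg's K.** With V the phylogenetic covariance matrix (shared
root-to-MRCA branch length; built here by one postorder traversal and
cross-checked in the tests against an independent construction),

* GLS root estimate: `a = (1'V⁻¹X) / (1'V⁻¹1)`
* `MSE0 = (X−a)'(X−a)/(n−1)`, `MSE = (X−a)'V⁻¹(X−a)/(n−1)`
* `K = (MSE0/MSE) / [(tr V − n/(1'V⁻¹1)) / (n−1)]`

K = 1 is the Brownian expectation; the package verifies affine-trait and
branch-rescaling invariance and agreement with a brute-force explicit-
inverse oracle to 1e-10. Significance: tip permutation, 999 shuffles by
default, one-tailed on large K, with the add-one estimator
`p = (1 + #{K_perm >= K_obs}) / (1 + n_perm)` — p can never be 0 and its
floor is 1/(n_perm+1). One-tailed was chosen because the shuffle null asks
"is there *more* signal than random labels"; a K significantly *below* 1 is
an interpretive statement relative to the Brownian benchmark, not to the
shuffle null, and the package reports K and p separately so users can make
that distinction.

**Sankoff parsimony.** Categorical habitat preferences are scored by the
classic leaf-to-root dynamic program under a unit (equal-cost) step matrix
— the minimum number of preference changes. Low scores mean conserved
preferences, so the permutation p-value uses the lower tail
(`S_perm <= S_obs`). The DP handles multifurcations and arbitrary
non-negative cost matrices; tests compare it against exhaustive enumeration
of all internal-state assignments on trees of up to 8 tips.

**NRI / NTI.** For each habitat-preference group (species positive for
exactly one habitat, or `neutral`), observed MPD and MNTD are compared with
999 random draws of equal size from the species pool — all species passing
the stage's abundance filter. `NRI = −(MPD_obs − mean_null)/sd_null`, NTI
analogously; positive values mean clustering. The "draw from the pool
phylogeny" null was chosen as the simplest assemblage null consistent with
the group/pool framing; it is the package's default, not a claim about any
particular prior study, and `n_null` and the pool are arguments. Groups
with fewer than two members, or equal to the whole pool, are reported as
untestable rather than given a degenerate score.

**Preference groups.** A species with any negative association, or positive
association with more than one habitat, is removed before the dispersion
analysis; exactly one positive verdict assigns the species to that
habitat's group; no verdicts either way means `neutral`.

## 5. The synthetic world

The generator states one fixed world; its defaults were chosen once and are
not tuned to test outcomes.

| knob | default | meaning |
|---|---|---|
| `n_species` | 64 | tips of the pure-birth (Yule, unit-rate) tree, rescaled to depth 1 |
| `grid_width x grid_height` | 50 x 20 | quadrats of `quadrat_size` 20 m |
| `autocorr_range` | 40 m | exponential correlation length of environment fields |
| `bm_sigma2` | 1 | Brownian rate of niche-optimum evolution (per unit depth) |
| `conservatism_lambda` | 1 | internal-branch scaling: 1 = Brownian, 0 = star/labile |
| `niche_breadth` | 0.5 | s.d. of the Gaussian occurrence response (axis units) |
| `mean_abundance` / `seedling_abundance` | 150 / 60 | expected stems per species per stage |

Niche optima evolve by Brownian motion on the lambda-transformed tree
(internal branches scaled by lambda, tip branches stretched to preserve
depth — the standard interpolation between the full covariance and a star
phylogeny). Both life stages share one set of optima and are placed
independently, so a stage comparison on synthetic data sees the same truth
with independent sampling noise. Stems are placed per quadrat by a Poisson
draw with intensity proportional to the Gaussian response
`exp(−(x_q − optimum)² / (2·breadth²))`, normalized so the expected total
is the stage abundance, then jittered uniformly inside the quadrat —
downstream analysis is quadrat-level, so nothing finer is needed.

Environment fields are stationary Gaussian random fields with exponential
covariance `exp(−d/range)`, synthesized by dense Cholesky on the quadrat
centers (exact for these grid sizes), standardized to zero mean and unit
variance. Aspect is built as the angle of two auxiliary fields, giving a
spatially coherent circular variable. Two caveats, verified empirically and
reflected in the tests: (i) the real plot's spatial covariance family is
unknown — exponential is a stand-in; (ii) after standardization, a
near-constant large-range field leaves a smooth gradient residual whose
lag-1 neighbour correlation plateaus around 0.90 ± 0.03 regardless of how
large the range is, so the "very large range" regime is asserted at 0.85
rather than a higher bar.

The spec'd grid (50 x 20 = 1000 quadrats) is twice the area of a real 20-ha
plot at 20-m quadrats (500); the larger default is kept as stated and only
affects synthetic-data resolution, not any method.

What a green synthetic suite establishes: the statistics are computed
correctly (oracle equivalence), their permutation nulls hold their nominal
size, the K test has power against conserved (lambda = 1) niches at n = 64,
and the p(E|x) argmax recovers known optima to within one bin width for
over 90% of species under narrow niches. What it does not establish:
behaviour under dispersal limitation, demographic structure, interspecific
interactions, measurement error in the environment, or phylogenetic
uncertainty — none of which the generator emulates.

## 6. Numerical and degenerate-input policy

* All p-values use the add-one form; with 999 permutations the floor is
  0.001.
* Constant traits, species with zero stems, groups smaller than two,
  group = pool, and zero-variance nulls raise errors rather than returning
  NaN — silent NaNs would corrupt batch tables.
* Strict Newick parsing requires branch lengths (every statistic here needs
  them); lenient mode imputes 0 with a warning.
* All randomness flows from one master seed split into per-stage streams;
  runs are byte-reproducible, and the RNG state of the caller is never
  disturbed.
* The permutation engines for K and Sankoff are vectorized across
  permutations (one covariance factorization, one DP sweep per batch), which
  is what keeps the 1000-replicate calibration suites inside a desk-scale
  budget.

## 7. Known limitations

* The habitat classifier is a pragmatic stand-in (Ward on topography);
  classifications from field protocols will differ in detail, which is why
  the habitat map is also accepted as a direct input (`habitat_map()`).
* K on niche *estimates* is attenuated relative to K on the underlying
  optima: the binned argmax is a noisy, bounded transform. The permutation
  test retains power, but the magnitude of K should not be read as the
  magnitude of conservatism.
* NRI/NTI conclusions depend on the pool definition; the default pool (all
  species passing the stage filter) is one defensible choice among several.
* Torus-translation quantiles are conservative on translation-invariant
  (perfectly regular) habitat maps; see section 3.
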