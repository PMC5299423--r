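# nichesignal

Do closely related tree species occupy similar local environments? In
mapped forest-dynamics plots this question is usually answered indirectly,
through functional traits; `nichesignal` answers it directly. It estimates
each species' **local-scale environmental niche** from quadrat-level
topography and soil chemistry, tests **species–habitat association** with
torus-translation null models, and then asks whether the resulting niches
and habitat preferences carry **phylogenetic signal** — whether relatives
resemble each other more than chance expects.

The package is aimed at plot ecologists and comparative biologists working
with stem maps (tag, species, x, y, life stage), quadrat environment tables,
and a dated phylogeny of the plot's flora.

## The statistics

**Niche estimation.** For a species E and an environmental axis x (northness,
convexity, elevation, slope, or one of three soil-fertility PCA axes from
nine soil nutrients), the conditional occurrence probability is estimated
per equal-width bin of quadrat values,

    p(E | x) = (quadrats in bin occupied by E) / (quadrats in bin),

and the species' niche value on that axis is the x at which p(E|x) is
maximal. Occupancy, not stem counts, defines presence.

**Habitat association.** Quadrats are classified into habitats
(valley / slope / ridge by default) by Ward clustering of standardized
topography. A species' relative density in a habitat (stems per habitat
quadrat) is compared with the null distribution obtained by translating the
habitat map around the torus by every whole-quadrat shift — plus the
map's 180° rotation and two mirror images — with two-tailed verdicts at
α = 0.025 per tail.

**Phylogenetic signal.** Three complementary measures:

- *Blomberg's K* for the continuous niche values: with V the phylogenetic
  covariance matrix and â the GLS root state,
  `K = [MSE0/MSE] / [(tr V − n/(1'V⁻¹1)) / (n − 1)]`,
  where `MSE0/MSE` is the ratio of the ordinary to the
  phylogenetically-corrected mean squared error. K = 1 matches Brownian
  motion; K > 1 means stronger, K < 1 weaker resemblance among relatives.
  Significance comes from permuting niche values across tips (999 shuffles,
  add-one p-value).
- *Sankoff parsimony* for categorical habitat preferences: the minimum
  number of preference changes on the tree (unit transition costs), compared
  with tip-permutation nulls; conserved preferences give low scores.
- *NRI / NTI* for habitat-preference groups: negated standardized effect
  sizes of mean pairwise distance (MPD) and mean nearest-taxon distance
  (MNTD) against random draws from the species pool. Positive values =
  phylogenetic clustering, negative = overdispersion.

A seeded synthetic generator (pure-birth tree; Brownian niche evolution with
a conservatism knob λ ∈ [0,1]; spatially autocorrelated Gaussian environment
fields; Poisson stem placement under a Gaussian niche response) provides
ground truth for every stage.

## Worked example

A fully synthetic analysis with conserved niches (λ = 1), 32 species on a
20 × 10-quadrat plot, signal injected along the elevation axis:

```r
library(nichesignal)
res <- run_pipeline(list(n_species = 32, grid_width = 20, grid_height = 10,
                         n_perm = 199, n_null = 199, seed = 11))
res$habitats
#> <habitat_map> 10 x 20 quadrats; valley: 72, ridge: 57, slope: 71
res$adult$k_table
#>  stage      axis          K     p n_species
#>  adult northness 0.05300290 0.615        32
#>  adult convexity 0.17601594 0.020        32
#>  adult elevation 0.16776808 0.010        32
#>  adult     slope 0.08449815 0.335        32
#>  adult  soil_pc1 0.05511923 0.560        32
#>  adult  soil_pc2 0.08120224 0.310        32
#>  adult  soil_pc3 0.05070799 0.705        32
```

Elevation — the axis that actually carries the simulated niche signal — is
detected (p = 0.010); unrelated axes are not (the neighbouring convexity
value reflects this single run's sampling noise, not injected signal). Note
that K itself is far below 1 even for elevation: the binned niche estimate
is a noisy transform of the underlying Brownian optimum, which attenuates K
while the permutation test retains power.

```r
res$adult$sankoff
#>  stage score p n_species
#>  adult     4 1        22
res$adult$dispersion
#>  stage   group  n    NRI p_NRI   NTI p_NTI
#>  adult neutral 18  2.762 0.020 1.383 0.110
#>  adult  valley  3 -0.244 0.365 0.256 0.355
#>  adult   ridge  0     NA    NA    NA    NA
#>  adult   slope  1     NA    NA    NA    NA
```

Groups with fewer than two members are reported but not testable (`NA`).
The same pipeline runs from files (`simulate = FALSE` with `tree_path`,
`stem_path`, `env_path`) and from the command line:

```sh
inst/cli/nichesignal run-all --config config.txt --seed 11 --out-dir out/
```

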