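# morphmod

Phylogenetic geometric morphometrics of evolutionary modularity and
integration. The package is for comparative morphologists asking whether a
body plan evolves as one integrated unit or as semi-independent regional
modules: it takes digitized landmark configurations, a rooted phylogeny with
branch lengths and a partition of landmarks into hypothesized modules, and
carries the complete analysis from superimposition to macroevolutionary
pattern. It was built around the kind of dataset collected for suckermouth
armoured catfishes (tens of species, a few specimens each, ~33 body
landmarks, published phylogenies), but every step is generic.

The analytical core:

- **Shape**: generalized Procrustes superimposition (reflections forbidden,
  reproducible principal-axis orientation), species mean shapes from one
  joint alignment, PCA of species means with broken-stick axis selection
  (axis *i* of *p* retained while its share exceeds
  b_i = (1/p) Σ_{j≥i} 1/j), backtransformed theoretical shapes, and
  phylomorphospace projection through Brownian-motion (GLS) ancestral
  estimates.
- **Phylogenetic signal**: the multivariate K statistic
  K = [SSE₀/SSE] / [(tr C − n(1′C⁻¹1)⁻¹)/(n−1)], equal to 1 in expectation
  under single-rate Brownian motion, with permutation p-values.
- **Modularity**: the covariance ratio
  CR = √( tr(S₁₂S₂₁) / √(tr(S₁₁°S₁₁°)·tr(S₂₂°S₂₂°)) ) (mean over module
  pairs for >2 modules), tested by randomizing the landmark partition, with
  phylogenetic correction by the tree's inverse-square-root transform;
  model comparison across a ten-hypothesis battery by log-CR effect sizes;
  EMMLi-style maximum-likelihood selection with pooled within/between
  correlations on the Fisher-z scale and AICc weights.
- **Integration**: phylogenetic two-block PLS; rPLS is the correlation of
  the first singular-variate pair of the between-block covariance.
- **Rates**: per-module Brownian rate ratios tested against single-rate
  replication along the tree, and penalized-likelihood multirate Brownian
  motion (per-branch rates, smoothing coefficient λ).
- **Macroevolution**: Stayton's C1-C4 convergence metrics with
  Brownian-simulation p-values, morphospace ellipse crossing counts, and
  disparity-through-time profiles at 31 time slices with burst detection
  (disparity step > 10 between consecutive slices).

A block-structured Brownian simulator (`sim_spec()`,
`simulate_modular_shapes()`) generates landmark datasets with known modular
covariance, per-module rates and digitizing noise, so the whole chain is
testable without any external data.

## Worked example

Simulate a 40-species dataset under the seven-module covariance structure
with the caudal module evolving five times faster, then run the analysis:

```r
library(morphmod)

spec <- sim_spec(n_species = 40, rate_multipliers = c(1, 1, 1, 1, 1, 1, 5),
                 seed = 11)
sim   <- simulate_modular_shapes(spec)   # specimens, tree, true module map
fit   <- gpa_align(sim$specimens)
means <- species_mean_shapes(fit)

pca <- shape_pca(means)
pca
#> Shape PCA: 40 species, 39 axes
#>   variance: PC1 28.2%, PC2 19.5%, PC3 13.8%, PC4 8.1%, PC5 6.2%, ...
broken_stick_axes(pca)
#> [1] 5

flat <- as_species_matrix(means)
kmult(flat, sim$tree, n_perm = 999, seed = 1)
#> Multivariate phylogenetic signal
#>   K = 0.7290, p = 0.001 (999 permutations, 40 species)

modularity_test(flat, sim$module_map, tree = sim$tree, n_perm = 999,
                d = 3, seed = 2)
#> Phylogenetically corrected covariance-ratio test
#>   CR = 0.5329, p = 0.001, Z = -7.563 (999 permutations)

integration_test(flat, sim$module_map, tree = sim$tree, n_perm = 999,
                 d = 3, seed = 3)
#> Phylogenetic two-block PLS integration test
#>   overall r-PLS = 0.5342, p = 0.001 (999 permutations)

compare_cr_models(flat, module_battery(sim$module_map), tree = sim$tree,
                  n_perm = 999, d = 3, seed = 4)$best
#> [1] "seven_modules"

module_rate_ratio_test(flat, sim$module_map, sim$tree, n_sim = 999,
                       d = 3, seed = 5)
#> Evolutionary rate ratio test among modules
#>   per-module sigma^2:
#>        m1        m2        m3        m4        m5        m6        m7
#> 0.0001750 0.0001520 0.0002284 0.0001970 0.0002143 0.0002774 0.0011910
#>   max/min ratio = 7.835, p = 0.001 (999 simulations)
```

Reading the output: K < 1 reflects the digitizing noise added on top of the
Brownian signal; CR = 0.53 (p = 0.001) says between-module covariance is
about half what random partitions of the same sizes produce, i.e. the body
is clearly modular; the moderate rPLS says the modules still covary; the
model comparison recovers the generating seven-module partition; and the
rate test isolates the fast caudal module (its rate is the outlier, and the
max/min ratio exceeds the simulated 5x because the ratio of a maximum to a
minimum estimate is upward-biased at finite sample size).

`run_pipeline()` drives the same analysis from a YAML config (landmark TPS
or CSV file, Newick tree, module-map CSV, seed) and writes all result
tables, disparity profiles and a manifest to an output directory;
subfamily-style subgroups with at least five species are re-analysed
automatically.

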