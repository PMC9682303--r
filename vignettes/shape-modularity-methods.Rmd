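---
title: "Methods: phylogenetic modularity and integration of landmark shapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic modularity and integration of landmark shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

morphmod implements a complete comparative analysis of body-shape modularity
and integration for landmark data on a phylogeny, of the kind used to ask
whether an organism's body evolves as a single integrated unit or as
semi-independent regional modules (the motivating system is the suckermouth
armoured catfishes, whose fused neurocranium/pectoral girdle and independent
oral jaw suggest a head/postcranium or finer regional modular organization).
This vignette documents the models, the tunable parameters, the numerical
choices, and what the simulation-based tests do and do not establish.

## Shape analysis

**Procrustes superimposition.** `gpa_align()` removes translation (centroids
to the origin), size (unit centroid size) and orientation (least-squares
rotation to an iteratively updated consensus; iteration stops when the
root-mean-square change of the consensus drops below `tol = 1e-10` or after
`max_iter = 100` rounds). Rotations are constrained to determinant +1:
specimens have handedness, so reflections are never admissible. After
convergence the consensus is rotated to its principal axes with a sign
convention taken from the consensus coordinates themselves (first d-1 axes:
largest-magnitude coordinate positive; the last sign preserves determinant
+1), so output orientation is reproducible and invariant to how the input
was oriented. Orthogonal projection to the tangent space is available
(`project = TRUE`) but off by default; downstream Euclidean operations
assume small shape variation either way, and the projection makes almost no
numerical difference in that regime. Species means are computed from one
joint superimposition of all specimens — never from per-species alignments —
and are re-centered but not re-superimposed (means of aligned configurations
are already centered up to numerical error).

**Ordination.** `shape_pca()` is an SVD of the centered, flattened
species-mean coordinates (covariance denominator n − 1), with no
phylogenetic correction so that convergence remains visible in the
morphospace. Axis signs follow a deterministic largest-loading-positive
convention. `broken_stick_axes()` retains the initial run of axes whose
variance share strictly exceeds the broken-stick expectation
b_i = (1/p) Σ_{j≥i} 1/j; counting stops at the first failure so the retained
set is always contiguous. Strictness and the stop-at-first-failure rule are
the standard stopping form and prevent non-contiguous "significant" sets.
`backtransform_shape()` reconstructs theoretical shapes anywhere in the
morphospace as mean + Σ score·loading.

## Brownian-motion machinery

All phylogenetically corrected statistics share one kernel
(`phylo_vcv()`, `phylo_transform()`, `ancestral_states_bm()`): the tree
covariance C (shared root-to-ancestor path lengths), the GLS phylogenetic
mean, and the transformation U = C^{-1/2}(Y − 1â′) whose rows are
uncorrelated under single-rate Brownian motion. The inverse square root is
computed by eigendecomposition with eigenvalues floored at 1e-12, because
trees with very short terminal branches make C nearly singular. The
transform is deliberately not idempotent and the API refuses to apply it
twice. Ancestral states are GLS/ML estimates per trait; the root estimate
equals the phylogenetic mean used by the transform (asserted in tests).

**Phylogenetic signal.** `kmult()` is the multivariate generalization of
Blomberg's K: the ratio of the tips' mean squared deviation from the
phylogenetic mean to its phylogenetically corrected counterpart, scaled by
the Brownian expectation (tr C − n/(1′C⁻¹1))/(n − 1) so K ≈ 1 under
single-rate Brownian motion. Significance comes from permuting species
across tips; permutation p-values throughout the package use the
(b + 1)/(m + 1) estimator, which can never return zero. One practical
caveat documented here because it shaped the simulator defaults: K is
extremely sensitive to non-phylogenetic noise on trees with short terminal
branches (the phylogenetically corrected denominator amplifies white noise
by the reciprocal of terminal branch lengths), so digitizing error that is
harmless for covariance-structure analyses can depress K well below 1.

## Modularity and integration

**Covariance ratio.** For module blocks S11, S22 (within, diagonals zeroed)
and S12 (between), CR = √( Σ S12² / √(Σ S11°² · Σ S22°²) ); for more than
two modules the statistic is the mean over module pairs. CR = 1 is the
no-modularity anchor, values below 1 indicate modularity, values above 1
between-module covariance exceeding within-module covariance.
`modularity_test()` builds the null by randomly reassigning landmarks to
modules (module sizes preserved — the hypothesis under test is the
partition, so the partition is what gets randomized), reports the raw-scale
effect size Z = (obs − mean null)/sd null and a lower-tail p-value.
`compare_cr_models()` ranks competing partitions by the effect size of
log(CR) against each model's own permutation null; the log scale stabilizes
the variance of a ratio statistic whose null mean and spread both shift
with module count. A one-module hypothesis has no CR and anchors the
"no modularity" end of the table.

A limitation worth stating plainly: when the data-generating structure has a
*uniform* between-module correlation, every coarsening of the true partition
is itself a valid modular hypothesis (its between-module correlation is
exactly as low as the truth's), and partitions then differ only in
refinement. CR effect sizes discriminate refinement weakly in that regime —
simulations in the acceptance suite recover the generating seven-module
model by CR effect size in roughly three quarters of runs, with the
remainder going to coarser merges of adjacent regions — whereas the
likelihood route (below) prices every mis-pooled landmark pair and recovers
the generating model essentially always. Superimposition compounds this
mildly: Procrustes alignment removes the rigid-motion-like component that
uniform between-module correlation produces and couples geometrically
adjacent landmarks, making adjacent-region merges genuinely competitive in
the empirical covariance.

**Integration.** `integration_test()` computes, per module pair, the
singular value decomposition of the between-block covariance of the
(optionally phylogenetically transformed) data; rPLS is the absolute
correlation of the first pair of singular-variate scores, the overall
statistic the mean over pairs, and the null permutes the species rows of
one block. Pairwise p-values are reported raw, as is conventional for these
tests; a Benjamini-Hochberg adjusted column is emitted for reference but
plays no role in any summary. Summary networks label rPLS ≥ 0.75 as high
integration and CR ≥ 1.00 as high covariation; both cut-offs are arguments.

**Likelihood model selection (EMMLi).** `emmli_fit()` builds the
landmark-by-landmark congruence-coefficient matrix (inner-product
correlation of the d-dimensional landmark deviations — the natural
association measure when each landmark is a d-vector), pools correlations
into one rho per within-module set and one per between-module pair, and
scores each hypothesis by a Fisher-z normal likelihood: z(r) ~
N(z(rho), 1/(n_species − 3)). Models are compared by AICc with K = number
of distinct rho parameters + 1. The AICc sample size is the number of
unique landmark pairs — the data points entering the likelihood — not the
species count; with the species count in the denominator the small-sample
correction overwhelms any parameter-rich model at realistic sizes, which
contradicts the method's well-documented (and here intended) willingness to
adopt richly parametrized models when the pairwise correlations support
them. Species count still controls the Fisher-z variance, so fewer species
always means flatter model discrimination. Models with more parameters than
pairs are flagged unfit and excluded from the Akaike weights.

**The hypothesis battery.** `module_battery()` holds ten models from fully
integrated to seven modules, built by merging a seven-region base map
(mouth, neurocranium, opercula, pectoral+dorsal fins, pelvic fins, anal
area, caudal peduncle). The two-module (head/postcranium), three-module
(head/midbody/tail) and four-module (mouth | skull | fins | tail) groupings
are the biologically named hypotheses; the intermediate models refine the
four-module groupings one merger at a time so the battery forms a nested
hierarchy. The shipped 33-landmark base map is a labelled reconstruction of
the seven body regions (region sizes 6/10/4/5/4/2/2); real datasets should
supply their own map via `read_module_map()`.

## Evolutionary rates

`module_rate_ratio_test()` estimates each module's multivariate Brownian
rate as the mean squared phylogenetically transformed deviation over the
module's coordinates and tests the max/min ratio against datasets
replicated along the phylogeny under single-rate Brownian motion. The null
keeps one common per-trait rate (the pooled estimate) but preserves the
observed trait correlations; an independent-trait null would understate the
sampling variance of per-module rate sums whenever coordinates are
correlated — which landmark data always are — and inflate the false
positive rate.

`multirate_bm()` fits branch-specific rates to a single trait (in practice
each significant PC axis separately) by penalized likelihood: trait
log-likelihood plus lambda times the log-density of the log-rates
themselves evolving by Brownian motion on the tree. Rates live on the log
scale at every node, an edge's rate is exp of the mean of its endpoint
log-rates, and optimization is BFGS with numerical gradients started from
the single-rate ML estimate (reproducibility over speed; the fit is
deterministic given the data). Lambda defaults to 1, an intermediate
penalty; as lambda grows the profile flattens onto the single-rate estimate
(asserted within 1% at lambda = 1e6), and the variance of fitted log-rates
is empirically non-increasing in lambda.

## Convergence and disparity through time

`convergence_c_metrics()` implements the C1-C4 distance measures: per focal
pair, Dtip is the tips' phenotypic distance and Dmax the maximum distance
between any two points (ancestral estimates or tips) on the two paths since
divergence; C1 = 1 − Dtip/Dmax, C2 = Dmax − Dtip, C3 scales C2 by the
phenotypic path length of the two lineages, C4 by the total phenotypic
evolution in the clade spanned by the focal taxa. Metrics are averaged over
focal pairs. p-values are the plain proportion of Brownian simulations
(rate matrix estimated from the data) reaching the observed value — these
are simulation, not permutation, p-values and may legitimately be zero.

`convnum_ellipse()` places the minimal-area enclosing ellipse (Khachiyan's
algorithm, rescaled so all focal points satisfy the quadratic form exactly)
around the focal taxa in a two-axis morphospace and counts root-to-tip
lineages whose ancestral polyline enters it. Because the original
construction of the ellipse is not specified beyond "an ellipse around the
convergent taxa", the enclosing-ellipse choice is documented as this
package's convention and the ellipse area is reported for reference only.
Counts are reported both including and excluding the focal lineages.

`disparity_through_time()` slices the tree at `n_slices = 31` evenly spaced
times from root to present; each branch alive at a slice contributes a
point linearly interpolated between its parent and child positions
(ancestors by GLS), and disparity is the mean squared pairwise Euclidean
distance among those points. The mean-squared form is stable across lineage
counts; absolute disparity magnitudes are therefore not comparable to
conventions that sum rather than average, and only profile shape, ordering
and burst structure are meaningful quantities. `detect_bursts()` flags
intervals whose disparity increase strictly exceeds a threshold (default
10, matching the burst convention the profile analysis was built around);
adjacent qualifying intervals are separate bursts.

## The synthetic-data generator

`simulate_modular_shapes()` is the package's test bed: species mean
deviations evolve by multivariate Brownian motion on a pure-birth tree
(depth rescaled to 1) with a block trait covariance — unit diagonal,
`within_module_corr` inside each module's coordinate block,
`between_module_corr` elsewhere, per-module rate multipliers applied
symmetrically — and specimens add isotropic digitizing noise around their
species mean. Configurations are emitted around a regular polygon (2D) or
helix (3D) so superimposition is well conditioned. Defaults mirror the
emulated study system: 71 species, 33 landmarks in 3D partitioned
6/10/4/5/4/2/2 into seven regions, 3-5 specimens per species, within/between
correlations 0.7/0.1 for the modular regime. Scale parameters are expressed
relative to the base shape's RMS landmark radius: Brownian divergence
accrues sd 0.1 per unit tree depth per coordinate and digitizing noise has
sd 0.005 — an order of magnitude apart, as in family-level comparative data
where landmarking error is small against interspecific differences. The
positive definiteness of the block covariance is checked at construction.

What the generator does not emulate: allometry and size variation (the
generator works directly in shape space), semilandmark sliding, missing
landmarks, asymmetric digitizing protocols, and — importantly — any
non-rigid-motion structure for the between-module correlation. Passing
calibration tests on these simulations shows the statistics behave as
designed under their own model; it does not certify behaviour under model
violations such as heterogeneous noise or strongly allometric data.

## Problem sizes used by the test suite

Unit tests run each operation at small sizes (5-60 species, 6-21
landmarks). The calibration suite runs the conditions the methods are
designed around: 200 datasets of 40 species x 20 2D landmarks for the
covariance-ratio null anchor and the type-I checks, 500 Brownian
simulations on a 30-tip tree for the Kmult anchor, 100 end-to-end runs at
the generator defaults for model recovery, and 100 runs of 50 species for
the five-fold rate recovery. These sizes were chosen as the smallest at
which the quantities of interest are estimated stably.

## Pipeline

`run_pipeline()` executes the full analysis order — superimposition,
species means, ordination with broken-stick selection, phylomorphospace,
Kmult, modularity with model comparison, integration, EMMLi, rate ratios,
disparity through time, and convergence when focal taxa are configured —
from a YAML or list config with a mandatory seed; every stage draws its
randomness from fixed offsets of that seed, so reruns are byte-identical.
Subgroups (e.g. subfamilies) with at least five species are re-analysed
from the joint superimposition's species means; smaller subgroups are
skipped with a logged warning, mirroring how sparsely sampled lineages are
conventionally excluded. This package is a library with a programmatic
interface; the pipeline function and the exported analysis functions are
the intended entry points and no shell executable is installed.
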