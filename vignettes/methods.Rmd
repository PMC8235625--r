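---
title: "Methods: sliding semilandmarks, phylogenetic signal, and rate shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding semilandmarks, phylogenetic signal, and rate shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and the numerical and design choices
behind `morphorate`, in the spirit of a methods supplement: what each stage
assumes, which knobs matter, and what the synthetic test bed does and does
not demonstrate about real data.

## The study design the package implements

The package analyzes 3D landmark configurations of limb long bones
(humerus, femur) across a clade of species split into two locomotor
categories: vertical clinging and leaping (VCL; trunk-to-trunk leaping on
large vertical supports) and horizontal leaping (HL; leaping among thin,
compliant terminal branches). Questions addressed: does bone *size* differ
between categories once phylogeny is accounted for; does bone *shape* carry
phylogenetic signal and allometry; can the categories be told apart from
shape; and did evolutionary *rates* of size and shape shift in particular
clades.

## Thin-plate splines and bending energy

All semilandmark machinery rests on the 3D thin-plate spline. For a
reference configuration of k landmarks we build the bordered kernel system
with kernel phi(r) = -r. The sign matters: with -r the landmark block of
the inverse bordered system is a positive semidefinite quadratic form — the
bending energy — while with +r the same block is negative semidefinite and
"minimum bending energy" would be ill-posed. The interpolating warp itself
is identical under either sign. Numerically, eigenvalues of the energy
matrix that are negative by roundoff are clipped to zero; the clipping
threshold is relative to the spectral radius (1e-10 × the largest
eigenvalue), because an absolute threshold is meaningless across coordinate
scales. A reference whose points are coplanar or collinear makes the
bordered system singular and is rejected with an explicit error.

## Sliding semilandmarks

Curve semilandmarks slide along one tangent (the normalized chord between
their curve neighbours, one-sided at curve ends); surface semilandmarks
slide in the tangent plane orthogonal to the nearest mesh vertex normal.
With `y` the stacked specimen coordinates, `x` the reference superimposed
onto the specimen (ordinary Procrustes with scaling), `U` the block tangent
basis and `B` the three-axis block-diagonal bending-energy form of the
superimposed reference, the sliding amplitudes minimize the quadratic
`(y + Ut - x)' B (y + Ut - x)`, with the closed form
`t* = -(U'BU)^-1 U'B (y - x)`. Choices:

* **Slide-then-project.** After every sliding step, curve points are
  re-projected onto the piecewise-linear curve through their pre-slide
  positions, and surface points onto the specimen mesh (exact
  point-to-triangle projection). Projection keeps semilandmarks on
  anatomy; it can raise the energy slightly above the unconstrained
  minimum, which is why monotonicity assertions carry a small relative
  tolerance.
* **Singular sliding systems.** `U'BU` can become numerically singular
  when projection makes neighbouring curve points nearly coincide; the
  solver then falls back to a ridge-regularized solve and warns.
* **Which points slide when relaxing to a template** is flag-controlled;
  the default slides both curve and surface semilandmarks.
* **Replicate digitizations** are combined by rigid (no-scale) ordinary
  Procrustes alignment of the second replicate onto the first and
  coordinate averaging — the minimal-variance combination that leaves the
  specimen's scale untouched.
* **Relaxation against the consensus** repeats (GPA, consensus, one
  sliding step per specimen) three times by default, the conventional
  iteration count for this workflow.

## Superimposition

GPA uses full Procrustes: every configuration is centered and scaled to
unit centroid size, rotations are proper only (no reflections — left/right
bones must never be mirrored implicitly; side handling is the caller's
job), the consensus is re-estimated and re-unitized until it changes by
less than 1e-10 (at most 100 iterations). The original workflow does not
state whether size was removed during superimposition; unit-size scaling
is assumed here because it is the convention of the superimposition
routines this pipeline mirrors. Species mean forms are the per-species
Procrustes consensus multiplied by the arithmetic mean of the specimens'
raw centroid sizes (mm).

## Phylogenetic signal, ANOVA, MANCOVA

* **Blomberg's K / Kmult.** K is the ratio of observed to
  phylogenetically-transformed mean squared deviations from the GLS mean,
  normalized by its Brownian expectation; Kmult is the same ratio with
  squared deviations summed over all shape dimensions and reduces exactly
  to K for one dimension. Both are tested by permuting species across tips
  (default 10,000 permutations, add-one p-values). A star phylogeny gives
  K = 1 identically, so polytomies are allowed for these statistics.
* **Phylogenetic ANOVA.** The observed one-way F is compared with F values
  from Brownian simulations on the tree (default 1000), the rate estimated
  from the data by the mean squared phylogenetically independent contrast.
  This is the stage that separates "VCL bones are smaller" from "the
  VCL-rich clades happen to be small": a clade-confounded size difference
  gives a significant t-test whose phylogenetic p-value is null-calibrated
  (the calibration experiment in the test suite runs 500 such replicates).
* **MANCOVA.** Shape is reduced to the leading principal components
  covering 95% of variance, then modelled sequentially (Type I) as
  `scores ~ size + locomotion + size:locomotion` with Pillai's trace and
  Rao's F per term, every term tested against the full-model residual
  SSCP. The implementation computes the sequential SSCP decomposition
  directly (and is cross-checked against `stats::manova` in the tests) so
  that a single retained axis degrades exactly to the univariate
  sequential ANCOVA.

## Between-group PCA and classification

The between-group axes are the eigenvectors of the covariance of the group
mean vectors (equal group weights); with two groups there is exactly one
axis, collinear with the difference of group means. Classification uses
squared Mahalanobis distances to each group mean under the pooled
within-group covariance, converted to typicality probabilities by the
small-sample F transformation; assignment is by arg-max probability, and
specimens whose best typicality falls below 0.05 are flagged atypical but
still assigned (a single accuracy number is reported). Cross-validation
leaves the evaluated specimen out of *everything*: the between-group axes,
the group means, and the pooled covariance. Leaving the axes in (the
common shortcut) inflates chance-level accuracy well above 50% — the
known between-group-PCA overfitting artifact — which is why the full chain
is re-fit per specimen. By default the classifier operates in the
PC-reduced space used for the MANCOVA; full shape space is available by
flag. Group separation is additionally tested by permuting labels and
comparing Euclidean distances between group means (one-tailed, add-one,
10,000 permutations by default).

## Phylogenetic ridge regression and rate shifts

Tip phenotypes (species mean shapes as flattened vectors, or log centroid
size) are centered on the phylogenetic GLS mean and regressed on the
root-to-tip path design `X` (entry = branch length if the branch is on the
tip's path, else 0). The ridge solution `beta = (X'X + lambda I)^-1 X'y`
assigns every branch a rate vector; its Euclidean norm is the branch's
rate magnitude. The reference method's exact penalty-tuning rule is not
published; here `lambda` is chosen by golden-section search on
log-lambda minimizing the leave-one-out tip prediction error (computed
exactly from the SVD hat matrix), a documented stand-in validated by
calibration rather than equivalence.

For the shift search, every clade with 2 to n/2 tips is scored by the
difference between its branches' mean rate magnitude (stem branch
included) and the mean over the rest of the tree, with a two-tailed
randomization p-value from globally shuffling magnitudes across branches.
One deliberate deviation from the simplest form of this null: magnitudes
are **length-standardized** (multiplied by the square root of their branch
length) before the statistic and the shuffle. Under Brownian motion the
rate estimate of branch e has standard deviation proportional to
1/sqrt(t_e), so raw magnitudes are systematically larger on short
branches, and shuffling raw magnitudes flags short-branch clades far in
excess of the nominal level (we measured ~30% flagging for the
shortest-branch clades in null simulations). With standardization the
per-tree flagged proportion sits near the nominal 5% while a genuine
sigma-squared multiplier — which scales magnitudes uniformly — is still
recovered (the planted-shift experiment in the test suite detects an 8×
clade in essentially every replicate). The raw behaviour remains available
via `standardize = FALSE`. Per-clade significance is reported raw, with a
Benjamini–Hochberg column alongside.

## Ancestral states

Parsimony reconstruction is exact: `cost(v, s)`, the minimum number of
changes over the whole tree with node v fixed in state s, is computed by
dynamic programming with rerooting, and each node's probability vector is
uniform over its set of states attaining the minimum (the full MPR set).
This reproduces the unresolved 0.5/0.5 root for the study's VCL/HL coding
and matches brute-force enumeration on small trees. Stochastic character
mapping uses the equal-rates 2-state Markov model with maximum-likelihood
rate and a flat (0.5/0.5) root prior — the conventional default, recorded
in the output — and reports per-node posterior frequencies with Monte
Carlo standard errors.

## Composite trees

Taxa missing from the time-calibrated backbone are added from patch
phylogenies by cross multiplication: the scaling factor is the ratio of the
shared species' root-to-tip depth in the backbone to its depth in the
patch, and the new taxon attaches to the shared species' lineage at the
scaled divergence time with a matching pendant length. When that time falls
above an internal node, the attachment simply moves to the corresponding
ancestral edge (making the new taxon sister to a larger clade); a scaled
divergence older than the backbone root is a hard error. The exact
within-edge attachment rule is not specified by the workflow this mirrors;
attaching on the lineage's edge at the scaled time is the documented
choice. Ultrametric inputs yield ultrametric composites. Polytomies are
rejected everywhere a bifurcating tree is assumed (parsimony, contrasts,
grafting) rather than silently resolved.

## The synthetic test bed

`simulation_recipe()` fixes the generating model; its defaults are the
study conditions:

| parameter | default | meaning |
|---|---|---|
| tree | 25-species callitrichid fixture | topology as published; branch lengths APPROXIMATE (My) |
| group_map | study VCL/HL coding | 15 VCL, 10 HL |
| base_rate | 1e-4 | Brownian rate of shape change (Procrustes units² / My / coordinate); gives tip-to-tip shape distances of a few hundredths of a Procrustes unit over the ~15 My tree depth, the magnitude typical of congeneric long-bone data |
| group_offset_magnitude | 0.02 | VCL mean-shape offset (Procrustes distance), a subtle but detectable ecological signal |
| allometry_slope | 0.02 | shape change per unit log centroid size along a seeded direction |
| size_base_log, size_rate | 4.0 log-mm, 0.002 /My | log centroid size evolves by Brownian motion (≈ 55 mm centroid size, ~0.17 sd over the tree) so size carries phylogenetic signal |
| specimen_noise_sd | 0.002 | per-coordinate digitization/individual noise |
| n_specimens | 3 | up to three specimens per species, as in museum sampling |

Shape simulation happens in the tangent space at the template (flattened
unit-size coordinates) and configurations are re-embedded afterwards — the
standard small-deformation shortcut that avoids simulating on the curved
shape manifold. Specimens are realized by scaling to their drawn centroid
size, TPS-warping the template mesh to each specimen (so surface
semilandmarks lie exactly on a valid mesh), and applying a random rigid
motion.

What the generator does *not* emulate: real callitrichid bone geometry
beyond the landmark-role structure, digitization biases that correlate
across landmarks, measurement error in the phylogeny, bilateral asymmetry,
or non-Brownian evolutionary processes (no Ornstein–Uhlenbeck optima).
Passing the calibration experiments therefore shows the statistics are
correct and calibrated *under the stated generating model*, not that real
data meet that model.

## Problem sizes in the shipped experiments

The test suite keeps the simulations at sizes chosen to make the
calibration targets statistically meaningful while remaining quick to run:
500 Brownian replicates for the K/Kmult and phylogenetic-ANOVA
calibrations (binomial standard error ≈ 1% at the 5% level), 200
replicates with 1000 randomizations each for the rate-shift power and null
experiments, 200 replicates for classifier chance level and permutation
uniformity, and small (≈ 40–70 landmark, ≈ 700 vertex) templates for the
geometric stages, where the properties under test are scale-free.

## Known limitations

* Sliding projects curve points onto the polyline through their pre-slide
  positions; extremely coarse curves can make adjacent semilandmarks
  collapse onto a shared vertex (handled by the regularized solver, but a
  denser resampling is the real fix).
* The ridge-regression rate field shrinks all branches jointly; rates on
  branches with little data (deep, short) are strongly regularized and
  only their clade-level aggregation is tested.
* `phyl_anova` estimates the Brownian rate from the same data it
  simulates under, which is standard but slightly anticonservative for
  very small trees.
* No missing-landmark estimation, no bilateral symmetry decomposition, no
  2D support.
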