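# morphorate

Phylogenetically-informed 3D geometric morphometrics and evolutionary
rate-shift detection for limb long bones, built around the study design of
callitrichid primates (tamarins and marmosets): two locomotor categories —
vertical clinging and leaping (VCL) on large trunks versus horizontal
leaping (HL) among terminal branches — whose functional demands may be
written into humeral and femoral shape.

## What the package does

Starting from per-specimen 3D landmark configurations (fixed anatomical
landmarks, ordered curve semilandmarks, surface semilandmark patches on
triangulated meshes), a time-calibrated phylogeny, and a locomotor
category per species, the pipeline runs:

1. **Semilandmark processing** — curve resampling to equal arc-length
   spacing; template-based transfer of surface semilandmarks onto each
   specimen mesh through a thin-plate-spline (TPS) warp followed by
   closest-point projection; sliding of semilandmarks along their tangent
   directions by exact minimization of TPS bending energy, first against a
   template and then for three iterations against the Procrustes consensus.
   With `y` the stacked specimen, `x` the superimposed reference, `U` the
   tangent basis and `B` the bending-energy form, one sliding step is the
   closed-form GLS minimizer `t* = -(U'BU)^-1 U'B(y - x)`.
2. **Superimposition** — generalized Procrustes analysis (full Procrustes:
   centered, unit centroid size, proper rotations only) and species mean
   forms (Procrustes consensus × mean centroid size).
3. **Comparative statistics** — Blomberg's K for log centroid size and its
   multivariate generalization (Kmult) for shape, tested by permutation;
   Welch's t-test plus simulation-based phylogenetic ANOVA for group
   differences in size; MANCOVA (sequential Pillai tests) of retained
   principal components (95% of variance) on log size, locomotor group and
   their interaction.
4. **Classification** — between-group PCA, cross-validated typicality
   probability classification (small-sample F transformation, with the
   full axis-plus-classifier chain left-one-out), and a permutation test
   of the Euclidean distance between group mean shapes.
5. **Evolutionary rates** — phylogenetic ridge regression: tip phenotypes
   are regressed on the design of root-to-tip branch paths,
   `beta = (X'X + lambda I)^-1 X'y` with the penalty chosen by
   leave-one-out prediction error, giving a rate vector per branch; clade
   rate shifts are found by comparing each clade's mean rate magnitude
   (length-standardized) with the rest of the tree under a randomization
   null.
6. **Ancestral states** — exact maximum-parsimony reconstruction of the
   binary locomotor character (full most-parsimonious state sets per node)
   and stochastic character mapping under the equal-rates Markov model.

A synthetic-data module generates bone-like templates (watertight meshes
with all three landmark roles), species mean shapes evolving by Brownian
motion with clade-specific rate multipliers, locomotor group offsets,
allometry tied to log centroid size, and specimen-level noise — so every
stage is testable against known ground truth without any downloads.

## Worked example

```r
library(morphorate)

# a synthetic study: 25 species, 2 specimens each, with allometry and a
# VCL group shape offset
rec <- simulation_recipe(seed = 42, n_specimens = 2)
atlas <- make_template(n_fixed = 6, curve_counts = c(8, 8),
                       n_surface = 20, seed = 42)
ds <- simulate_dataset(rec, atlas = atlas)

cfg <- pipeline_config(dataset = ds, out_dir = "analysis_out",
                       n_perm = 200, n_sim = 200, n_rand = 200, seed = 7)
bundle <- run_pipeline(cfg)

bundle$signal_size$K          # 0.649  : strong phylogenetic signal in size
bundle$signal_shape$K         # 0.717  : Kmult for shape
bundle$retained_pcs$n_axes    # 15     : axes covering 95% of shape variance
bundle$mancova                # size p = 0.028, locomotion p = 0.0013,
                              # interaction p = 0.31 (sequential Pillai)
bundle$classification$accuracy  # 88   : % correct cross-validated
                                #        VCL/HL reclassification
bundle$group_permutation$p    # 0.005  : group mean-shape distance test
bundle$asr_parsimony$root_probs # 0.5 / 0.5 : unresolved root state
head(bundle$shifts_shape)     # per-clade rate differences with p-values
```

The numbers above are what this exact configuration prints: the generator
planted allometry and a VCL offset (both detected by the MANCOVA and the
classifier), size evolved by Brownian motion (detected as phylogenetic
signal), and the VCL/HL coding of the study taxa leaves the root state
unresolved under parsimony (probability 0.5 for each state).

The study phylogeny fixture (`callitrichid_tree()`, 25 species with
APPROXIMATE branch lengths) and the locomotor coding
(`callitrichid_locomotion()`) ship in `inst/extdata/`.

A command-line wrapper over the same pipeline is in
`inst/scripts/run_pipeline.R` (`--config analysis.yaml --seed 1 --out dir`).

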