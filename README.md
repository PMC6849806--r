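# jointatlas

Fully automated multi-atlas segmentation of the left atrium (LA), pulmonary
veins (PVs) and left atrial appendage (LAA) from 3D bright-blood MRA, using
**joint-atlas-optimization**: instead of registering each annotated atlas to
the target image independently (the conventional pairwise approach), the
target is embedded in the atlas group and one groupwise registration aligns
all `N + 1` images at once by minimizing the intensity variance over the
group,

```
C(mu) = (T_mu(I) - Ibar_mu)^2 + sum_i (T_mu(A_i) - Ibar_mu)^2,
Ibar_mu = 1/(N+1) [ T_mu(I) + sum_i T_mu(A_i) ]        (the mean-shape image)
```

with `mu` the ensemble of one transform (affine + cubic B-spline free-form
deformation) per image.  Atlas labels are propagated to the mean-shape
image, fused by per-voxel majority voting over the full label roster
(background, LA chamber, LSPV, LIPV, RSPV, RIPV, LAA), back-propagated to
the target through the inverse of the target's transform, and refined by a
3D Chan-Vese level set.  Aligning every image to the evolving group mean
regularizes the problem: atlases too far from the target to register
pairwise are still pulled into the common frame by their proximity to other
atlases, which is what rescues the thin distal PV tubes where pairwise
multi-atlas segmentation degrades.

The package is for researchers in cardiac image analysis who want a
complete, self-contained reference implementation of the groupwise
formulation next to its pairwise baseline: both modes share one transform
model, optimizer (stochastic gradient descent with decaying gain,
multi-resolution), fusion rule and refinement, so comparisons isolate the
registration strategy.  A synthetic LA phantom generator with known
ground-truth anatomy and known inter-subject deformations makes the whole
pipeline testable without patient data.

## Worked example

```r
library(jointatlas)

# a synthetic study: one target + 10 annotated atlases with known warps
spec <- phantom_spec(shape = c(48, 48, 32), spacing = c(2.5, 2.5, 4.54),
                     seed = 11)
aset <- make_atlas_set(spec, 10,
                       amplitude_overrides = c(18, 18, rep(8, 8)),
                       warp_spacing_overrides = c(40, 40, rep(25, 8)))
cfg <- registration_config(iterations_per_resolution = 300, seed = 5)

seg_joint <- la_segment(aset$target$image, aset$atlases, "joint", cfg,
                        refine = FALSE)
seg_pair  <- la_segment(aset$target$image, aset$atlases, "pairwise", cfg,
                        refine = FALSE)

ej <- evaluate(seg_joint$atlas_segmentation, aset$target$labels)
ep <- evaluate(seg_pair$atlas_segmentation, aset$target$labels)
data.frame(structure = ej$structure,
           joint = round(ej$dice, 3), pairwise = round(ep$dice, 3))
```

On this study (two of the ten atlases carry deliberately large
deformations, the regime in which individual pairwise registrations fail)
the run above prints:

```
   structure joint pairwise
1   whole_LA 0.934    0.934
2 LA_chamber 0.948    0.963
3       LSPV 0.807    0.704
4       LIPV 0.905    0.773
5       RSPV 0.836    0.734
6       RIPV 0.667    0.650
7        LAA 0.673    0.713
```

Whole-LA accuracy is matched, but every pulmonary vein is segmented more
accurately by the joint mode (tube mean Dice 0.804 vs 0.715): the
disagreement of the pairwise vote concentrates exactly at the distal
tubes, and the joint formulation removes the failing registrations that
cause it.  The directed whole-LA surface-to-surface distance tells the
same story (0.75 mm joint vs 1.03 mm pairwise).  Adding the level-set
refinement (`refine = TRUE`) improves both modes and preserves the
ordering.

A thin command-line front end (`inst/cli/jointatlas.R`) exposes
`simulate` (write a phantom atlas directory), `segment` and `evaluate`
for shell use; volumes are read and written as MetaImage (`.mhd`) or
NIfTI (`.nii`, `.nii.gz`).

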