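# wmhseg

Automated segmentation of white matter hyperintensities (WMH) from FLAIR
MRI, with validation tools and synthetic phantoms.

WMHs are bright white-matter regions on fluid-attenuated inversion
recovery (FLAIR) MRI, a common finding in older people that is associated
with small-vessel disease and cognitive decline. Large-cohort studies need
their volume measured automatically. This package implements, as plain R
functions over NIfTI-1 volumes:

- **Modal-intensity thresholding** (`segment_threshold()`): on the
  skull-stripped FLAIR, find the modal in-brain intensity *M* (the
  histogram peak, which tracks normal white matter), keep voxels with
  intensity > 1.45 · *M*, and remove isolated clusters below a minimum
  size.
- **Seeded fuzzy connectedness** (`segment_fuzzy()`): detect lesion seeds
  at intensity ≥ mean + *k*·SD of the in-brain histogram (*k* = 3, with a
  2.5 variant), grow them by max–min path strength under a Gaussian
  intensity-affinity kernel, iteratively re-detect seeds among unsegmented
  voxels until none remain, and pool the clusters.
- **A priori lesion probability maps** (`build_prior()`): the voxelwise
  mean of co-registered binary lesion masks across a cohort, optionally
  Gaussian-smoothed (`smooth_prior()`), for use as a spatial prior by
  atlas-based segmentation tools.
- **Overlap validation** (`overlap()`, `summarize_overlaps()`,
  `rater_agreement()`): the statistic
  Overlap = 100 · |ROI₁ ∩ ROI₂| / |ROI₁ ∪ ROI₂| (Jaccard index as a
  percentage) with per-method summary tables.
- **Synthetic phantoms** (`generate_phantom()`): brain-shaped CSF/GM/WM
  compartments with spherical lesions of known position and intensity,
  Gaussian noise and bright single-voxel "flow artifact" confounds — so
  every segmenter can be validated against exact ground truth.

Supporting plumbing: NIfTI-1 I/O (`read_volume()`, `read_mask()`,
`write_mask()`), brain-mask construction from GM/WM probability maps
(`make_brain_mask()`), and strict grid-compatibility checks everywhere —
images on different grids are refused, never silently resampled.

## Worked example

```r
library(wmhseg)

# A 64^3 phantom: WM mean 100, two lesions at 1.8 x WM, noise SD 10
ctr <- 32.5
sp <- phantom_spec(shape = c(64, 64, 64),
                   lesions = list(lesion_spec(c(ctr, ctr, ctr), 5, 1.8),
                                  lesion_spec(c(ctr - 9, ctr - 6, ctr - 3), 3, 1.8)),
                   noise_sd = 10, seed = 42)
ph <- generate_phantom(sp)

compute_stats(ph$flair, ph$brain_mask)
#> <wmh_stats> mode 101.341, mean 82.4359, sd 36.362 (bin width 2.941, n = 100024)

seg <- segment_threshold(ph$flair, ph$brain_mask)
seg
#> <wmh_segmentation> method threshold: 687 voxels (0.687 mL), threshold 146.945, 2 clusters removed

overlap(seg$mask, ph$lesion_truth)
#> <wmh_overlap> 99.85% (|∩| = 687, |∪| = 688; |ROI1| = 687, |ROI2| = 688)

lesion_volume_ml(ph$lesion_truth)
#> [1] 0.688
```

Reading the output: the in-brain histogram peaks near the WM mean (101.3
under noise), so the threshold lands at 1.45 × mode ≈ 147; the segmenter
recovers 687 of the 688 true lesion voxels and the two noise-induced
spurious clusters are removed by the isolated-cluster filter, giving
99.85% volumetric overlap with the ground truth and a lesion load of
0.69 mL.

A command-line interface wrapping the same functions ships with the
package:

```sh
WMHSEG=$(Rscript -e 'cat(system.file("cli", "wmhseg.R", package = "wmhseg"))')
Rscript $WMHSEG phantom --spec spec.json --out-dir work/
Rscript $WMHSEG segment-threshold --flair work/flair.nii.gz \
    --brain-mask work/brain_mask.nii.gz --out work/seg.nii.gz
Rscript $WMHSEG overlap --a work/seg.nii.gz --b work/lesion_truth.nii.gz
```

Every file-writing subcommand leaves a `.json` sidecar with the resolved
parameters, thresholds and (for the fuzzy segmenter) per-iteration seed
counts.

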