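---
title: "Segmenting white matter hyperintensities: methods and design notes"
author: "wmhseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting white matter hyperintensities: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhseg)
```

## The problem

White matter hyperintensities (WMH) are bright regions in the cerebral
white matter on FLAIR MRI, common in older people and associated with
small-vessel disease and cognitive decline. Quantifying their volume across
a cohort requires segmenting them, and manual outlining is slow and
rater-dependent. This package implements two fully automated segmenters
that work directly from the FLAIR intensity histogram, a builder for an a
priori lesion probability map usable by atlas-based tools, the
intersection-over-union overlap statistic used to validate segmentations
against a manual reference, and a synthetic phantom generator so that every
computation can be exercised against known ground truth without any
patient data.

## The two segmenters

**Modal-intensity thresholding.** On a skull-stripped FLAIR image the modal
(most frequent) intensity tracks normal white matter, which dominates the
in-brain histogram. The segmenter computes the in-brain mode, thresholds at
`factor * mode` with `factor = 1.45` by default, and removes isolated
clusters below a minimum size (default 2 voxels, 26-connectivity). The
candidate rule is strict (`intensity > threshold`): the choice between
strict and non-strict inequality is arbitrary for continuous data, and it
is fixed and documented so results are reproducible.

Three details matter:

* The mode is computed over in-mask voxels only. The zeroed background of a
  skull-stripped image would otherwise dominate the histogram, drag the
  mode toward zero and make a multiplicative threshold meaningless.
* Histogram binning: integer-valued images use bin width 1; continuous
  images use the Freedman–Diaconis width clamped to at least
  `(max - min)/512`, so the mode is stable for both raw-integer and
  float-scaled data. When two bins tie, the lower-intensity bin wins —
  deterministic, and conservative in the direction of sensitivity since
  the threshold is a multiple of the mode.
* "Isolated pixel" removal is interpreted as removing connected components
  below a configurable minimum size, in 3D, not per slice. The smallest
  faithful reading (singletons only) is the default's intent; the size and
  connectivity are parameters because reasonable implementations differ.

**Seeded fuzzy connectedness.** The second segmenter detects lesion seeds
as in-brain voxels at or above `mean + k * SD` of the in-brain intensities
(`k = 3` by default, with a 2.5 variant), labels them, and grows each seed
set by fuzzy connectedness: a voxel's connectivity is the strength of its
strongest path from any seed, a path's strength being its weakest step.
The per-step affinity between adjacent voxels $c,d$ is the Gaussian
intensity-homogeneity kernel

$$\mu(c,d) = \exp\!\left(-\frac{\left(\tfrac{I(c)+I(d)}{2}-m\right)^2}{2\sigma^2}\right),$$

with $m$ the mean of the current seed intensities and $\sigma$ the
`sigma_scale` multiple of their SD. Voxels with connectivity at or above
`connectivity_threshold` (default 0.5) join the mask, are excluded from
further seed detection, statistics are recomputed over the remaining
voxels, and the loop repeats until no seeds remain; the final mask is the
union over iterations.

Design choices the method summary leaves open, and how they were fixed:

* *Affinity function.* Classical fuzzy connectedness requires a kernel; we
  adopt the canonical intensity-homogeneity Gaussian with parameters
  estimated from the current seeds, and expose `sigma_scale`, plus direct
  `mu`/`sigma` overrides on `fuzzy_connectivity()`, for tuning. The
  override also keeps the field well-defined in the degenerate case where
  all seeds share one intensity (SD 0): the width then falls back to a
  near-delta kernel and growth is confined to seed-intensity voxels.
* *Propagation.* Connectivity is computed by best-first (priority-queue)
  propagation, the max–min analogue of Dijkstra's algorithm. This is
  mathematically equal to exhaustive max–min path enumeration, and the
  test suite certifies the equality on small grids against two independent
  oracles: literal enumeration of all simple paths, and the
  maximum-spanning-tree bottleneck construction.
* *Seed update.* "Iteratively updating the seeds" is read as: segmented
  voxels are removed from the pool, seed statistics are recomputed over
  the remainder, and detection repeats. This matches the stopping rule
  ("no seeds remain") and guarantees termination: each iteration either
  adds voxels or stops, so the loop runs at most once per brain voxel,
  with `max_iterations` (default 20) as an additional cap that returns a
  partial result with a warning.
* *Statistics scope.* Whether the original mean/SD were global or
  slice-wise is not documented; we use global in-brain statistics,
  mirroring the thresholding segmenter's in-mask convention.
* *Adjacency* is 26-neighbourhood for seed labelling and path steps,
  consistent with the cluster filter, and configurable.

Skull stripping and tissue segmentation are deliberately not
reimplemented: `make_brain_mask()` consumes GM and WM probability maps
from any external unified segmentation, thresholds their sum at 0.5 (the
conventional posterior cut), fills interior cavities and keeps the largest
connected component; `apply_brain_mask()` zeroes non-brain voxels.
Likewise, building the a priori lesion map consumes binary masks already
resampled to a common grid — affine registration to a standard space is an
external, solved problem, and the package refuses mismatched grids
(tolerance 1e-4 on affine entries) rather than resampling silently.

## Validation currency

`overlap()` implements
$\mathrm{Overlap} = 100\,|R_1 \cap R_2| / |R_1 \cup R_2|$ — the Jaccard
index as a percentage, computed in voxel counts (grids are enforced
identical, so counts and volumes are equivalent). When both masks are
empty the ratio is 0/0; the package reports 100 with a `both_empty` flag
and a warning, on the reasoning that two raters agreeing there is nothing
to segment are in perfect agreement. Summaries (`summarize_overlaps()`,
`rater_agreement()`) report per-method mean, sample SD (n − 1), minimum
and maximum, rounding only at presentation.

## What the phantom emulates — and what it does not

`generate_phantom()` builds concentric ellipsoidal compartments (CSF shell
⊃ GM shell ⊃ WM core, semi-axes 0.45/0.40/0.34 of the field of view) on a
default 64³ grid at 1 mm isotropic spacing, with FLAIR-like intensities:
background 0, suppressed CSF 30, WM 100, GM 110, spherical lesions inside
the WM core at `intensity_factor × WM` (factors above ~1.45 are
detectable by construction; 1.8 is the default "well-defined lesion"),
additive Gaussian noise inside the brain (default SD 5, i.e. 5% of the WM
mean), and optional single-voxel "flow artifacts" placed uniformly in GM
at `flow_factor × WM` with `flow_factor` at least the largest lesion
factor, reproducing the failure mode where blood flow appears brighter
than the lesions and is picked up by intensity rules. The geometry makes
the WM core the largest compartment, so with zero noise the in-brain mode
equals the WM mean exactly — the anchor for exactness tests.

Deliberate simplifications, which bound what passing tests show about real
data: noise is Gaussian, not Rician; there is no bias field and no partial
volume; lesions are spheres with uniform intensity; background stays
noise-free (as after skull stripping); the T1 channel is represented only
by the label image. The phantoms exercise intensity ordering, histogram
statistics, connectivity and cluster logic — they do not certify
performance on scanner data, where bias fields and partial volume blur the
histogram structure these methods rely on.

All randomness flows through one seed stored in the spec; generation
restores the caller's RNG state, and identical specs give bit-identical
phantoms (and therefore byte-identical pipeline outputs).

## Behaviour the suite demonstrates on phantoms

* With zero noise, WM at 100 and lesions at 180, the threshold segmenter's
  threshold is exactly 145 and its mask equals the ground truth
  voxel-for-voxel, end to end through the CLI.
* With well-defined lesions (factor ≥ 1.8) and noise up to 10% of the WM
  mean, threshold-segmentation overlap against truth stays above 80%.
* The in-brain intensity SD on these phantoms is large (~35, driven by the
  CSF/GM/WM spread), so `mean + 3 SD` sits near 1.9 × WM: lesions at
  factor 1.8 produce no seeds at all, and a small lesion at factor 1.55 is
  missed by the fuzzy segmenter while the 1.45 × mode rule catches it —
  the documented tendency of the seeded method to miss low-contrast and
  small lesions. Bright lesions (factor 2.6, roughly four SDs above the
  in-brain mean) are recovered above 80% overlap.
* Lowering the seed bar from 3 to 2.5 SD never removes seeds and never
  shrinks the mask; with bright artifacts present it grows the mask and
  lowers overlap against truth — more non-lesion voxels are included, the
  behaviour reported when that change was tried on real scans.
* Segmented volume responds monotonically to both thresholds (factor sweep
  1.1→2.0 non-increasing; k 3.0→2.5 non-decreasing).

Problem sizes in the tests — 48³ phantom grids for most scenarios, 64³ for
the exactness check, 16³ random masks for metric and cluster oracles, and
≤ 3×3×3 grids for the exact fuzzy-connectivity oracles (with literal path
enumeration limited to 8-voxel regions, the complete-graph worst case) —
were chosen so the whole suite runs in minutes while keeping every
compartment large enough for the statistics to be meaningful.

## Numerical conventions and degenerate inputs

* Mask binarisation on read: raw value > 0.5 is `TRUE`, after checking the
  file holds at most two distinct rounded values — accepts {0,1} and
  {0,255} dialects, rejects label images.
* Empty masks: an error for statistics and segmentation inputs; a valid
  outcome for seed detection (it is the stopping rule) and for
  segmentation outputs.
* All-zero or constant brains: `segment_threshold()` refuses a mode of 0;
  `segment_fuzzy()` refuses an in-brain SD of 0.
* Prior maps are clamped to [0, 1]; averaging N binary masks yields values
  that are integer multiples of 1/N (asserted to 1e-9 in tests).
* Gaussian smoothing of priors (`smooth_prior()`, FWHM in mm, default off)
  uses separable convolution with the kernel renormalised over its
  in-bounds support at array boundaries, so a uniform map is a fixed point
  and interior mass is conserved exactly.

## Known limitations

The segmenters are intensity-only: they inherit the documented
misclassification of bright non-lesion structures (flow, bright GM) and
offer cluster-size filtering as the only guard. The fuzzy segmenter's
accuracy depends strongly on the relation between lesion contrast and the
global intensity spread; on data whose histogram is dominated by tissue
heterogeneity it will under-segment, as the phantom scenarios show. The
prior-map builder assumes upstream registration quality and simply
averages; it does not weight by registration confidence.
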