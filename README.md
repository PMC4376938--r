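# cordseg

Semi-automated spinal cord segmentation from 3D T2-weighted MR volumes,
with cord straightening, cervical template construction, and a synthetic
phantom generator for validation.

## The problem and the method

Measuring spinal cord atrophy — in motor neuron disease, multiple
sclerosis, or after cord injury — requires segmenting the cord from MR
images accurately enough that cross-sectional areas of ~80 mm² can be
compared across subjects and time points. Manual outlining is accurate
but takes hours per scan; fully interactive methods are operator
dependent.

`cordseg` implements a **double threshold-based method (DTbM)** that
exploits the contrast polarity of T2-weighted images: cerebrospinal
fluid (CSF) forms a bright ring around the darker cord. Per axial
slice:

1. **S1** — Otsu's threshold (first threshold) selects the brightest
   pixels, mainly CSF.
2. **S2** — the 8-connected component with the highest mean intensity
   and at least 50 pixels becomes the CSF mask `M_CSF`.
3. **S3** — flood filling closes the ring, giving `M_F`.
4. **S4** — if the ring is open (`M_F − M_CSF = ∅`), the slice contrast
   is enhanced by truncating the top 0.1% of the histogram and
   rescaling, and S1–S3 are retried (up to 10 times).
5. **S5** — both masks are eroded by a 3-pixel disk into conservative
   seed regions.
6. **S6** — the second threshold is the Losseff mid-intensity rule,
   `T = (mean(cord seed) + mean(CSF seed)) / 2`; pixels below `T`
   inside `M_F` form the cord mask `M_SC`, and `CSA = |M_SC| ×` pixel
   area.
7. **S7** — the per-slice results are assembled in 3D: the centerline
   (per-slice centre of mass) is screened for aberrant jumps (> 15
   voxels against a degree-5 polynomial fit and the slice-to-slice
   derivative), smoothed by robust locally weighted regression, and
   gaps are filled with cubic splines; each mask is parameterized as 72
   polar radii (one per 5°), radii are smoothed per angle across slices
   and missing slices interpolated, and every slice is re-rasterized
   from its contour.

Downstream, the volume is resampled in planes perpendicular to the
centerline (rotation-minimizing frames, tricubic interpolation) to give
a straight, FOV-centred cord; a cohort of straightened volumes is
length-standardized to the median and averaged into a template, with the
averaged binary masks forming a voxelwise cord-probability map.
Segmentations are scored by the Dice coefficient
`2|GT∩S| / (|GT|+|S|)` and the signed relative CSA error
`100·(S−GT)/GT`.

Because no clinical data ship with the package, a seedable phantom
generator renders a cord tube with CSF ring, sagittal curvature,
partial-volume boundaries, bias field, Rician noise and optional
lesions — with analytic ground truth — so the whole chain is testable.

## Worked example

```r
library(cordseg)

spec <- phantom_spec(fov_mm = c(36, 36, 63), amplitude_mm = 5,
                     noise_snr = 15, bias_range = c(0.8, 1.2))
ph  <- generate_phantom(spec, seed = 7)
pre <- correct_bias_field(ph$volume)
seg <- segment_cord(pre)           # S1-S7
seg
#> <cord_segmentation> 210 slices (68 repaired), volume 3122.1 mm^3
#>   per-slice CSA: mean 49.56 mm^2, range [49.05, 50.22]

evaluate_segmentation(ph$truth_mask, seg$mask, ph$volume$spacing)
#> <evaluation_report> 210 slices: mean DSC 98.66%, mean CSA error -1.49%

st <- straighten_volume(pre, seg)
st
#> <straightened_cord> 120 x 120 x 211, 0.3 mm iso, cord centred at (60.5, 60.5)
```

The phantom's true cross-section is `pi * 4^2 = 50.27` mm²; the
segmented per-slice mean of 49.7 mm² and per-slice Dice above 98%
against the analytic truth show the chain operating at sub-voxel
accuracy despite curvature, noise and bias. On clinical volumes, use
`load_volume()`, `crop_to_roi()` and `resample_isotropic()` in place of
the generator.

A command-line front end is installed with the package
(`exec/cordseg`): `cordseg preprocess`, `segment`, `straighten`, `c2`,
`template`, `evaluate`, `phantom`.

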