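---
title: "Double threshold-based cord segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double threshold-based cord segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordseg)
```

## The image model

On a T2-weighted scan the cerebrospinal fluid (CSF) surrounding the
spinal cord is the brightest structure in an axial slice, the cord is
darker, and the surrounding tissue darker still. Everything in this
package follows from that single contrast assumption. The method makes
no shape assumption beyond the cord being a simply connected region
inside a (mostly) closed CSF ring, which is what lets it track the
changing cross-sectional shape of a diseased cord where active-surface
approaches, which assume slowly varying shape and smooth radii,
degrade.

Volumes are handled as plain arrays with mm spacing and axis-role
labels; after loading, axes are permuted so the third array axis is
always superior-inferior (SI), and "slice" always means an axial
plane. Voxel indices are 1-based, following R convention.

## The two thresholds

Per axial slice, the first threshold is Otsu's: the histogram cut
maximizing between-class variance, with pixels strictly above it as
foreground. Two implementation details matter:

* the histogram keeps, per bin, both the pixel count and the sum of
  pixel values, so class means are exact rather than bin-centre
  approximations. For 8-bit data with the default 256 bins this makes
  the chosen cut coincide exactly with exhaustive search over all value
  cuts, which the test suite verifies;
* on ties, the smallest maximizing bin edge is returned.

The CSF mask is the 8-connected foreground component with the highest
*mean* intensity (robust to isolated bright speckle, unlike a
max-intensity rule) among components of at least `min_size = 50`
pixels. Foreground connectivity is 8 and background connectivity 4 —
the standard dual pair — so a diagonal one-pixel gap does not count as
an opening of the ring.

The second threshold is the Losseff mid-intensity rule: the midpoint of
the mean intensities over two seed regions, obtained by eroding the
raw cord and CSF masks with a discrete disk of radius 3 pixels. The
erosion deliberately shrinks the seeds to well inside their true
regions; the classification is then insensitive to the exact seed
shape. A property test confirms the CSA varies by under 2% when the
seeds are replaced by random 10–30% subsets of the true regions, which
is the robustness that makes the method's automatic initialization
viable at all.

One bookkeeping choice: boundary pixels that the second threshold
assigns to the cord are removed from the CSF mask, not the other way
around. Subtracting the CSF mask from the cord mask instead would clip
the boundary pixels that lie above the Otsu cut but below the
mid-intensity threshold — they belong to the cord — and systematically
shrink the CSA by roughly 3% at 0.3 mm resolution.

## The contrast-enhancement loop

When the CSF ring does not close (flood fill finds no interior), or no
foreground component reaches `min_size`, the slice's histogram is
truncated at its top 0.1% quantile and linearly rescaled to the
original range, and the steps are retried (cap: 10 iterations). Two
properties of this map are worth stating plainly, because they bound
what the loop can and cannot do:

* Otsu's partition is invariant under affine intensity maps, so the
  rescale by itself changes nothing; all progress comes from the
  *clipping*, which merges the top tail into the bright class.
* When the top 0.1% quantile equals the maximum (a point mass at the
  top), the map is the identity and the loop stalls; the slice is then
  reported as failed and left to the 3D repair.

The loop is therefore effective exactly when the first Otsu cut is
captured by a sparse bright tail (flow artifacts, fat, hot pixels):
one or two truncations collapse the tail and the cut falls to the
tissue/CSF boundary. It cannot rescue a slice whose cord and CSF
intensity ranges genuinely overlap; those slices fail and are
reconstructed by the 3D step. Failures are data, not exceptions —
`segment_slice()` never raises.

## 3D correction

The correction step treats the stack of per-slice masks as noisy
observations of a smooth tube:

1. centres of mass form the raw centerline;
2. slices whose centre deviates from a degree-5 polynomial fit by more
   than 15 voxels (Euclidean residual), or whose *both* adjacent
   slice-to-slice differences exceed 15 voxels, are discarded as
   aberrant. Requiring both differences keeps the innocent neighbour
   of a displaced slice unflagged; the detection runs on the raw
   centerline *before* any smoothing, because a robust smoother would
   suppress precisely the outliers that need flagging;
3. the remaining centres are smoothed with robust locally weighted
   regression (LOWESS, span 0.3, 2 bisquare iterations — `stats::lowess`)
   and gaps filled coordinate-wise with cubic splines, nearest-value at
   the range ends (no spline extrapolation);
4. each retained mask becomes 72 polar radii (5° resolution, sub-pixel
   boundary by linear interpolation along each ray, outermost crossing
   so interior holes are ignored); radii are smoothed per angle across
   slices — this is what suppresses nerve-root spurs, which appear as
   radial spikes at isolated angles — and missing slices'
   radii spline-interpolated;
5. every slice is re-rasterized from its contour (points-in-polygon on
   the 72-gon, even-odd rule). Slices rebuilt from scratch are marked
   `repaired`.

The polynomial degree (5) is far below the slice count, so the fit
cannot chase the outliers it is meant to expose. The LOWESS span and
robustness iterations are the package's choices; span 0.3 follows the
usual rule of smoothing over a window long enough to span several
vertebral levels but short enough to track cervical lordosis.

## Straightening and the C2 stack

Planes perpendicular to the smoothed centerline are resampled with
tricubic interpolation (nearest-neighbour for masks) at uniform arc
length, the cord centre mapping to the centre of each output slice.
Frames are parallel-transported (rotation-minimizing) rather than
Frenet: Frenet frames are undefined at zero curvature and flip at
inflections, both of which occur in near-straight cords. Because the
cord continues beyond the imaged region, sampling beyond the SI ends
replicates the end slices rather than cutting the first and last
oblique planes; in-plane out-of-field samples are zero and counted.

The standard cross-sectional measurement cuts five 3 mm slabs superior
to the C2/C3 disk, the most inferior slab centred on the
operator-supplied landmark slice (vertebral labelling stays manual by
design); each slab slice is the voxelwise mean of its ten 0.3 mm thin
slices.

## Template construction

Straightened pairs are standardized in length to the cohort median
slice count (SI-axis rescaling only: cubic for intensities, nearest
neighbour for masks, in-plane geometry untouched), averaged voxelwise,
and the mean image smoothed with a separable Gaussian of FWHM
0.3 × 0.3 × 0.6 mm (σ = FWHM / (2√(2 ln 2))). The probability map is
the unsmoothed voxelwise mean of the binary masks — the fraction of
subjects whose cord covers each voxel — so its voxel sum times the
voxel volume equals the cohort's mean cord volume exactly, a property
the tests assert. Whole-length standardization (rather than
per-vertebral-level) is used; it preserves nerve-root positions better
and removes cord-length effects.

## The bias-field stand-in

True B1 correction is an external preprocessing concern; the package
ships a deliberately simple stand-in plus a hook for substituting an
externally corrected volume. The stand-in fits a 3D polynomial
(default order 3) to the log-intensity of bright voxels and divides the
fitted gain out, preserving the mean. Three details were found
necessary for the estimator to behave:

* fit a *single* tissue class: a second Otsu within the bright set
  isolates the CSF. Mixing cord and CSF voxels cancels the gain
  signal, because in low-gain regions only CSF clears the first
  threshold — the class mixture varies exactly opposite to the gain;
* erode the bright mask in-plane by one pixel first, dropping
  partial-volume boundary voxels whose systematic intensity structure
  the polynomial would absorb as gain;
* clamp the fitted log-gain to its range over the fitted voxels: the
  polynomial is unconstrained in corners that contain no bright voxels
  and explodes there.

Intensity normalization for template building is a 2nd–98th percentile
rescale to [0, 1]; the percentile choice is the package's own default
for a method-unspecified step.

## The phantom: what it emulates, and what it does not

The generator renders a cord tube (default radius 4 mm, intensity 100)
inside a CSF ring (2 mm, intensity 200) on tissue background (50) at
0.3 mm isotropic spacing, with 4× supersampled partial-volume
boundaries, optional sagittal sinusoidal curvature (amplitude in mm,
period 150 mm, the scale of cervical lordosis), Gaussian edge blur
(0.3 mm), a smooth multiplicative bias field, and Rician noise
(default SNR 15 relative to the cord, the magnitude-MRI noise model).
The bias field is a sum of three random separable cosine products with
0.2–0.6 cycles across the FOV, rescaled to the requested gain range —
coil-scale inhomogeneity, smooth enough that a low-order polynomial is
a sensible corrector, which is also what physical B1 variation at 3T
looks like. Lesion stand-ins (focal atrophy, intramedullary
hyperintensity, canal narrowing) are raised-cosine-windowed parameter
modulations, not biophysical simulations.

All randomness flows from one integer seed; identical seeds give
bit-identical volumes, and truth structures (mask, centerline, analytic
CSA = πr²) are computed before any degradation.

What passing tests on the phantom demonstrate: correct geometry and
arithmetic of every step, sub-voxel CSA recovery under partial volume,
robustness of the chain to curvature, noise, smooth bias and injected
per-slice failures. What they do not demonstrate: performance on real
cords with nerve roots touching the mask, pulsatile flow artifacts,
susceptibility distortions, or pathology that destroys the CSF/cord
contrast — the documented failure modes (large T2-hyperintense lesions,
severely narrowed canals) are *not* claimed to be handled, and the
phantom's lesion models are too tame to probe them.

## Numerical choices and problem sizes

* Tricubic resampling uses the Catmull-Rom kernel (exact on constants
  and linear ramps); stencils clamp at borders; negative overshoot is
  clipped at 0, nothing is clipped above.
* Resampled grid sizes round the physical extent to the nearest voxel,
  preserving extent to within one target voxel per axis.
* `min_size = 50` pixels and the 3-pixel erosion disk are defined at
  the 0.3 mm working resolution, where they were calibrated.
* Ray casting samples masks bilinearly every 0.25 px; fractional
  coverage maps are accepted and sharpen the boundary estimate.
* The validation suite runs phantoms of 100–120² in-plane voxels and
  40–210 slices: large enough that a 210-slice curved cord exercises
  every repair path, small enough that the whole suite runs in about a
  minute on one core. `scripts/acceptance.R` re-computes the headline
  figures from scratch at the same sizes.

## Known limitations

* Grey/white matter separation inside the cord is out of reach at this
  contrast, by design.
* The per-slice method needs a visible, mostly closed CSF ring; where
  CSF space vanishes (severe canal narrowing) slices fail and the
  repair interpolates through them, which is only as good as the
  neighbouring slices.
* The contrast-enhancement loop cannot separate genuinely overlapping
  cord/CSF intensity distributions (see the affine-invariance argument
  above).
* The discontinuity detector's derivative rule can flag an intact
  slice sandwiched between two displaced neighbours; this costs a
  benign re-synthesis of a slice that was fine.
* N3/N4-class bias correction is not re-implemented; the polynomial
  stand-in handles coil-scale gain only.
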