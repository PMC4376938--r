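# 3D correction of the per-slice segmentations: centerline extraction
# and smoothing, detection and removal of aberrant slices, and
# re-synthesis of missing contours by per-angle robust regression of the
# polar radii followed by spline interpolation across slices.

#' Extract the centerline from per-slice cord masks
#'
#' The centerline is the curve joining the centres of mass of the cord
#' mask in each axial slice; slices without a usable mask get `NA`.
#'
#' @param slices List of `slice_segmentation` objects, or a list of 2D
#'   logical masks (NULL for missing slices).
#' @return A numeric matrix of class `centerline`, one row per slice,
#'   columns `row` and `col` (voxel coordinates), `NA` where absent.
#' @export
extract_centerline <- function(slices) {
  centers <- t(vapply(slices, function(s) {
    m <- if (inherits(s, "slice_segmentation")) {
      if (identical(s$status, "ok")) s$m_sc else NULL
    } else s
    if (is.null(m) || !any(m)) c(NA_real_, NA_real_) else .center_of_mass(m)
  }, numeric(2)))
  colnames(centers) <- c("row", "col")
  if (!any(stats::complete.cases(centers)))
    stop("no slice provides a cord mask", call. = FALSE)
  class(centers) <- c("centerline", class(centers))
  centers
}

#' Robust locally weighted regression of a series
#'
#' Cleveland's LOWESS with tricube weights and iterated bisquare
#' robustness reweighting, evaluated at every present index. Entries
#' that are `NA` stay `NA` (they are filled later by spline
#' interpolation).
#'
#' @param y Numeric series indexed by slice.
#' @param span Smoothing span as a fraction of the points (default 0.3).
#' @param iter Robustness iterations (default 2).
#' @return The smoothed series, same length as `y`.
#' @export
robust_lowess <- function(y, span = 0.3, iter = 2) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  present <- which(is.finite(y))
  if (length(present) < 5)
    stop("robust smoothing needs at least 5 points", call. = FALSE)
  sm <- stats::lowess(present, y[present], f = span, iter = iter)
  out <- y
  out[present] <- sm$y
  out
}

#' Detect aberrant centerline discontinuities
#'
#' A slice is aberrant when its centre deviates from a low-order
#' polynomial fit of the centerline by more than `threshold_vox`
#' (Euclidean residual), or when both of its slice-to-slice first
#' differences exceed `threshold_vox` (an isolated jump; requiring both
#' sides keeps the neighbours of a displaced slice unflagged).
#'
#' @param centerline A [extract_centerline()] matrix.
#' @param threshold_vox Deviation threshold in voxels (default 15 at the
#'   0.3 mm working resolution).
#' @param degree Polynomial degree for the fit (default 5; reduced
#'   automatically when few slices are present).
#' @return Integer vector of aberrant slice indices (possibly empty).
#' @export
detect_discontinuities <- function(centerline, threshold_vox = 15,
                                   degree = 5) {
  if (threshold_vox <= 0) stop("threshold must be positive", call. = FALSE)
  present <- which(stats::complete.cases(centerline))
  if (length(present) < 3) return(integer(0))
  deg <- min(degree, length(present) - 2)
  x <- present
  rr <- centerline[present, 1]
  cc <- centerline[present, 2]
  fit_r <- stats::lm(rr ~ stats::poly(x, deg, raw = TRUE))
  fit_c <- stats::lm(cc ~ stats::poly(x, deg, raw = TRUE))
  resid <- sqrt(stats::residuals(fit_r)^2 + stats::residuals(fit_c)^2)
  flag <- resid > threshold_vox
  # isolated jumps: both adjacent first differences large
  if (length(present) >= 3) {
    d <- sqrt(diff(rr)^2 + diff(cc)^2)
    interior <- 2:(length(present) - 1)
    jump <- d[interior - 1] > threshold_vox & d[interior] > threshold_vox
    flag[interior] <- flag[interior] | jump
  }
  present[flag]
}

#' Fill missing centerline points by cubic splines
#'
#' Interior gaps are interpolated coordinate-wise with a cubic spline
#' over the present slices; gaps at the ends of the range are filled
#' with the nearest present value (splines are not extrapolated).
#'
#' @param centerline A [extract_centerline()] matrix with `NA` gaps.
#' @return A complete `centerline` matrix.
#' @export
interpolate_centerline <- function(centerline) {
  present <- which(stats::complete.cases(centerline))
  if (length(present) < 4)
    stop("centerline interpolation needs at least 4 points", call. = FALSE)
  out <- centerline
  out[, 1] <- .spline_fill(ifelse(seq_len(nrow(out)) %in% present,
                                  centerline[, 1], NA_real_))
  out[, 2] <- .spline_fill(ifelse(seq_len(nrow(out)) %in% present,
                                  centerline[, 2], NA_real_))
  class(out) <- c("centerline", "matrix", "array")
  out
}

#' Polar parameterization of an axial mask
#'
#' Measures the radius from the centre to the outermost mask boundary
#' crossing along 72 rays (one per 5 degrees; angle 0 points toward
#' +col, angles increase toward +row). The boundary position is located
#' at sub-pixel precision by linear interpolation of the bilinearly
#' sampled mask along each ray. Using the outermost crossing makes the
#' contour robust to interior holes.
#'
#' @param mask 2D logical mask, non-empty. A numeric coverage map in
#'   \[0, 1\] (e.g. from supersampled rasterization) is also accepted;
#'   values of at least 0.5 count as inside, and the fractional values
#'   sharpen the sub-pixel boundary estimate.
#' @param center Centre `(row, col)`; defaults to the centre of mass.
#'   Must lie inside the mask.
#' @param n_angles Number of rays (default 72).
#' @return An object of class `radial_contour`: list with `center`,
#'   `radii` (pixel units) and `angles` (radians).
#' @export
mask_to_polar <- function(mask, center = NULL, n_angles = 72) {
  inside <- mask >= 0.5
  if (!any(inside)) stop("empty mask", call. = FALSE)
  if (is.null(center)) center <- .center_of_mass(inside)
  pr <- min(max(round(center[1]), 1), nrow(mask))
  pc <- min(max(round(center[2]), 1), ncol(mask))
  if (!inside[pr, pc]) stop("center outside mask", call. = FALSE)
  ang <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  idx <- which(inside)
  r <- (idx - 1) %% nrow(mask) + 1
  c <- (idx - 1) %/% nrow(mask) + 1
  rmax <- sqrt(max((r - center[1])^2 + (c - center[2])^2)) + 2
  step <- 0.25
  t <- seq(0, rmax, by = step)
  mnum <- mask * 1
  radii <- numeric(n_angles)
  # sample all rays in one gather
  rr <- outer(sin(ang), t) + center[1]
  cc <- outer(cos(ang), t) + center[2]
  v <- matrix(.sample_bilinear(mnum, as.vector(rr), as.vector(cc)),
              nrow = n_angles)
  for (a in seq_len(n_angles)) {
    inside <- which(v[a, ] >= 0.5)
    if (!length(inside)) { radii[a] <- 0; next }
    k <- max(inside)
    if (k == length(t)) {
      radii[a] <- t[k]
    } else {
      v0 <- v[a, k]; v1 <- v[a, k + 1]
      radii[a] <- t[k] + step * (v0 - 0.5) / (v0 - v1)
    }
  }
  structure(list(center = as.numeric(center[1:2]), radii = radii,
                 angles = ang),
            class = "radial_contour")
}

#' Smooth and complete polar radii across slices
#'
#' For each of the 72 angles independently, the radius profile along the
#' slice axis is smoothed with robust locally weighted regression (which
#' suppresses the radial spikes caused by nerve roots) and missing
#' slices are filled by cubic-spline interpolation (nearest value at the
#' range ends).
#'
#' @param contours List with one [mask_to_polar()] contour per slice,
#'   `NULL` for missing slices.
#' @param span LOWESS span (default 0.3).
#' @return Matrix of smoothed radii, slices in rows and angles in
#'   columns, complete over the slice range; negative smoothed values
#'   are clipped at 0.
#' @export
smooth_radii <- function(contours, span = 0.3) {
  ok <- !vapply(contours, is.null, TRUE)
  if (sum(ok) < 5)
    stop("radius smoothing needs at least 5 contoured slices", call. = FALSE)
  n_angles <- length(contours[[which(ok)[1]]]$radii)
  R <- matrix(NA_real_, length(contours), n_angles)
  for (z in which(ok)) R[z, ] <- contours[[z]]$radii
  for (a in seq_len(n_angles)) {
    sm <- robust_lowess(R[, a], span = span)
    R[, a] <- .spline_fill(sm)
  }
  R[R < 0] <- 0
  R
}

#' Rasterize a polar contour back to a binary mask
#'
#' The 72 polar vertices form a closed polygon; pixels whose centres lie
#' inside it (even-odd rule) form the mask.
#'
#' @param contour A `radial_contour`, or a list with `center` and
#'   `radii`.
#' @param shape Output matrix dimensions `c(nrow, ncol)`.
#' @return 2D logical mask.
#' @export
polar_to_mask <- function(contour, shape) {
  radii <- contour$radii
  if (all(radii <= 0)) stop("degenerate contour: all radii zero", call. = FALSE)
  ang <- if (!is.null(contour$angles)) contour$angles
         else (seq_along(radii) - 1) * 2 * pi / length(radii)
  vr <- contour$center[1] + radii * sin(ang)
  vc <- contour$center[2] + radii * cos(ang)
  out <- matrix(FALSE, shape[1], shape[2])
  r0 <- max(1L, floor(min(vr))); r1 <- min(shape[1], ceiling(max(vr)))
  c0 <- max(1L, floor(min(vc))); c1 <- min(shape[2], ceiling(max(vc)))
  if (r0 > r1 || c0 > c1) return(out)
  pr <- rep(r0:r1, times = c1 - c0 + 1)
  pc <- rep(c0:c1, each = r1 - r0 + 1)
  crossings <- integer(length(pr))
  nv <- length(vr)
  j <- nv
  for (i in seq_len(nv)) {
    y1 <- vr[i]; y2 <- vr[j]; x1 <- vc[i]; x2 <- vc[j]
    hit <- (y1 > pr) != (y2 > pr)
    if (any(hit)) {
      xint <- x1 + (pr[hit] - y1) * (x2 - x1) / (y2 - y1)
      crossings[hit] <- crossings[hit] + (pc[hit] < xint)
    }
    j <- i
  }
  inside <- crossings %% 2 == 1
  out[cbind(pr[inside], pc[inside])] <- TRUE
  out
}

#' 3D correction of per-slice segmentations
#'
#' Assembles the per-slice results into a coherent 3D cord segmentation:
#' aberrant slices (centre jumps beyond `threshold_vox`) are detected on
#' the raw centerline and discarded together with failed slices; the
#' remaining centres are smoothed by robust locally weighted regression
#' and gaps filled by cubic splines; every retained slice's mask is
#' converted to a 72-ray polar contour, the radii are smoothed per angle
#' across slices and missing slices' radii spline-interpolated; finally
#' every slice in the range is re-rasterized from its (smoothed) polar
#' contour. Slices whose mask was re-synthesized from scratch are marked
#' `repaired`.
#'
#' @param slices List of `slice_segmentation` objects (as returned by
#'   [segment_cord()] with `correct = FALSE`).
#' @param spacing Voxel spacing, length-3, mm.
#' @param shape Grid dimensions `c(nrow, ncol, nslices)`; taken from the
#'   attribute set by [segment_cord()] when omitted.
#' @param threshold_vox Discontinuity threshold in voxels.
#' @param span LOWESS span for centerline and radius smoothing.
#' @param poly_degree Polynomial degree for discontinuity detection.
#' @param n_angles Number of polar rays.
#' @return An object of class `cord_segmentation`: list with `mask` (3D
#'   logical array), `centerline` (complete, smoothed), `csa_mm2`
#'   (per-slice), `provenance` (`"segmented"` or `"repaired"` per
#'   slice), `volume_mm3` and `spacing`.
#' @export
correct_segmentation <- function(slices, spacing = attr(slices, "spacing"),
                                 shape = attr(slices, "shape"),
                                 threshold_vox = 15, span = 0.3,
                                 poly_degree = 5, n_angles = 72) {
  if (is.null(spacing) || is.null(shape))
    stop("spacing and shape must be supplied", call. = FALSE)
  nz <- length(slices)
  status_ok <- vapply(slices, function(s)
    inherits(s, "slice_segmentation") && identical(s$status, "ok"), TRUE)
  raw <- extract_centerline(slices)
  aberrant <- detect_discontinuities(raw, threshold_vox, poly_degree)
  keep <- which(status_ok & !(seq_len(nz) %in% aberrant))
  if (length(keep) < 5)
    stop("unrecoverable: fewer than 5 usable slices", call. = FALSE)

  # smoothed, complete centerline
  cl <- raw
  cl[-keep, ] <- NA_real_
  cl[, 1] <- robust_lowess(cl[, 1], span = span)
  cl[, 2] <- robust_lowess(cl[, 2], span = span)
  cl <- interpolate_centerline(cl)
  attr(cl, "smoothed") <- TRUE

  contours <- vector("list", nz)
  usable <- logical(nz)
  for (z in keep) {
    contours[[z]] <- tryCatch(mask_to_polar(slices[[z]]$m_sc,
                                            n_angles = n_angles),
                              error = function(e) NULL)
    usable[z] <- !is.null(contours[[z]])
  }
  if (sum(usable) < 5)
    stop("unrecoverable: fewer than 5 contoured slices", call. = FALSE)
  R <- smooth_radii(contours, span = span)

  mask <- array(FALSE, shape)
  csa <- numeric(nz)
  for (z in seq_len(nz)) {
    m <- polar_to_mask(list(center = cl[z, ], radii = R[z, ]), shape[1:2])
    mask[, , z] <- m
    csa[z] <- compute_csa(m, spacing[1:2])
  }
  provenance <- ifelse(usable, "segmented", "repaired")
  structure(list(mask = mask,
                 centerline = cl,
                 csa_mm2 = csa,
                 provenance = provenance,
                 volume_mm3 = sum(mask) * prod(spacing),
                 spacing = spacing),
            class = "cord_segmentation")
}

#' @export
print.cord_segmentation <- function(x, ...) {
  cat(sprintf("<cord_segmentation> %d slices (%d repaired), volume %.1f mm^3\n",
              length(x$csa_mm2), sum(x$provenance == "repaired"),
              x$volume_mm3))
  cat(sprintf("  per-slice CSA: mean %.2f mm^2, range [%.2f, %.2f]\n",
              mean(x$csa_mm2), min(x$csa_mm2), max(x$csa_mm2)))
  invisible(x)
}

#' Build a cord segmentation object from a 3D mask
#'
#' Convenience constructor for masks obtained outside the per-slice
#' pipeline (e.g. a straightened mask or a manual segmentation): the
#' centerline is the per-slice centre of mass, smoothed when at least 5
#' slices are present.
#'
#' @param mask 3D logical array (slices along axis 3; empty slices
#'   allowed at the ends).
#' @param spacing Voxel spacing, length-3, mm.
#' @param smooth Smooth the centerline with [robust_lowess()].
#' @return A `cord_segmentation`.
#' @export
segmentation_from_mask <- function(mask, spacing, smooth = TRUE) {
  nz <- dim(mask)[3]
  masks <- lapply(seq_len(nz), function(z) {
    m <- mask[, , z]
    if (any(m)) m else NULL
  })
  cl <- extract_centerline(masks)
  if (smooth && sum(stats::complete.cases(cl)) >= 5) {
    cl[, 1] <- robust_lowess(cl[, 1])
    cl[, 2] <- robust_lowess(cl[, 2])
  }
  if (anyNA(cl)) cl <- interpolate_centerline(cl)
  csa <- vapply(seq_len(nz), function(z)
    compute_csa(mask[, , z], spacing[1:2]), 0)
  structure(list(mask = mask, centerline = cl, csa_mm2 = csa,
                 provenance = rep("segmented", nz),
                 volume_mm3 = sum(mask) * prod(spacing),
                 spacing = spacing),
            class = "cord_segmentation")
}
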