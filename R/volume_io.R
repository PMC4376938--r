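# Volume containers and NIfTI input/output. A cord_volume is a plain 3D
# array of scanner-unit intensities plus voxel spacing in mm and axis
# role labels; after loading, axes are permuted to the canonical order
# (RL, AP, SI) so that the third array axis is always superior-inferior
# and "slice" always means an axial plane.

#' Construct an intensity volume
#'
#' @param data 3D numeric array of intensities (finite values).
#' @param spacing Numeric length-3, voxel spacing in mm per axis (> 0).
#' @param axes Character length-3, a permutation of `c("RL","AP","SI")`
#'   naming the anatomical role of each array axis.
#' @return An object of class `cord_volume`: a list with elements
#'   `data`, `spacing`, `axes`.
#' @export
cord_volume <- function(data, spacing, axes = c("RL", "AP", "SI")) {
  if (length(dim(data)) != 3)
    stop("expected 3D scalar volume", call. = FALSE)
  if (any(!is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive values (mm)", call. = FALSE)
  if (!setequal(axes, c("RL", "AP", "SI")))
    stop("axes must be a permutation of RL, AP, SI", call. = FALSE)
  data <- as.array(data)
  attributes(data) <- list(dim = dim(data))
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, axes = axes),
            class = "cord_volume")
}

#' @export
print.cord_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cord_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm (%s)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              paste(x$axes, collapse = ",")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.cord_volume <- function(x) dim(x$data)

# Map an orientation string like "RAS"/"LPI" to axis roles.
.axes_from_orientation <- function(orient) {
  ch <- strsplit(toupper(orient), "")[[1]]
  roles <- vapply(ch, function(l) switch(l,
    R = "RL", L = "RL", A = "AP", P = "AP", S = "SI", I = "SI",
    NA_character_), "")
  if (length(roles) != 3 || any(is.na(roles)) ||
      !setequal(roles, c("RL", "AP", "SI")))
    return(c("RL", "AP", "SI"))
  unname(roles)
}

#' Read a NIfTI-1 volume
#'
#' Loads a 3D scalar NIfTI file, takes the voxel spacing from the
#' header, infers the anatomical role of each axis from the orientation
#' metadata (assuming canonical RL/AP/SI order when no orientation is
#' stored) and permutes the array so the axes are ordered (RL, AP, SI).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [cord_volume].
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3)
    stop("expected 3D scalar volume", call. = FALSE)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid voxel spacing in header", call. = FALSE)
  axes <- tryCatch(.axes_from_orientation(RNifti::orientation(img)),
                   error = function(e) c("RL", "AP", "SI"))
  vol <- cord_volume(as.array(img), spacing, axes)
  canonicalize_axes(vol)
}

#' Permute a volume to canonical (RL, AP, SI) axis order
#' @param vol A [cord_volume].
#' @return The same volume with axes reordered to (RL, AP, SI).
#' @export
canonicalize_axes <- function(vol) {
  perm <- match(c("RL", "AP", "SI"), vol$axes)
  if (all(perm == 1:3)) return(vol)
  cord_volume(aperm(vol$data, perm), vol$spacing[perm], vol$axes[perm])
}

#' Write a volume or mask to NIfTI-1
#'
#' Intensities are stored as 32-bit float, masks as unsigned 8-bit.
#'
#' @param vol A [cord_volume], or a 3D 0/1 array when `mask = TRUE`.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param mask Logical; write as an unsigned 8-bit binary mask.
#' @param spacing Spacing override (mm), required when `vol` is a bare
#'   array.
#' @return Invisibly, `path`.
#' @export
save_volume <- function(vol, path, mask = FALSE, spacing = NULL) {
  if (inherits(vol, "cord_volume")) {
    data <- vol$data
    spacing <- vol$spacing
  } else {
    data <- as.array(vol)
    if (is.null(spacing)) stop("spacing required for bare arrays", call. = FALSE)
  }
  if (mask) {
    storage.mode(data) <- "integer"
    img <- RNifti::asNifti(structure(data, pixdim = spacing),
                           datatype = "uint8")
  } else {
    storage.mode(data) <- "double"
    img <- RNifti::asNifti(structure(data, pixdim = spacing),
                           datatype = "float")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary cord mask from NIfTI-1
#' @param path Path to the mask file.
#' @return List with `data` (3D logical array) and `spacing` (mm).
#' @export
load_mask <- function(path) {
  vol <- load_volume(path)
  if (!all(vol$data %in% c(0, 1)))
    stop("mask file contains values other than 0/1", call. = FALSE)
  list(data = vol$data != 0, spacing = vol$spacing)
}

#' Crop a volume to an operator-selected slice range
#'
#' Replaces the interactive selection of the upper and lower limits of
#' the cord region by two axial slice indices along the SI axis
#' (1-based, inclusive). Intensities are copied, not resampled.
#'
#' @param vol A [cord_volume].
#' @param slice_lo,slice_hi Inclusive slice range, `1 <= slice_lo <
#'   slice_hi <=` number of SI slices.
#' @return The cropped [cord_volume].
#' @export
crop_to_roi <- function(vol, slice_lo, slice_hi) {
  nz <- dim(vol$data)[3]
  if (!(slice_lo >= 1 && slice_lo < slice_hi && slice_hi <= nz))
    stop(sprintf("invalid ROI [%s, %s] for %d slices", slice_lo, slice_hi, nz),
         call. = FALSE)
  cord_volume(vol$data[, , slice_lo:slice_hi, drop = FALSE],
              vol$spacing, vol$axes)
}

#' Resample a volume to isotropic voxels
#'
#' Tricubic (separable Catmull-Rom) resampling to the segmentation
#' working resolution, 0.3 mm by default. The physical extent is
#' preserved to within one target voxel per axis, and cubic overshoot is
#' clipped at zero (scanner units are unbounded above, so no upper
#' clip).
#'
#' @param vol A [cord_volume].
#' @param target_mm Target isotropic spacing in mm (> 0).
#' @return The resampled [cord_volume].
#' @export
resample_isotropic <- function(vol, target_mm = 0.3) {
  if (!is.numeric(target_mm) || target_mm <= 0)
    stop("target spacing must be positive", call. = FALSE)
  a <- vol$data
  for (axis in 1:3) {
    n_in <- dim(a)[axis]
    sp <- vol$spacing[axis]
    n_out <- max(2L, round(n_in * sp / target_mm))
    x_out <- ((seq_len(n_out) - 0.5) * target_mm) / sp + 0.5
    a <- .apply_axis(a, axis, .interp_matrix(n_in, x_out, "cubic"))
  }
  a[a < 0] <- 0
  cord_volume(a, rep(target_mm, 3), vol$axes)
}

#' Percentile intensity normalization
#'
#' Maps the `lower` to `upper` intensity percentiles to \[0, 1\],
#' clipping outside. Monotone and order-preserving; used to put cohort
#' volumes on a common intensity scale before template averaging.
#'
#' @param vol A [cord_volume].
#' @param lower,upper Percentile bounds as fractions (defaults 0.02 and
#'   0.98).
#' @return The normalized [cord_volume] with intensities in \[0, 1\].
#' @export
normalize_intensity <- function(vol, lower = 0.02, upper = 0.98) {
  q <- stats::quantile(vol$data, c(lower, upper), names = FALSE)
  if (q[2] <= q[1])
    stop("no dynamic range: volume is (nearly) constant", call. = FALSE)
  a <- (vol$data - q[1]) / (q[2] - q[1])
  a[a < 0] <- 0
  a[a > 1] <- 1
  cord_volume(a, vol$spacing, vol$axes)
}

#' Polynomial bias-field correction
#'
#' Fits a low-order 3D polynomial to the log-intensity of bright voxels
#' (above the volume-wide Otsu threshold), divides the fitted
#' multiplicative gain out and rescales so the mean intensity is
#' preserved. This is a deliberately simple smooth-gain model for B1
#' inhomogeneity; `hook` lets a caller substitute a volume corrected by
#' an external tool, and `method = "none"` bypasses correction entirely.
#'
#' @param vol A [cord_volume].
#' @param order Polynomial order (>= 1, default 3).
#' @param method `"poly"` (default) or `"none"` (pass-through).
#' @param hook Optional function taking and returning a [cord_volume];
#'   when supplied it replaces the built-in correction.
#' @param max_fit_voxels Upper bound on the number of bright voxels used
#'   for the least-squares fit (subsampled deterministically).
#' @return The corrected [cord_volume].
#' @export
correct_bias_field <- function(vol, order = 3, method = c("poly", "none"),
                               hook = NULL, max_fit_voxels = 20000) {
  method <- match.arg(method)
  if (!is.null(hook)) return(hook(vol))
  if (method == "none") return(vol)
  if (order < 1) stop("polynomial order must be >= 1", call. = FALSE)
  a <- vol$data
  if (all(a <= 0)) stop("no bright voxels to fit the bias field",
                        call. = FALSE)
  thr <- .otsu_core(a)$threshold
  bright <- which(a > thr & a > 0)
  if (!length(bright)) stop("no bright voxels to fit the bias field",
                            call. = FALSE)
  # a second Otsu within the bright set isolates the brightest tissue
  # class (CSF on T2); fitting a single class keeps the gain signal from
  # being cancelled by spatially varying class mixtures
  thr2 <- tryCatch(.otsu_core(a[bright])$threshold, error = function(e) thr)
  bmask <- a > thr2
  # drop partial-volume boundary pixels by in-plane erosion: they carry
  # systematic intensity structure the polynomial would absorb as gain
  for (z in seq_len(dim(a)[3]))
    bmask[, , z] <- erode_mask(bmask[, , z], 1)
  bright2 <- which(bmask)
  if (length(bright2) >= 500) bright <- bright2
  d <- dim(a)
  # normalised coordinates in [-1, 1]
  coords <- arrayInd(bright, d)
  cx <- 2 * (coords[, 1] - 1) / max(d[1] - 1, 1) - 1
  cy <- 2 * (coords[, 2] - 1) / max(d[2] - 1, 1) - 1
  cz <- 2 * (coords[, 3] - 1) / max(d[3] - 1, 1) - 1
  if (length(bright) > max_fit_voxels) {
    keep <- seq(1, length(bright), length.out = max_fit_voxels)
    cx <- cx[keep]; cy <- cy[keep]; cz <- cz[keep]
    yv <- log(a[bright][keep])
  } else {
    yv <- log(a[bright])
  }
  terms <- expand.grid(i = 0:order, j = 0:order, k = 0:order)
  terms <- terms[rowSums(terms) <= order, , drop = FALSE]
  X <- mapply(function(i, j, k) cx^i * cy^j * cz^k,
              terms$i, terms$j, terms$k)
  beta <- stats::lm.fit(X, yv)$coefficients
  beta[is.na(beta)] <- 0
  # evaluate log-gain on the full grid, term by term
  px <- 2 * (seq_len(d[1]) - 1) / max(d[1] - 1, 1) - 1
  py <- 2 * (seq_len(d[2]) - 1) / max(d[2] - 1, 1) - 1
  pz <- 2 * (seq_len(d[3]) - 1) / max(d[3] - 1, 1) - 1
  logg <- array(0, d)
  for (t in seq_len(nrow(terms))) {
    if (beta[t] == 0) next
    logg <- logg + beta[t] * outer(outer(px^terms$i[t], py^terms$j[t]),
                                   pz^terms$k[t])
  }
  # the polynomial is only constrained where bright voxels exist; clamp
  # the log-gain elsewhere to the range seen at the fitted voxels so the
  # extrapolated field cannot explode in empty corners
  fitted_rng <- range(logg[bright])
  logg <- pmin(pmax(logg, fitted_rng[1]), fitted_rng[2])
  gain <- exp(logg - mean(logg))
  out <- a / gain
  out <- out * (mean(a) / mean(out))
  cord_volume(out, vol$spacing, vol$axes)
}
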