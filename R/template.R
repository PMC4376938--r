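# Cervical cord template construction: straightened, centred volumes are
# standardized to a common length, averaged, and smoothed; the averaged
# binary masks give a voxelwise cord-probability map.

#' Standardize the cord length of a straightened pair
#'
#' Rescales the SI axis to exactly `target_slices` slices (typically the
#' cohort median length), using cubic interpolation for intensities and
#' nearest neighbour for the mask. In-plane axes are untouched, so
#' per-slice cross-sectional geometry is preserved.
#'
#' @param vol A [cord_volume] (straightened).
#' @param mask 3D logical array paired with `vol`.
#' @param target_slices Target number of SI slices (>= 2).
#' @return List with rescaled `volume` and `mask`.
#' @export
standardize_length <- function(vol, mask, target_slices) {
  if (target_slices < 2) stop("target length must be >= 2 slices", call. = FALSE)
  nz <- dim(vol$data)[3]
  if (nz < 2) stop("degenerate input length", call. = FALSE)
  # voxel-centre mapping: output slice k centre at fraction (k-0.5)/target
  x_out <- (seq_len(target_slices) - 0.5) * nz / target_slices + 0.5
  Wc <- .interp_matrix(nz, x_out, "cubic")
  Wn <- .interp_matrix(nz, x_out, "nearest")
  a <- .apply_axis(vol$data, 3, Wc)
  a[a < 0] <- 0
  m <- .apply_axis(mask * 1, 3, Wn) > 0.5
  sp <- vol$spacing
  sp[3] <- sp[3] * nz / target_slices
  list(volume = cord_volume(a, sp, vol$axes), mask = m)
}

#' Gaussian sigma corresponding to a FWHM
#' @param fwhm Full width at half maximum.
#' @return `fwhm / (2 * sqrt(2 * log(2)))`.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Build the cord template and tissue probability map
#'
#' The mean image is the voxelwise average of the standardized
#' straightened intensity volumes, smoothed with a separable 3D Gaussian
#' of the given FWHM (default 0.3 x 0.3 x 0.6 mm on RL, AP, SI). The
#' probability map is the voxelwise average of the binary cord masks --
#' the fraction of subjects whose cord covers each voxel -- and is not
#' smoothed.
#'
#' @param cohort List of subjects, each a list with `volume` (a
#'   [cord_volume]) and `mask` (3D logical), all standardized to the
#'   same shape.
#' @param fwhm Gaussian FWHM per axis in mm, length-3.
#' @return An object of class `cord_template`: list with `mean_image`,
#'   `probability_map` (both 3D arrays of the common shape),
#'   `n_subjects`, `standard_length_slices` and `spacing`.
#' @export
build_template <- function(cohort, fwhm = c(0.3, 0.3, 0.6)) {
  if (length(cohort) < 2) stop("template needs at least 2 subjects", call. = FALSE)
  d <- dim(cohort[[1]]$volume$data)
  sp <- cohort[[1]]$volume$spacing
  for (s in cohort) {
    if (!identical(dim(s$volume$data), d) || !identical(dim(s$mask), d))
      stop("all subjects must share the same standardized shape", call. = FALSE)
  }
  mean_img <- array(0, d)
  prob <- array(0, d)
  for (s in cohort) {
    mean_img <- mean_img + s$volume$data
    prob <- prob + (s$mask * 1)
  }
  n <- length(cohort)
  mean_img <- mean_img / n
  prob <- prob / n
  sigma_vox <- fwhm_to_sigma(fwhm) / sp
  for (axis in 1:3)
    mean_img <- .apply_axis(mean_img, axis, .gauss_matrix(d[axis], sigma_vox[axis]))
  structure(list(mean_image = mean_img,
                 probability_map = prob,
                 n_subjects = n,
                 standard_length_slices = d[3],
                 spacing = sp),
            class = "cord_template")
}

#' @export
print.cord_template <- function(x, ...) {
  d <- dim(x$mean_image)
  cat(sprintf("<cord_template> %d subjects, %d x %d x %d at %.3g x %.3g x %.3g mm\n",
              x$n_subjects, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  probability map range [%.3f, %.3f]\n",
              min(x$probability_map), max(x$probability_map)))
  invisible(x)
}

#' Mis-segmentation error rate
#'
#' Percentage of axial slices whose automatic segmentation needed
#' manual adjustment during template construction:
#' `100 * n_missegmented / n_total`.
#'
#' @param n_missegmented Number of mis-segmented axial slices.
#' @param n_total Total number of segmented axial slices (> 0).
#' @return Percentage.
#' @export
misseg_error_rate <- function(n_missegmented, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_missegmented < 0 || n_missegmented > n_total)
    stop("n_missegmented must lie in [0, n_total]", call. = FALSE)
  100 * n_missegmented / n_total
}
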