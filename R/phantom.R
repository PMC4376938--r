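# Synthetic cord phantom: a dark cord tube inside a brighter CSF ring
# embedded in darker tissue background, with optional sagittal-plane
# curvature, edge blur, multiplicative bias, Rician noise and minimal
# parametric lesions. Ground truth (mask, centerline, analytic CSA) is
# computed before any degradation, and a single seed determines the
# output bit for bit.

#' Phantom specification
#'
#' The defaults emulate the T2 contrast the segmentation method relies
#' on: bright CSF (200) around a darker cord (100) in darker background
#' tissue (50), a 4 mm cord radius, a 2 mm CSF ring, 0.3 mm isotropic
#' voxels, and Rician noise at SNR 15 relative to the cord intensity.
#'
#' @param fov_mm Field of view per axis (RL, AP, SI) in mm.
#' @param spacing_mm Isotropic voxel spacing in mm.
#' @param radius_mm Cord radius in mm: a constant or a function of SI
#'   position (mm).
#' @param ring_mm CSF ring thickness in mm.
#' @param amplitude_mm Sagittal (AP) sinusoidal curvature amplitude (0 =
#'   straight).
#' @param period_mm Sinusoid period in mm.
#' @param intensities Named means `c(cord, csf, background)`; must
#'   satisfy csf > cord > background.
#' @param blur_sigma_mm Gaussian edge blur in mm (0 = none).
#' @param noise_snr Rician SNR (cord intensity / noise sigma); 0 or
#'   `Inf` disables noise.
#' @param bias_range Multiplicative gain range `c(lo, hi)` of a smooth
#'   bias field, or `NULL` for none.
#' @param lesions List of lesions; each element is a list with `type`
#'   (`"focal_atrophy"`, `"hyperintensity"` or `"narrow_canal"`),
#'   `center_mm` (SI position), `extent_mm`, and a magnitude:
#'   `reduction_mm` (atrophy), `intensity` (hyperintensity) or
#'   `ring_mm` (canal narrowing).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(fov_mm = c(36, 36, 60), spacing_mm = 0.3,
                         radius_mm = 4, ring_mm = 2,
                         amplitude_mm = 0, period_mm = 150,
                         intensities = c(cord = 100, csf = 200,
                                         background = 50),
                         blur_sigma_mm = 0.3, noise_snr = 15,
                         bias_range = NULL, lesions = list()) {
  if (spacing_mm <= 0) stop("spacing must be positive", call. = FALSE)
  if (!(intensities["csf"] > intensities["cord"] &&
        intensities["cord"] > intensities["background"]))
    stop("contrast polarity must satisfy csf > cord > background",
         call. = FALSE)
  if (ring_mm <= 0) stop("CSF ring thickness must be positive", call. = FALSE)
  if (ring_mm < spacing_mm)
    warning("CSF ring thinner than one voxel; the ring may not close")
  structure(list(fov_mm = fov_mm, spacing_mm = spacing_mm,
                 radius_mm = radius_mm, ring_mm = ring_mm,
                 amplitude_mm = amplitude_mm, period_mm = period_mm,
                 intensities = intensities, blur_sigma_mm = blur_sigma_mm,
                 noise_snr = noise_snr, bias_range = bias_range,
                 lesions = lesions),
            class = "phantom_spec")
}

# raised-cosine window of a lesion along SI, in [0, 1]
.lesion_window <- function(z_mm, center_mm, extent_mm) {
  u <- (z_mm - center_mm) / (extent_mm / 2)
  w <- numeric(length(u))
  inside <- abs(u) < 1
  w[inside] <- 0.5 * (1 + cos(pi * u[inside]))
  w
}

# block mean of a (f*nr x f*nc) matrix down to (nr x nc)
.block_mean <- function(m, f) {
  nr <- nrow(m) %/% f
  nc <- ncol(m) %/% f
  dim(m) <- c(f, nr * f * nc)
  s1 <- colSums(m)
  dim(s1) <- c(nr, f, nc)
  s1 <- aperm(s1, c(2, 1, 3))
  dim(s1) <- c(f, nr * nc)
  matrix(colSums(s1) / (f * f), nr, nc)
}

#' Generate a phantom instance
#'
#' Renders the cord tube and CSF ring slice by slice with 4x
#' supersampled (partial-volume) boundaries, then applies edge blur,
#' bias field and Rician noise, in that order. Truth structures are
#' computed before degradation. The same spec and seed always produce
#' the identical volume; the caller's RNG state is left untouched.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed driving all phantom randomness.
#' @return An object of class `cord_phantom`: list with `volume` (a
#'   [cord_volume]), `truth_mask` (3D logical), `truth_centerline`
#'   (slices x 2, voxel coordinates), `truth_csa_mm2` (analytic, per
#'   slice), `spec` and `seed`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  sp <- spec$spacing_mm
  d <- pmax(4L, as.integer(round(spec$fov_mm / sp)))
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx_mm <- (nx - 1) * sp / 2
  cy_mm <- (ny - 1) * sp / 2
  z_mm <- (seq_len(nz) - 1) * sp

  r_of_z <- if (is.function(spec$radius_mm)) spec$radius_mm(z_mm)
            else rep(spec$radius_mm, nz)
  ring_of_z <- rep(spec$ring_mm, nz)
  hyper_list <- list()
  for (L in spec$lesions) {
    w <- .lesion_window(z_mm, L$center_mm, L$extent_mm)
    if (L$type == "focal_atrophy") {
      r_of_z <- r_of_z - L$reduction_mm * w
    } else if (L$type == "narrow_canal") {
      ring_of_z <- pmax(spec$spacing_mm / 2,
                        ring_of_z - (spec$ring_mm - L$ring_mm) * w)
    } else if (L$type == "hyperintensity") {
      hyper_list[[length(hyper_list) + 1]] <- list(w = w, dI = L$intensity)
    } else stop("unknown lesion type: ", L$type, call. = FALSE)
  }
  if (any(r_of_z <= 0))
    stop("invalid geometry: cord radius must stay positive", call. = FALSE)

  cy_mm_z <- cy_mm + if (spec$amplitude_mm != 0)
    spec$amplitude_mm * sin(2 * pi * z_mm / spec$period_mm) else rep(0, nz)

  f <- 4L  # in-plane supersampling factor
  xs <- ((seq_len(nx * f) - 0.5) / f - 0.5) * sp   # mm, fine grid
  ys <- ((seq_len(ny * f) - 0.5) / f - 0.5) * sp
  ints <- spec$intensities
  vol <- array(0, c(nx, ny, nz))
  truth <- array(FALSE, c(nx, ny, nz))
  truth_csa <- pi * r_of_z^2
  centerline <- cbind(row = rep(cx_mm / sp + 1, nz),
                      col = cy_mm_z / sp + 1)

  dx2 <- (xs - cx_mm)^2
  for (z in seq_len(nz)) {
    dy2 <- (ys - cy_mm_z[z])^2
    dist2 <- outer(dx2, dy2, `+`)
    cord_f <- .block_mean((dist2 <= r_of_z[z]^2) * 1, f)
    canal_f <- .block_mean((dist2 <= (r_of_z[z] + ring_of_z[z])^2) * 1, f)
    slice <- ints["background"] +
      (ints["csf"] - ints["background"]) * canal_f +
      (ints["cord"] - ints["csf"]) * cord_f
    for (h in hyper_list) {
      if (h$w[z] > 0)
        slice <- slice + h$dI * h$w[z] * cord_f
    }
    vol[, , z] <- slice
    truth[, , z] <- cord_f >= 0.5
  }

  if (spec$blur_sigma_mm > 0) {
    sv <- spec$blur_sigma_mm / sp
    for (axis in 1:3)
      vol <- .apply_axis(vol, axis, .gauss_matrix(dim(vol)[axis], sv))
  }
  if (!is.null(spec$bias_range)) {
    lo <- spec$bias_range[1]; hi <- spec$bias_range[2]
    gx <- seq(0, 1, length.out = nx)
    gy <- seq(0, 1, length.out = ny)
    gz <- seq(0, 1, length.out = nz)
    g <- array(0, c(nx, ny, nz))
    for (k in 1:3) {
      amp <- stats::runif(1, 0.5, 1)
      # B1 gain varies on the coil scale: below one cycle across the FOV
      fr <- stats::runif(3, 0.2, 0.6)
      ph <- stats::runif(3, 0, 2 * pi)
      g <- g + amp * outer(outer(cos(2 * pi * fr[1] * gx + ph[1]),
                                 cos(2 * pi * fr[2] * gy + ph[2])),
                           cos(2 * pi * fr[3] * gz + ph[3]))
    }
    g <- (g - min(g)) / (max(g) - min(g))
    vol <- vol * (lo + (hi - lo) * g)
  }
  if (is.finite(spec$noise_snr) && spec$noise_snr > 0) {
    sigma <- as.numeric(spec$intensities["cord"]) / spec$noise_snr
    n <- length(vol)
    vol <- sqrt((vol + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  }

  structure(list(volume = cord_volume(vol, rep(sp, 3)),
                 truth_mask = truth,
                 truth_centerline = centerline,
                 truth_csa_mm2 = truth_csa,
                 spec = spec, seed = as.integer(seed)),
            class = "cord_phantom")
}

#' @export
print.cord_phantom <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("<cord_phantom> %d x %d x %d at %.3g mm, seed %d\n",
              d[1], d[2], d[3], x$volume$spacing[1], x$seed))
  cat(sprintf("  cord radius %s mm, curvature amplitude %.3g mm, SNR %s\n",
              if (is.function(x$spec$radius_mm)) "(profile)"
              else format(x$spec$radius_mm),
              x$spec$amplitude_mm, format(x$spec$noise_snr)))
  invisible(x)
}

#' Inject per-slice failures into a phantom truth
#'
#' Builds the per-slice input of [correct_segmentation()] from the
#' phantom ground truth, then marks a random fraction of slices as
#' failed (mask removed) and translates the masks of a disjoint random
#' fraction of slices by more than the discontinuity threshold,
#' exercising the repair path.
#'
#' @param instance A [generate_phantom()] result.
#' @param fraction Fraction of slices to fail, in \[0, 1).
#' @param displace_frac Fraction of slices to displace (default 0.05).
#' @param displace_vox Translation magnitude in voxels (default 20).
#' @param seed Integer seed.
#' @return List with `slices` (per-slice `slice_segmentation`-like
#'   objects with spacing/shape attributes), `failed` and `displaced`
#'   (slice indices).
#' @export
inject_failures <- function(instance, fraction, displace_frac = 0.05,
                            displace_vox = 20, seed = 1L) {
  stopifnot(inherits(instance, "cord_phantom"))
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  sp <- instance$volume$spacing
  shape <- dim(instance$truth_mask)
  nz <- shape[3]
  n_fail <- floor(fraction * nz)
  failed <- sort(sample(nz, n_fail))
  pool <- setdiff(seq_len(nz), failed)
  n_disp <- floor(displace_frac * nz)
  displaced <- sort(sample(pool, min(n_disp, length(pool))))
  slices <- vector("list", nz)
  for (z in seq_len(nz)) {
    m <- instance$truth_mask[, , z]
    if (z %in% failed) {
      slices[[z]] <- .failed_slice("injected")
      next
    }
    if (z %in% displaced) {
      theta <- stats::runif(1, 0, 2 * pi)
      dr <- round(displace_vox * sin(theta))
      dc <- round(displace_vox * cos(theta))
      # keep the displacement magnitude above the threshold after rounding
      if (sqrt(dr^2 + dc^2) < displace_vox) {
        dr <- sign(dr + 0.5) * ceiling(abs(displace_vox * sin(theta)))
        dc <- sign(dc + 0.5) * ceiling(abs(displace_vox * cos(theta)))
      }
      m <- .translate_mask(m, dr, dc)
    }
    slices[[z]] <- structure(
      list(m_csf = NULL, m_f = NULL, m_sc = m,
           otsu_threshold = NA_real_, losseff_threshold = NA_real_,
           enhancement_iterations = 0L,
           csa_mm2 = compute_csa(m, sp[1:2]), status = "ok"),
      class = "slice_segmentation")
  }
  attr(slices, "spacing") <- sp
  attr(slices, "shape") <- shape
  list(slices = slices, failed = failed, displaced = displaced)
}

.translate_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  idx <- which(m)
  r <- (idx - 1) %% nrow(m) + 1 + dr
  c <- (idx - 1) %/% nrow(m) + 1 + dc
  keep <- r >= 1 & r <= nrow(m) & c >= 1 & c <= ncol(m)
  out[cbind(r[keep], c[keep])] <- TRUE
  out
}
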