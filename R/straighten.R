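# Curved-to-straight reformatting: the volume is resampled in planes
# perpendicular to the smoothed centerline so the cord becomes a
# straight column centred in the field of view, and the standard
# five-slab cross-sectional stack at C2 is cut from the result.

#' Per-slice orthonormal frames along the centerline
#'
#' Resamples the centerline at uniform arc length and builds a
#' rotation-minimizing (parallel-transport) frame at each sample: the
#' unit tangent comes from central differences on the arc-length
#' parameterized curve, and the in-plane axes are transported from an
#' initial frame with minimal twist. Parallel transport is used rather
#' than Frenet frames, which are undefined at zero curvature and flip
#' sign at inflections.
#'
#' @param centerline Complete centerline matrix (`row`, `col` per
#'   slice).
#' @param spacing Voxel spacing, length-3, mm.
#' @param step_mm Arc-length step between output planes (defaults to the
#'   SI spacing).
#' @return List with `points` (n x 3, mm), `tangent`, `u`, `v` (n x 3
#'   orthonormal), and `arc_mm`.
#' @export
frame_field <- function(centerline, spacing, step_mm = spacing[3]) {
  n <- nrow(centerline)
  if (n < 2 || anyNA(centerline))
    stop("frame field needs a complete centerline with >= 2 points",
         call. = FALSE)
  P <- cbind((centerline[, 1] - 1) * spacing[1],
             (centerline[, 2] - 1) * spacing[2],
             (seq_len(n) - 1) * spacing[3])
  seg <- sqrt(rowSums(diff(P)^2))
  if (any(seg == 0)) stop("degenerate centerline step", call. = FALSE)
  s <- c(0, cumsum(seg))
  L <- s[n]
  n_out <- max(2L, floor(L / step_mm) + 1L)
  s_out <- (seq_len(n_out) - 1) * step_mm
  Q <- cbind(stats::spline(s, P[, 1], xout = s_out, method = "fmm")$y,
             stats::spline(s, P[, 2], xout = s_out, method = "fmm")$y,
             stats::spline(s, P[, 3], xout = s_out, method = "fmm")$y)
  tg <- matrix(0, n_out, 3)
  tg[1, ] <- Q[2, ] - Q[1, ]
  tg[n_out, ] <- Q[n_out, ] - Q[n_out - 1, ]
  if (n_out > 2)
    tg[2:(n_out - 1), ] <- Q[3:n_out, ] - Q[1:(n_out - 2), ]
  tg <- tg / sqrt(rowSums(tg^2))
  u <- matrix(0, n_out, 3)
  v <- matrix(0, n_out, 3)
  e <- c(1, 0, 0)
  u0 <- e - sum(e * tg[1, ]) * tg[1, ]
  if (sqrt(sum(u0^2)) < 1e-8) {
    e <- c(0, 1, 0)
    u0 <- e - sum(e * tg[1, ]) * tg[1, ]
  }
  u[1, ] <- u0 / sqrt(sum(u0^2))
  v[1, ] <- .cross3(tg[1, ], u[1, ])
  for (k in 2:n_out) {
    w <- u[k - 1, ] - sum(u[k - 1, ] * tg[k, ]) * tg[k, ]
    u[k, ] <- w / sqrt(sum(w^2))
    v[k, ] <- .cross3(tg[k, ], u[k, ])
  }
  list(points = Q, tangent = tg, u = u, v = v, arc_mm = s_out)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Straighten a volume along the cord centerline
#'
#' Each output axial slice samples the plane perpendicular to the
#' centerline at uniform arc length; the cord centre maps to the centre
#' of the output grid. Intensities are interpolated tricubically and
#' the mask by nearest neighbour. Sample points falling outside the
#' source field of view are set to 0 and counted.
#'
#' @param vol A [cord_volume] (isotropic working resolution).
#' @param seg A `cord_segmentation` whose centerline guides the
#'   reformat.
#' @param out_plane Output in-plane dimensions `c(nrow, ncol)`
#'   (defaults to the source in-plane dimensions).
#' @param step_mm Output (isotropic) spacing in mm; defaults to the SI
#'   spacing of `vol`.
#' @return An object of class `straightened_cord`: list with `volume`
#'   (a [cord_volume]), `mask` (3D logical), `center` (fixed in-plane
#'   cord position, row/col), `arc_mm` (source arc length per output
#'   slice) and `n_outside`.
#' @export
straighten_volume <- function(vol, seg, out_plane = NULL, step_mm = NULL) {
  if (is.null(step_mm)) step_mm <- vol$spacing[3]
  d <- dim(vol$data)
  if (is.null(out_plane)) out_plane <- d[1:2]
  ff <- frame_field(seg$centerline, vol$spacing, step_mm)
  n_out <- nrow(ff$points)
  cx <- (out_plane[1] + 1) / 2
  cy <- (out_plane[2] + 1) / 2
  off_a <- (rep(seq_len(out_plane[1]), times = out_plane[2]) - cx) * step_mm
  off_b <- (rep(seq_len(out_plane[2]), each = out_plane[1]) - cy) * step_mm
  out <- array(0, c(out_plane, n_out))
  outm <- array(FALSE, c(out_plane, n_out))
  n_outside <- 0L
  for (k in seq_len(n_out)) {
    pos <- cbind(ff$points[k, 1] + off_a * ff$u[k, 1] + off_b * ff$v[k, 1],
                 ff$points[k, 2] + off_a * ff$u[k, 2] + off_b * ff$v[k, 2],
                 ff$points[k, 3] + off_a * ff$u[k, 3] + off_b * ff$v[k, 3])
    pts <- cbind(pos[, 1] / vol$spacing[1] + 1,
                 pos[, 2] / vol$spacing[2] + 1,
                 pos[, 3] / vol$spacing[3] + 1)
    # the cord continues beyond the imaged SI range: replicate the end
    # slices there instead of cutting the first/last oblique planes
    pts[, 3] <- pmin(pmax(pts[, 3], 1), d[3])
    vals <- .sample_tricubic(vol$data, pts)
    n_outside <- n_outside + attr(vals, "n_outside")
    vals[vals < 0] <- 0
    out[, , k] <- vals
    outm[, , k] <- .sample_nearest(seg$mask * 1, pts) > 0.5
  }
  if (n_outside > 0)
    warning(sprintf("%d sample points fell outside the source FOV", n_outside))
  structure(list(volume = cord_volume(out, rep(step_mm, 3), vol$axes),
                 mask = outm,
                 center = c(row = cx, col = cy),
                 arc_mm = ff$arc_mm,
                 n_outside = n_outside),
            class = "straightened_cord")
}

#' @export
print.straightened_cord <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("<straightened_cord> %d x %d x %d, %.3g mm iso, cord centred at (%.1f, %.1f)\n",
              d[1], d[2], d[3], x$volume$spacing[1], x$center[1], x$center[2]))
  invisible(x)
}

#' Select the five-slab cross-sectional stack at C2
#'
#' Partitions the region superior to the C2/C3 disk landmark into
#' `n_slabs` contiguous slabs of `slab_mm` thickness, the most inferior
#' slab centred on the landmark slice; each output slice is the
#' voxelwise mean of the thin slices in its slab. The superior
#' direction is taken as increasing slice index.
#'
#' @param straight A `straightened_cord` or [cord_volume].
#' @param disk_slice Slice index of the C2/C3 disk (operator-supplied
#'   anatomical landmark).
#' @param slab_mm Slab thickness in mm (default 3).
#' @param n_slabs Number of slabs (default 5).
#' @return 3D array `nrow x ncol x n_slabs` of slab-averaged slices;
#'   attributes `slab_indices` (list of thin-slice indices) and
#'   `spacing`.
#' @export
select_c2_stack <- function(straight, disk_slice, slab_mm = 3, n_slabs = 5) {
  vol <- if (inherits(straight, "straightened_cord")) straight$volume
         else straight
  dz <- vol$spacing[3]
  nz <- dim(vol$data)[3]
  per <- max(1L, round(slab_mm / dz))
  start <- disk_slice - per %/% 2
  idx_last <- start + n_slabs * per - 1
  if (start < 1 || idx_last > nz)
    stop("insufficient extent for the requested slab stack", call. = FALSE)
  out <- array(0, c(dim(vol$data)[1:2], n_slabs))
  slab_indices <- vector("list", n_slabs)
  for (k in seq_len(n_slabs)) {
    idx <- start + (k - 1) * per + 0:(per - 1)
    slab_indices[[k]] <- idx
    sub <- vol$data[, , idx, drop = FALSE]
    out[, , k] <- apply(sub, c(1, 2), mean)
  }
  attr(out, "slab_indices") <- slab_indices
  attr(out, "spacing") <- c(vol$spacing[1:2], slab_mm)
  out
}
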