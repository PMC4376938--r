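# Per-axial-slice double threshold-based segmentation. On a T2-weighted
# slice the CSF ring around the cord is the brightest structure: an Otsu
# threshold (first threshold) isolates it, flood filling closes it, and a
# Losseff-style mid-intensity threshold (second threshold) separates the
# darker cord from the CSF inside the filled region. Slices where the
# ring cannot be closed after repeated contrast enhancement are reported
# as failed and handed to the 3D correction step, never raised as errors.

.csf_not_found <- function(msg = "csf-not-found") {
  structure(class = c("cordseg_csf_not_found", "error", "condition"),
            list(message = msg, call = NULL))
}

# Shared exact-moment Otsu: histograms values into equal-width bins over
# [min, max], keeping per-bin counts and value sums so between-class
# variance is computed from exact class means rather than bin centres.
.otsu_core <- function(x, bins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[2] <= rng[1]) stop("no contrast: constant input", call. = FALSE)
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  w <- (rng[2] - rng[1]) / bins
  bin <- pmin(floor((x - rng[1]) / w) + 1L, bins)
  cnt <- tabulate(bin, bins)
  sums <- numeric(bins)
  rs <- rowsum(x, bin)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  W0 <- cumsum(as.numeric(cnt))
  S0 <- cumsum(sums)
  n <- W0[bins]; tot <- S0[bins]
  k <- seq_len(bins - 1)
  w0 <- W0[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, bins - 1)
  m0 <- S0[k][valid] / w0[valid]
  m1 <- (tot - S0[k][valid]) / w1[valid]
  bcv[valid] <- w0[valid] * w1[valid] * (m0 - m1)^2
  kstar <- which.max(bcv)  # smallest maximizing bin edge
  list(threshold = rng[1] + kstar * w, between_class = bcv[kstar])
}

#' Otsu threshold of an axial slice
#'
#' Histogram-based Otsu thresholding: the intensity histogram over
#' \[min, max\] is split at every bin edge and the edge maximizing the
#' between-class variance is returned (the smallest such edge on ties).
#' Class means are computed from exact per-bin value sums, so for data
#' with at most one distinct value per bin the result coincides with
#' exhaustive search over all value cuts. Pixels strictly above the
#' threshold form the foreground, which on T2 slices is mainly CSF.
#'
#' @param slice 2D numeric matrix of intensities.
#' @param bins Number of histogram bins (default 256).
#' @return The threshold intensity (a bin edge).
#' @export
otsu_threshold <- function(slice, bins = 256) {
  .otsu_core(slice, bins)$threshold
}

#' Extract the CSF mask from the Otsu foreground
#'
#' Ranks the 8-connected components of the foreground that have at least
#' `min_size` pixels by their mean intensity and returns the
#' highest-mean component as the CSF mask. Mean (rather than maximum)
#' intensity makes the ranking robust to isolated bright speckle.
#'
#' @param slice 2D numeric matrix of intensities.
#' @param fg Logical matrix, foreground from [otsu_threshold()].
#' @param min_size Minimum component size in pixels (default 50, defined
#'   at the 0.3 mm working resolution).
#' @return Logical CSF mask. Throws a classed condition
#'   (`cordseg_csf_not_found`) when no component reaches `min_size`;
#'   [segment_slice()] catches it and enters the contrast-enhancement
#'   loop.
#' @export
extract_csf_mask <- function(slice, fg, min_size = 50) {
  if (min_size < 1) stop("min_size must be >= 1", call. = FALSE)
  lab <- label_components(fg)
  n <- attr(lab, "n")
  if (n == 0) stop(.csf_not_found())
  sizes <- tabulate(lab[lab > 0], n)
  cand <- which(sizes >= min_size)
  if (!length(cand)) stop(.csf_not_found())
  sums <- rowsum(as.numeric(slice[lab > 0]), lab[lab > 0])
  means <- sums[, 1] / sizes[as.integer(rownames(sums))]
  best <- cand[which.max(means[match(cand, as.integer(rownames(sums)))])]
  lab == best
}

#' Global contrast enhancement by upper-histogram truncation
#'
#' Clips intensities above the `1 - upper_frac` quantile and linearly
#' rescales the clipped range back to the original \[min, max\]. Applied
#' iteratively when the CSF ring fails to close, this stretches the
#' upper intensities apart so the ring eventually separates from
#' surrounding tissue.
#'
#' @param slice 2D numeric matrix.
#' @param upper_frac Fraction of the histogram's upper end to truncate
#'   (default 0.001, i.e. 0.1 percent).
#' @return The enhanced slice; a monotone non-decreasing intensity map.
#' @export
enhance_contrast <- function(slice, upper_frac = 0.001) {
  if (upper_frac <= 0 || upper_frac >= 1)
    stop("upper_frac must be in (0, 1)", call. = FALSE)
  rng <- range(slice)
  if (rng[2] <= rng[1]) stop("no contrast: constant slice", call. = FALSE)
  q <- stats::quantile(slice, 1 - upper_frac, names = FALSE)
  if (q >= rng[2] || q <= rng[1]) return(slice)
  out <- pmin(slice, q)
  rng[1] + (out - rng[1]) / (q - rng[1]) * (rng[2] - rng[1])
}

#' Mid-intensity (Losseff) cord classification
#'
#' Computes the second threshold of the method as the midpoint of the
#' mean intensities over the cord and CSF seed regions, classifies
#' pixels below it (within the filled CSF domain) as cord candidates,
#' and returns the 8-connected candidate component containing the cord
#' seed's centre of mass.
#'
#' @param slice 2D numeric matrix (the original, non-enhanced slice).
#' @param cord_seed,csf_seed Non-empty logical seed masks (typically the
#'   eroded cord and CSF masks).
#' @param domain Logical matrix restricting the classification,
#'   typically the filled CSF mask.
#' @return List with `mask` (logical cord mask) and `threshold`.
#' @export
losseff_segment <- function(slice, cord_seed, csf_seed, domain) {
  if (!any(cord_seed) || !any(csf_seed))
    stop("seed-empty: both seed regions must be non-empty", call. = FALSE)
  thr <- (mean(slice[cord_seed]) + mean(slice[csf_seed])) / 2
  cand <- domain & (slice < thr)
  if (!any(cand)) return(list(mask = cand, threshold = thr))
  lab <- label_components(cand)
  com <- .center_of_mass(cord_seed)
  pr <- min(max(round(com[1]), 1), nrow(cand))
  pc <- min(max(round(com[2]), 1), ncol(cand))
  id <- lab[pr, pc]
  if (id == 0) {
    # centre pixel not a candidate: take the component overlapping the
    # seed the most
    ov <- lab[cord_seed & cand]
    if (!length(ov)) return(list(mask = cand & FALSE, threshold = thr))
    id <- as.integer(names(which.max(table(ov))))
  }
  list(mask = lab == id, threshold = thr)
}

.center_of_mass <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  r <- (idx - 1) %% nr + 1
  c <- (idx - 1) %/% nr + 1
  c(mean(r), mean(c))
}

#' Cross-sectional area of a mask
#'
#' Pixel count times pixel area. For a multi-slice cross-sectional
#' measurement the reported CSA is the mean over slices, which
#' [evaluate_segmentation()] and [csa_table()] compute from per-slice
#' values.
#'
#' @param mask Logical or 0/1 matrix.
#' @param spacing In-plane pixel spacing, length-2, mm.
#' @return Area in mm^2.
#' @export
compute_csa <- function(mask, spacing) {
  sum(mask != 0) * spacing[1] * spacing[2]
}

#' Configuration for the per-slice segmentation
#'
#' @param min_size Minimum CSF component size in pixels.
#' @param erosion_radius Seed erosion disk radius in pixels.
#' @param max_enhance Cap on contrast-enhancement retries.
#' @param bins Otsu histogram bins.
#' @param upper_frac Upper-histogram truncation fraction per retry.
#' @return A list of class `dtbm_config`.
#' @export
dtbm_config <- function(min_size = 50, erosion_radius = 3, max_enhance = 10,
                        bins = 256, upper_frac = 0.001) {
  structure(list(min_size = min_size, erosion_radius = erosion_radius,
                 max_enhance = max_enhance, bins = bins,
                 upper_frac = upper_frac),
            class = "dtbm_config")
}

.failed_slice <- function(reason, m_csf = NULL, m_f = NULL,
                          otsu = NA_real_, iters = 0L) {
  structure(list(m_csf = m_csf, m_f = m_f, m_sc = NULL,
                 otsu_threshold = otsu, losseff_threshold = NA_real_,
                 enhancement_iterations = iters, csa_mm2 = NA_real_,
                 status = "failed", reason = reason),
            class = "slice_segmentation")
}

#' Segment one axial slice with the double threshold-based method
#'
#' Runs the full per-slice chain: Otsu thresholding of the (possibly
#' contrast-enhanced) slice, CSF component selection, flood fill,
#' contrast-enhancement retries while the ring is open or no CSF
#' component is found, disk erosion of both masks into seeds, and
#' mid-intensity classification on the original intensities. Failures
#' are encoded in the returned status, never raised, so the 3D
#' correction step can repair them.
#'
#' @param slice 2D numeric matrix of intensities.
#' @param spacing In-plane pixel spacing, length-2, mm.
#' @param cfg A [dtbm_config()].
#' @return An object of class `slice_segmentation` with elements
#'   `m_csf`, `m_f`, `m_sc`, `otsu_threshold`, `losseff_threshold`,
#'   `enhancement_iterations`, `csa_mm2`, `status` ("ok" or "failed")
#'   and, for failures, `reason`.
#' @export
segment_slice <- function(slice, spacing, cfg = dtbm_config()) {
  work <- slice
  iters <- 0L
  repeat {
    step <- tryCatch({
      t1 <- otsu_threshold(work, cfg$bins)
      fg <- work > t1
      m_csf <- extract_csf_mask(work, fg, cfg$min_size)
      m_f <- flood_fill(m_csf)
      list(t1 = t1, m_csf = m_csf, m_f = m_f, retry = !any(m_f & !m_csf))
    },
    cordseg_csf_not_found = function(e) "retry",
    error = function(e) "abort")
    if (identical(step, "abort"))
      return(.failed_slice("no-contrast", iters = iters))
    retry <- identical(step, "retry") || isTRUE(step$retry)
    if (!retry) break
    if (iters >= cfg$max_enhance) {
      reason <- if (identical(step, "retry")) "csf-not-found" else "ring-open"
      return(.failed_slice(reason, iters = iters))
    }
    work <- tryCatch(enhance_contrast(work, cfg$upper_frac),
                     error = function(e) NULL)
    if (is.null(work))
      return(.failed_slice("no-contrast", iters = iters))
    iters <- iters + 1L
  }
  m_csf <- step$m_csf
  m_f <- step$m_f
  m_sc0 <- m_f & !m_csf
  cord_seed <- erode_mask(m_sc0, cfg$erosion_radius)
  csf_seed <- erode_mask(m_csf, cfg$erosion_radius)
  if (!any(cord_seed) || !any(csf_seed))
    return(.failed_slice("seed-empty", m_csf, m_f, step$t1, iters))
  los <- losseff_segment(slice, cord_seed, csf_seed, m_f)
  m_sc <- los$mask
  if (!any(m_sc))
    return(.failed_slice("empty-cord", m_csf, m_f, step$t1, iters))
  # boundary pixels reassigned to the cord by the second threshold leave
  # the CSF mask, keeping the two masks disjoint
  m_csf <- m_csf & !m_sc
  structure(list(m_csf = m_csf, m_f = m_f, m_sc = m_sc,
                 otsu_threshold = step$t1,
                 losseff_threshold = los$threshold,
                 enhancement_iterations = iters,
                 csa_mm2 = compute_csa(m_sc, spacing),
                 status = "ok"),
            class = "slice_segmentation")
}

#' @export
print.slice_segmentation <- function(x, ...) {
  cat(sprintf("<slice_segmentation> status=%s", x$status))
  if (x$status == "ok")
    cat(sprintf(", csa=%.2f mm^2, thresholds=(%.3g, %.3g), retries=%d",
                x$csa_mm2, x$otsu_threshold, x$losseff_threshold,
                x$enhancement_iterations))
  else cat(sprintf(" (%s)", x$reason))
  cat("\n")
  invisible(x)
}

#' Per-slice results as a data frame
#'
#' @param slices List of `slice_segmentation` objects (one per axial
#'   slice).
#' @return A data frame with columns `slice_index`, `status`,
#'   `otsu_threshold`, `losseff_threshold`, `enhancement_iterations`,
#'   `csa_mm2`, exportable as CSV.
#' @export
csa_table <- function(slices) {
  data.frame(
    slice_index = seq_along(slices),
    status = vapply(slices, function(s) s$status, ""),
    otsu_threshold = vapply(slices, function(s) s$otsu_threshold, 0),
    losseff_threshold = vapply(slices, function(s) s$losseff_threshold, 0),
    enhancement_iterations = vapply(slices,
      function(s) as.integer(s$enhancement_iterations), 0L),
    csa_mm2 = vapply(slices, function(s) s$csa_mm2, 0)
  )
}

#' Segment a whole volume
#'
#' Applies [segment_slice()] to every axial slice and, unless
#' `correct = FALSE` (the cross-sectional mode), repairs the result with
#' the 3D correction step [correct_segmentation()].
#'
#' @param vol A [cord_volume] at the working resolution.
#' @param cfg A [dtbm_config()].
#' @param correct Run the 3D correction (default TRUE).
#' @return A [correct_segmentation()] result when `correct = TRUE`,
#'   otherwise the list of per-slice `slice_segmentation` objects with
#'   the volume spacing attached as an attribute.
#' @export
segment_cord <- function(vol, cfg = dtbm_config(), correct = TRUE) {
  nz <- dim(vol$data)[3]
  slices <- vector("list", nz)
  for (z in seq_len(nz))
    slices[[z]] <- segment_slice(vol$data[, , z], vol$spacing[1:2], cfg)
  attr(slices, "spacing") <- vol$spacing
  attr(slices, "shape") <- dim(vol$data)
  if (!correct) return(slices)
  correct_segmentation(slices, vol$spacing, dim(vol$data))
}
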