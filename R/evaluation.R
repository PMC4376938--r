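# Segmentation quality metrics: Dice similarity coefficient and the
# signed relative cross-sectional area error against a reference
# (typically manual) segmentation.

#' Dice similarity coefficient
#'
#' `2 |GT intersect S| / (|GT| + |S|)`, the standard overlap fraction in
#' \[0, 1\].
#'
#' @param gt,s Binary masks (2D or 3D) of identical shape.
#' @return Dice coefficient as a fraction.
#' @export
dice <- function(gt, s) {
  if (!identical(dim(gt), dim(s)))
    stop("masks must have the same shape", call. = FALSE)
  a <- sum(gt != 0)
  b <- sum(s != 0)
  if (a + b == 0)
    stop("Dice undefined: both masks are empty", call. = FALSE)
  2 * sum(gt != 0 & s != 0) / (a + b)
}

#' Relative CSA estimation error
#'
#' `100 * (s_csa - gt_csa) / gt_csa`; negative values mean the method
#' underestimates the reference cross-sectional area.
#'
#' @param gt_csa Reference CSA in mm^2 (> 0).
#' @param s_csa Measured CSA in mm^2.
#' @return Signed percentage.
#' @export
csa_error <- function(gt_csa, s_csa) {
  if (any(gt_csa <= 0))
    stop("reference CSA must be positive", call. = FALSE)
  100 * (s_csa - gt_csa) / gt_csa
}

#' Evaluate a segmentation against a reference
#'
#' Per-slice Dice and relative CSA error over the slices where the
#' reference is non-empty (slices without a drawn reference are
#' excluded from aggregation), plus their means. The 3D Dice is
#' reported both as the mean of per-slice values and, optionally, as a
#' single pooled-voxel coefficient.
#'
#' @param gt Reference 3D binary mask.
#' @param s Segmentation 3D binary mask, same shape.
#' @param spacing Voxel spacing, length-3, mm.
#' @param pooled Also compute the pooled-voxel 3D Dice.
#' @return An object of class `evaluation_report`: list with
#'   `per_slice` (data frame: `slice_index`, `dsc`, `csa_error_pct`),
#'   `mean_dsc`, `mean_dsc_pct`, `mean_csa_error_pct`, `n_slices` and,
#'   when requested, `dsc_3d_pooled`.
#' @export
evaluate_segmentation <- function(gt, s, spacing, pooled = FALSE) {
  if (!identical(dim(gt), dim(s)))
    stop("masks must have the same shape", call. = FALSE)
  nz <- dim(gt)[3]
  rows <- lapply(seq_len(nz), function(z) {
    g <- gt[, , z]
    if (!any(g != 0)) return(NULL)
    m <- s[, , z]
    d <- if (any(m != 0)) dice(g, m) else 0
    e <- csa_error(compute_csa(g, spacing[1:2]),
                   compute_csa(m, spacing[1:2]))
    data.frame(slice_index = z, dsc = d, csa_error_pct = e)
  })
  per_slice <- do.call(rbind, rows)
  if (is.null(per_slice))
    stop("reference mask is empty on every slice", call. = FALSE)
  rep <- list(per_slice = per_slice,
              mean_dsc = mean(per_slice$dsc),
              mean_dsc_pct = 100 * mean(per_slice$dsc),
              mean_csa_error_pct = mean(per_slice$csa_error_pct),
              n_slices = nrow(per_slice))
  if (pooled) rep$dsc_3d_pooled <- dice(gt, s)
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d slices: mean DSC %.2f%%, mean CSA error %+.2f%%\n",
              x$n_slices, x$mean_dsc_pct, x$mean_csa_error_pct))
  if (!is.null(x$dsc_3d_pooled))
    cat(sprintf("  pooled 3D DSC %.4f\n", x$dsc_3d_pooled))
  invisible(x)
}
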