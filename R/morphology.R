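# Binary morphology on axial slices. Foreground connectivity is
# 8-connected and background connectivity 4-connected (the standard dual
# pair), so a diagonal one-pixel gap does not open a CSF ring.

# Discrete disk structuring element {(i,j): i^2 + j^2 <= r^2}.
.disk_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  stopifnot(r >= 1)
  off <- (-r):r
  k <- outer(off^2, off^2, `+`) <= r^2
  storage.mode(k) <- "integer"
  k
}

#' Label 8-connected components of a binary mask
#'
#' Frontier-based breadth-first labelling with 8-connectivity for the
#' foreground. Returns an integer matrix of labels (0 = background),
#' numbered in first-encounter (column-major) order.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @return Integer matrix of the same shape; attribute `n` holds the
#'   number of components.
#' @keywords internal
label_components <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- integer(nr * nc)
  fg <- which(m)
  if (!length(fg)) {
    out <- matrix(lab, nr, nc)
    attr(out, "n") <- 0L
    return(out)
  }
  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  ncomp <- 0L
  for (seed in fg) {
    if (lab[seed] > 0L) next
    ncomp <- ncomp + 1L
    lab[seed] <- ncomp
    frontier <- seed
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nb <- integer(0)
      for (k in 1:8) {
        rr <- r + dr[k]; cc <- c + dc[k]
        keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (any(keep)) nb <- c(nb, rr[keep] + (cc[keep] - 1L) * nr)
      }
      nb <- unique(nb)
      nb <- nb[m[nb] & lab[nb] == 0L]
      lab[nb] <- ncomp
      frontier <- nb
    }
  }
  out <- matrix(lab, nr, nc)
  attr(out, "n") <- ncomp
  out
}

#' Fill the interior of a closed mask (flood fill)
#'
#' Background pixels not 4-connected to the slice border become
#' foreground; a mask forming a closed ring is therefore filled to a
#' disk, while an open (C-shaped) ring is returned unchanged because the
#' background leaks through the gap.
#'
#' @param mask Logical or 0/1 numeric matrix (typically the CSF mask).
#' @return Logical matrix with interior holes filled; always a superset
#'   of the input.
#' @export
flood_fill <- function(mask) {
  m <- mask != 0
  storage.mode(m) <- "integer"
  EBImage::fillHull(m) != 0
}

#' Erode a binary mask with a discrete disk
#'
#' Morphological erosion with structuring element
#' \eqn{\{(i,j): i^2+j^2 \le r^2\}}. Used to shrink the raw cord and CSF
#' masks into conservative seed regions before the mid-intensity
#' classification; the default radius of 3 pixels is defined at the
#' 0.3 mm working resolution.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param radius_px Disk radius in pixels (integer >= 1).
#' @return Logical matrix, always a subset of the input. May be empty;
#'   callers treat an empty seed as a failed slice.
#' @export
erode_mask <- function(mask, radius_px = 3) {
  m <- mask != 0
  if (!any(m)) return(m)
  # pad with background so pixels outside the image never support the
  # structuring element
  r <- as.integer(radius_px)
  p <- matrix(0L, nrow(m) + 2L * r, ncol(m) + 2L * r)
  p[r + seq_len(nrow(m)), r + seq_len(ncol(m))] <- m
  out <- EBImage::erode(p, .disk_kernel(r)) != 0
  out[r + seq_len(nrow(m)), r + seq_len(ncol(m)), drop = FALSE]
}
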