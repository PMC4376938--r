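# Independent brute-force oracles and small geometric fixtures used
# across the test files. Oracles are deliberately naive so they cannot
# share a bug with the implementation they check.

# exhaustive Otsu: try every unique value as a cut, maximize
# between-class variance directly; returns the foreground partition
brute_otsu_foreground <- function(x) {
  v <- as.vector(x)
  vals <- sort(unique(v))
  best <- -Inf
  best_fg <- NULL
  for (t in vals[-length(vals)]) {
    fg <- v > t
    n1 <- sum(fg); n0 <- length(v) - n1
    bc <- (n0 / length(v)) * (n1 / length(v)) *
      (mean(v[!fg]) - mean(v[fg]))^2
    if (bc > best) { best <- bc; best_fg <- fg }
  }
  matrix(best_fg, nrow(x), ncol(x))
}

# exhaustive erosion: a pixel survives iff every disk offset stays in
# the mask (offsets outside the image count as background)
brute_erode <- function(mask, r) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  offs <- expand.grid(i = -r:r, j = -r:r)
  offs <- offs[offs$i^2 + offs$j^2 <= r^2, ]
  for (rr in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (!mask[rr, cc]) next
    ri <- rr + offs$i; ci <- cc + offs$j
    inb <- ri >= 1 & ri <= nrow(mask) & ci >= 1 & ci <= ncol(mask)
    if (all(inb) && all(mask[cbind(ri, ci)])) out[rr, cc] <- TRUE
  }
  out
}

disk_mask <- function(n, center, radius) {
  d2 <- outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, `+`)
  d2 <= radius^2
}

annulus_mask <- function(n, center, r_in, r_out) {
  d2 <- outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, `+`)
  d2 >= r_in^2 & d2 <= r_out^2
}

mask_com <- function(mask) {
  idx <- which(mask)
  c(mean((idx - 1) %% nrow(mask) + 1), mean((idx - 1) %/% nrow(mask) + 1))
}

# hard-edged axial slice: cord disk inside a CSF annulus on background
hard_slice <- function(n = 100, r_cord = 13.3, r_out = 20,
                       ints = c(cord = 100, csf = 200, bg = 50)) {
  center <- c((n + 1) / 2, (n + 1) / 2)
  sl <- matrix(ints["bg"], n, n)
  sl[annulus_mask(n, center, 0, r_out)] <- ints["csf"]
  sl[disk_mask(n, center, r_cord)] <- ints["cord"]
  list(slice = sl, cord = disk_mask(n, center, r_cord),
       csf = annulus_mask(n, center, 0, r_out) &
         !disk_mask(n, center, r_cord),
       center = center)
}
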