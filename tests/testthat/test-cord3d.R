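test_that("centerline extraction is the per-slice centre of mass", {
  masks <- lapply(1:6, function(z) disk_mask(41, c(21, 21), 8))
  cl <- extract_centerline(masks)
  expect_equal(unname(cl[, 1]), rep(21, 6))
  expect_equal(unname(cl[, 2]), rep(21, 6))

  masks[[3]] <- disk_mask(41, c(21, 24), 8)  # shifted +3 columns
  cl2 <- extract_centerline(masks)
  expect_equal(unname(cl2[3, 2]) - unname(cl[3, 2]), 3)

  # two disjoint blobs: first moment of the union
  two <- disk_mask(41, c(10, 10), 4) | disk_mask(41, c(30, 30), 4)
  cl3 <- extract_centerline(list(two))
  expect_equal(unname(cl3[1, ]), mask_com(two))

  masks[[2]] <- NULL  # a list with some missing slices still works
  expect_true(anyNA(extract_centerline(list(disk_mask(21, c(11, 11), 5),
                                            NULL))))
  expect_error(extract_centerline(list(NULL, NULL)), "no slice")
})

test_that("robust lowess follows lines and shrugs off gross outliers", {
  y <- seq_len(40) * 0.5
  expect_equal(robust_lowess(y), y, tolerance = 1e-6)

  # small jitter keeps the residual scale estimate away from zero
  set.seed(8)
  y0 <- y + stats::rnorm(40, 0, 0.2)
  y2 <- y0; y2[20] <- y2[20] + 50
  sm_rob <- robust_lowess(y2)
  sm_plain <- stats::lowess(seq_along(y2), y2, f = 0.3, iter = 0)$y
  expect_lt(abs(sm_rob[20] - y0[20]), 1)
  expect_gt(abs(sm_plain[20] - y0[20]), 5)

  expect_equal(robust_lowess(rep(3, 10)), rep(3, 10))
  expect_error(robust_lowess(c(1, 2, 3)), "at least 5")
})

test_that("discontinuity detection flags isolated jumps beyond the threshold", {
  n <- 60
  cl <- cbind(row = 30 + 10 * sin(seq_len(n) / 12), col = rep(40, n))
  class(cl) <- c("centerline", class(cl))
  expect_length(detect_discontinuities(cl), 0)

  cl20 <- cl; cl20[25, 1] <- cl20[25, 1] + 20
  expect_equal(detect_discontinuities(cl20), 25)

  cl14 <- cl; cl14[25, 1] <- cl14[25, 1] + 14
  expect_length(detect_discontinuities(cl14), 0)
})

test_that("centerline gaps are spline-filled, ends by nearest value", {
  n <- 30
  lin <- cbind(row = seq_len(n) * 0.7 + 3, col = seq_len(n) * -0.2 + 50)
  gaps <- c(7, 12, 13, 21, 26)
  cl <- lin; cl[gaps, ] <- NA
  class(cl) <- c("centerline", class(cl))
  out <- interpolate_centerline(cl)
  expect_equal(out[gaps, 1], lin[gaps, 1], tolerance = 1e-6,
               ignore_attr = TRUE)

  sine <- cbind(row = 20 + 5 * sin(seq_len(n) / 5), col = rep(10, n))
  cls <- sine; cls[15, ] <- NA
  class(cls) <- c("centerline", class(cls))
  outs <- interpolate_centerline(cls)
  expect_lt(abs(outs[15, 1] - sine[15, 1]), 0.5)

  cle <- lin; cle[c(1, n), ] <- NA
  class(cle) <- c("centerline", class(cle))
  oute <- interpolate_centerline(cle)
  expect_equal(unname(oute[1, ]), unname(lin[2, ]))   # nearest-value end rule
  expect_equal(unname(oute[n, ]), unname(lin[n - 1, ]))

  few <- matrix(c(1, NA, NA, 2, NA, NA), 3, 2)
  expect_error(interpolate_centerline(few), "at least 4")
})

test_that("polar parameterization matches analytic radii", {
  dk <- disk_mask(61, c(31, 31), 20)
  ct <- mask_to_polar(dk)
  expect_length(ct$radii, 72)
  expect_true(all(abs(ct$radii - 20) <= 0.5))

  # axis-aligned ellipse, anti-aliased so the rasterization itself does
  # not corrupt the geometry: r(theta) = ab / sqrt(b^2 cos^2 + a^2
  # sin^2) with a = 20 along rows and b = 10 along columns
  a <- 20; b <- 10
  sub <- ((1:4) - 0.5) / 4 - 0.5
  el <- matrix(0, 61, 61)
  for (i in 1:61) for (j in 1:61)
    el[i, j] <- mean(outer(((i + sub - 31) / a)^2,
                           ((j + sub - 31) / b)^2, `+`) <= 1)
  ce <- mask_to_polar(el, center = c(31, 31))
  th <- ce$angles
  r_true <- a * b / sqrt((b * cos(th - pi / 2))^2 +
                         (a * sin(th - pi / 2))^2)
  expect_true(all(abs(ce$radii - r_true) <= 0.5))

  expect_error(mask_to_polar(matrix(FALSE, 9, 9)), "empty")
  expect_error(mask_to_polar(dk, center = c(2, 2)), "outside")
})

test_that("radius smoothing suppresses nerve-root spikes and fills gaps", {
  n <- 20
  base <- disk_mask(61, c(31, 31), 15)
  contours <- lapply(seq_len(n), function(z) mask_to_polar(base))
  sm <- smooth_radii(contours)
  expect_equal(dim(sm), c(n, 72))
  expect_true(all(abs(sm - contours[[1]]$radii[col(sm)]) < 0.1))

  spiked <- contours
  spiked[[10]]$radii[5] <- spiked[[10]]$radii[5] + 6  # simulated nerve root
  sm2 <- smooth_radii(spiked)
  expect_lt(abs(sm2[10, 5] - contours[[10]]$radii[5]), 2)

  # linear taper with 3 missing slices: filled on the taper line
  taper <- lapply(seq_len(n), function(z)
    list(center = c(31, 31), radii = rep(20 - 0.4 * z, 72),
         angles = (0:71) * pi / 36))
  taper[c(8, 9, 10)] <- list(NULL)
  sm3 <- smooth_radii(taper)
  expect_true(all(abs(sm3[8:10, ] -
                        outer(20 - 0.4 * (8:10), rep(1, 72))) < 0.5))
  expect_error(smooth_radii(list(NULL, NULL, NULL, NULL,
                                 mask_to_polar(base))), "at least 5")
})

test_that("polar contours rasterize back to near-identical masks", {
  ct <- list(center = c(31, 31), radii = rep(20, 72),
             angles = (0:71) * pi / 36)
  m <- polar_to_mask(ct, c(61, 61))
  expect_lt(abs(sum(m) - pi * 400) / (pi * 400), 0.02)

  dk <- disk_mask(61, c(30, 33), 17)
  rt <- polar_to_mask(mask_to_polar(dk), c(61, 61))
  expect_gte(dice(dk, rt), 0.99)

  expect_error(polar_to_mask(list(center = c(5, 5), radii = rep(0, 72)),
                             c(21, 21)), "degenerate")
})

test_that("3D correction is near-idempotent on clean stacks and repairs failures", {
  ph <- clean_straight_phantom()
  vol <- ph$volume
  slices <- segment_cord(vol, correct = FALSE)
  seg <- correct_segmentation(slices)
  # smoothing is near-identity on an already clean segmentation
  ds <- vapply(seq_along(slices), function(z)
    dice(slices[[z]]$m_sc, seg$mask[, , z]), 0)
  expect_true(all(ds >= 0.98))
  expect_true(all(seg$provenance == "segmented"))
  expect_true(all(seg$csa_mm2 > 0))
  # CSA variance does not increase on a constant-radius cord
  before <- vapply(slices, function(s) s$csa_mm2, 0)
  expect_lte(stats::sd(seg$csa_mm2), stats::sd(before) + 1e-9)
  # volume equals stacked CSA times slice thickness
  expect_lt(abs(seg$volume_mm3 - sum(seg$csa_mm2) * 0.3) /
              seg$volume_mm3, 0.005)

  # delete 10% of slices: repaired masks still match the truth
  set.seed(303)
  broken <- slices
  for (z in sample(length(slices), 5))
    broken[[z]] <- structure(list(m_csf = NULL, m_f = NULL, m_sc = NULL,
                                  otsu_threshold = NA_real_,
                                  losseff_threshold = NA_real_,
                                  enhancement_iterations = 0L,
                                  csa_mm2 = NA_real_, status = "failed",
                                  reason = "test"),
                             class = "slice_segmentation")
  attr(broken, "spacing") <- attr(slices, "spacing")
  attr(broken, "shape") <- attr(slices, "shape")
  seg2 <- correct_segmentation(broken)
  rep_idx <- which(seg2$provenance == "repaired")
  expect_gte(length(rep_idx), 5)
  for (z in rep_idx)
    expect_gte(dice(ph$truth_mask[, , z], seg2$mask[, , z]), 0.90)

  few <- broken[1:4]
  attr(few, "spacing") <- attr(slices, "spacing")
  attr(few, "shape") <- c(dim(vol$data)[1:2], 4)
  expect_error(correct_segmentation(few), "unrecoverable")
})
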