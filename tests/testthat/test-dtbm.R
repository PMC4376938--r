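test_that("Otsu threshold separates two-valued slices and matches exhaustive search", {
  two <- matrix(rep(c(0, 100), each = 50), 10, 10)
  t2 <- otsu_threshold(two)
  expect_true(all((two > t2) == (two == 100)))

  set.seed(201)
  for (i in 1:10) {
    sl <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    fg <- sl > otsu_threshold(sl)
    expect_identical(fg, brute_otsu_foreground(sl))
  }
  expect_error(otsu_threshold(matrix(7, 5, 5)), "no contrast")
})

test_that("CSF extraction picks the highest-mean component above the size floor", {
  img <- matrix(0, 40, 60)
  img[5:14, 5:16] <- 150          # 120 px at mean 150
  img[25:32, 40:49] <- 200        # 80 px at mean 200
  fg <- img > 100
  m <- extract_csf_mask(img, fg)
  expect_equal(sum(m), 80)
  expect_true(all(img[m] == 200))

  # single qualifying component is returned as-is
  img2 <- matrix(0, 20, 20)
  img2[3:12, 3:8] <- 180          # 60 px
  m2 <- extract_csf_mask(img2, img2 > 0)
  expect_equal(sum(m2), 60)

  # a 30-pixel component is below the default 50-pixel floor
  img3 <- matrix(0, 20, 20)
  img3[3:8, 3:7] <- 180           # 30 px
  expect_error(extract_csf_mask(img3, img3 > 0),
               class = "cordseg_csf_not_found")
})

test_that("flood fill closes rings and leaks through open gaps", {
  ring <- annulus_mask(31, c(16, 16), 8, 12)
  filled <- flood_fill(ring)
  expect_identical(filled, disk_mask(31, c(16, 16), 12) |
                     ring)  # disk (ring plus interior)
  expect_true(all(ring[filled == FALSE] == FALSE))

  blob <- disk_mask(21, c(11, 11), 6)
  expect_identical(flood_fill(blob), blob)

  cring <- ring
  cring[16, 24:31] <- FALSE  # open a radial channel to the border
  expect_identical(flood_fill(cring), cring)
})

test_that("contrast enhancement truncates the sparse upper tail", {
  set.seed(11)
  x <- matrix(stats::runif(1000, 50, 60), 40, 25)
  x[1, 1] <- 5000
  e <- enhance_contrast(x)
  # one application clips the outlier to the 99.9% quantile and
  # stretches the body; the outlier's lead over the rest shrinks by
  # more than half, and repeated application collapses it entirely
  gap <- function(m) diff(utils::tail(sort(m), 2))
  expect_lt(gap(e), 0.5 * gap(x))
  e3 <- enhance_contrast(enhance_contrast(e))
  expect_lt(gap(e3), 0.01 * diff(range(e3)))
  expect_equal(max(e), max(x))  # range preserved by the rescale
  expect_true(all(diff(sort(e)) >= -1e-9))

  # fixed point: max equals the truncation quantile (heavy top mass)
  y <- matrix(c(stats::runif(980, 0, 1), rep(2, 20)), 20, 50)
  expect_identical(enhance_contrast(y), y)
  expect_error(enhance_contrast(matrix(3, 5, 5)), "no contrast")
})

test_that("disk erosion matches the exhaustive structuring-element oracle", {
  sq <- matrix(FALSE, 15, 15); sq[3:13, 3:13] <- TRUE
  expect_identical(erode_mask(sq, 3), brute_erode(sq, 3))
  set.seed(77)
  for (r in 1:3) {
    m <- matrix(stats::runif(400) > 0.35, 20, 20)
    expect_identical(erode_mask(m, r), brute_erode(m, r))
  }
  expect_identical(erode_mask(matrix(FALSE, 9, 9), 3), matrix(FALSE, 9, 9))
  tiny <- matrix(FALSE, 9, 9); tiny[4:6, 4:6] <- TRUE
  expect_equal(sum(erode_mask(tiny, 3)), 0)  # annihilated
})

test_that("mid-intensity classification recovers the cord exactly on separable classes", {
  hs <- hard_slice()
  cord_seed <- erode_mask(hs$cord, 3)
  csf_seed <- erode_mask(hs$csf, 3)
  domain <- hs$cord | hs$csf
  los <- losseff_segment(hs$slice, cord_seed, csf_seed, domain)
  expect_equal(los$threshold, 150)  # midpoint of the 100/200 class means
  expect_identical(los$mask, hs$cord)
  expect_error(losseff_segment(hs$slice, matrix(FALSE, 100, 100),
                               csf_seed, domain), "seed-empty")

  # invariance under affine intensity rescaling
  los2 <- losseff_segment(3.7 * hs$slice + 11, cord_seed, csf_seed, domain)
  expect_identical(los2$mask, los$mask)
  expect_equal(los2$threshold, 3.7 * 150 + 11)

  # blurred interface: area still within 5% of the analytic disk
  ph <- clean_straight_phantom()
  spec_blur <- phantom_spec(fov_mm = c(30, 30, 6), noise_snr = 0,
                            blur_sigma_mm = 0.45)
  phb <- generate_phantom(spec_blur, seed = 41)
  z <- 10
  sl <- phb$volume$data[, , z]
  truth <- phb$truth_mask[, , z]
  csf_ring <- annulus_mask(100, mask_com(truth), 4.6 / 0.3, 5.6 / 0.3)
  los3 <- losseff_segment(sl, erode_mask(truth, 3), csf_ring,
                          flood_fill(csf_ring) | truth)
  csa <- compute_csa(los3$mask, c(0.3, 0.3))
  expect_lt(abs(csa - pi * 16) / (pi * 16), 0.05)
})

test_that("slice segmentation succeeds cleanly, retries through sparse tails, and encodes failure", {
  ph <- clean_straight_phantom()
  s <- segment_slice(ph$volume$data[, , 25], c(0.3, 0.3))
  expect_s3_class(s, "slice_segmentation")
  expect_equal(s$status, "ok")
  expect_equal(s$enhancement_iterations, 0L)
  expect_false(any(s$m_sc & !s$m_f))               # m_sc subset of m_f
  expect_false(any(s$m_sc & s$m_csf))              # disjoint masks
  expect_equal(s$csa_mm2, sum(s$m_sc) * 0.09)

  # a sparse very bright tail captures the first Otsu cut; the
  # truncation loop collapses it and the CSF ring is then found
  set.seed(42)
  hs <- hard_slice()
  sl <- hs$slice + matrix(stats::rnorm(10000, 0, 2), 100, 100)
  hot <- sample(which(!(hs$cord | hs$csf)), 8)
  sl[hot] <- seq(2000, 3000, length.out = 8)
  s2 <- segment_slice(sl, c(0.3, 0.3))
  expect_equal(s2$status, "ok")
  expect_gte(s2$enhancement_iterations, 1L)
  expect_gt(dice(hs$cord, s2$m_sc), 0.97)

  # structureless noise never yields a cord; failure is a status
  set.seed(9)
  noise <- matrix(stats::runif(10000, 0, 100), 100, 100)
  s3 <- segment_slice(noise, c(0.3, 0.3))
  expect_equal(s3$status, "failed")
  expect_true(is.na(s3$csa_mm2))
})

test_that("repeated enhancement grows the Otsu foreground until the ring is found", {
  set.seed(13)
  hs <- hard_slice()
  sl <- hs$slice + matrix(stats::rnorm(10000, 0, 2), 100, 100)
  bg <- which(!(hs$cord | hs$csf))
  sl[sample(bg, 8)] <- stats::runif(8, 1500, 3000)
  frac <- numeric(0)
  work <- sl
  found <- FALSE
  for (k in 1:6) {
    fr <- mean(work > otsu_threshold(work))
    frac <- c(frac, fr)
    m <- tryCatch(extract_csf_mask(work, work > otsu_threshold(work)),
                  error = function(e) NULL)
    if (!is.null(m) && sum(m & hs$csf) > 0.5 * sum(hs$csf)) {
      found <- TRUE
      break
    }
    work <- enhance_contrast(work)
  }
  expect_true(found)
  expect_true(all(diff(frac) >= 0))
})

test_that("CSA arithmetic follows the pixel-count definition", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(compute_csa(m, c(0.3, 0.3)), 9.0)
  expect_equal(compute_csa(matrix(FALSE, 5, 5), c(0.3, 0.3)), 0)
  # multi-slice CSA is the mean of per-slice areas
  areas <- c(80, 80, 80, 85, 85)
  masks <- lapply(areas, function(a) {
    mm <- matrix(FALSE, 40, 40); mm[seq_len(a)] <- TRUE; mm
  })
  expect_equal(mean(vapply(masks, compute_csa, 0, spacing = c(1, 1))), 82.0)
})

test_that("segmentation is robust to seed perturbation", {
  hs <- hard_slice()
  domain <- hs$cord | hs$csf
  set.seed(55)
  csas <- replicate(10, {
    # random subsets amounting to 10-30% of the true region areas
    ks <- sample(which(hs$cord), round(stats::runif(1, 0.1, 0.3) * sum(hs$cord)))
    kc <- sample(which(hs$csf), round(stats::runif(1, 0.1, 0.3) * sum(hs$csf)))
    cs <- matrix(FALSE, 100, 100); cs[ks] <- TRUE
    cf <- matrix(FALSE, 100, 100); cf[kc] <- TRUE
    compute_csa(losseff_segment(hs$slice, cs, cf, domain)$mask, c(0.3, 0.3))
  })
  expect_lt((max(csas) - min(csas)) / mean(csas), 0.02)
})

test_that("per-slice results export as a tidy table", {
  ph <- clean_straight_phantom()
  small <- cord_volume(ph$volume$data[, , 1:6], ph$volume$spacing)
  slices <- segment_cord(small, correct = FALSE)
  tab <- csa_table(slices)
  expect_named(tab, c("slice_index", "status", "otsu_threshold",
                      "losseff_threshold", "enhancement_iterations",
                      "csa_mm2"))
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$status == "ok"))
})
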