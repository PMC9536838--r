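test_that("colocalization masking excludes non-mitochondrial signal", {
  # all-zero mitochondrial channel: nothing colocalizes
  a <- array(runif(4 * 8 * 8), c(4, 8, 8))
  b <- array(0, c(4, 8, 8))
  expect_false(any(colocalization_mask(a, b)))
  expect_error(colocalization_mask(a, array(0, c(4, 8, 9))), "dimensions")
  # synthetic stack: out-of-mask foci are dropped by the mask
  set.seed(21)
  stk <- generate_foci_image(n_foci = 20, snr = 20, frac_outside = 0.25)
  m <- colocalization_mask(stk$channel_a, stk$channel_b)
  fc <- count_foci_3d(stk$channel_a, m)
  truth_in <- stk$truth$foci[stk$truth$foci$in_mask, ]
  expect_equal(fc$n_foci, nrow(truth_in))
  expect_equal(unname(match_foci(truth_in, fc$coordinates)["recovered"]), 1)
})

test_that("3D maxima counting recovers well-separated foci exactly", {
  # empty image
  empty <- array(0, c(6, 16, 16))
  expect_equal(count_foci_3d(empty, array(TRUE, dim(empty)))$n_foci, 0)
  expect_equal(count_foci_3d(empty, array(FALSE, dim(empty)))$n_foci, 0)
  # 25 foci at high SNR
  set.seed(22)
  stk <- generate_foci_image(n_foci = 25, snr = 50)
  fc <- count_foci_3d(stk$channel_a,
                      colocalization_mask(stk$channel_a, stk$channel_b))
  expect_equal(fc$n_foci, 25)
})

test_that("foci recovery >= 95% with false positives <= 5% across an SNR
           sweep", {
  recs <- c(); fps <- c()
  for (snr in c(5, 8, 12, 20)) {
    for (s in 1:3) {
      set.seed(1000 * snr + s)
      stk <- generate_foci_image(n_foci = 25, snr = snr)
      fc <- count_foci_3d(stk$channel_a,
                          colocalization_mask(stk$channel_a, stk$channel_b))
      m <- match_foci(stk$truth$foci, fc$coordinates)
      recs <- c(recs, m["recovered"]); fps <- c(fps, m["fp"])
    }
  }
  expect_gte(mean(recs), 0.95)
  expect_lte(mean(fps), 0.05)
})

test_that("foci counting is invariant to intensity scaling and assigns
           per-cell tallies from supplied labels", {
  set.seed(23)
  stk <- generate_foci_image(n_foci = 15, snr = 30)
  m <- colocalization_mask(stk$channel_a, stk$channel_b)
  f1 <- count_foci_3d(stk$channel_a, m)
  f2 <- count_foci_3d(stk$channel_a * 7.3, m)
  expect_equal(f1$n_foci, f2$n_foci)
  expect_equal(f1$coordinates[, c("z", "y", "x")],
               f2$coordinates[, c("z", "y", "x")])
  # split the stack into two labeled "cells" along y
  labs <- array(1L, dim(stk$channel_a))
  labs[, seq_len(dim(labs)[2] / 2), ] <- 2L
  fc <- count_foci_3d(stk$channel_a, m, cell_labels = labs)
  expect_equal(sum(fc$per_cell), fc$n_foci)
})

test_that("Manders coefficient respects its exact fixtures and bounds", {
  d <- c(4, 8, 8)
  b <- array(0, d); b[, , 1:4] <- 100       # B-positive half
  a_in <- array(0, d); a_in[, , 1:4] <- 5   # A entirely inside B
  expect_equal(manders_coefficient(a_in, b, threshold_b = 50), 1)
  a_out <- array(0, d); a_out[, , 5:8] <- 5 # disjoint
  expect_equal(manders_coefficient(a_out, b, threshold_b = 50), 0)
  # exactly half of A's intensity overlaps B
  a_half <- array(0, d)
  a_half[, , 4] <- 10; a_half[, , 5] <- 10
  expect_equal(manders_coefficient(a_half, b, threshold_b = 50), 0.5)
  expect_error(manders_coefficient(array(0, d), b, threshold_b = 50),
               "no intensity")
  set.seed(24)
  r <- array(runif(prod(d)), d)
  m <- manders_coefficient(r, b)
  expect_true(m >= 0 && m <= 1)
  expect_equal(manders_coefficient(b, b), 1)
})

test_that("acidification ratios report green/red means and cancel uniform
           rescaling", {
  set.seed(25)
  stk <- generate_acidified_image(network_ratio = 1, acidified_ratio = 0.25)
  debris <- acidification_ratio(stk$channel_a, stk$channel_b,
                                stk$truth$mask, "debris")
  body <- acidification_ratio(stk$channel_a, stk$channel_b,
                              stk$truth$network_mask & !stk$truth$mask,
                              "cell_body")
  expect_equal(debris$ratio, 0.25, tolerance = 0.05)
  expect_equal(body$ratio, 1, tolerance = 0.05)
  scaled <- acidification_ratio(stk$channel_a * 3.7, stk$channel_b * 3.7,
                                stk$truth$mask, "debris")
  expect_equal(scaled$ratio, debris$ratio)
  # identical channels give ratio 1 exactly
  same <- acidification_ratio(stk$channel_b, stk$channel_b,
                              stk$truth$network_mask, "roi")
  expect_equal(same$ratio, 1)
  expect_error(acidification_ratio(stk$channel_a, stk$channel_b,
                                   array(FALSE, dim(stk$channel_a))),
               "empty region")
})

test_that("the twofold rule flags deep acidification and spares shallow or
           boundary regions", {
  set.seed(26)
  deep <- generate_acidified_image(network_ratio = 1, acidified_ratio = 0.25)
  det <- detect_acidified_regions(deep$channel_a, deep$channel_b,
                                  deep$truth$network_mask)
  expect_true(det$flag)
  expect_equal(det$n_regions, 1)
  # the detected region sits inside the truth region (smoothing trims the
  # region rim, so recall is partial but precision should be high)
  expect_gt(sum(det$labels > 0 & deep$truth$mask) /
              max(1, sum(det$labels > 0)), 0.8)
  expect_gt(sum(det$labels > 0 & deep$truth$mask) / sum(deep$truth$mask),
            0.25)
  shallow <- generate_acidified_image(network_ratio = 1,
                                      acidified_ratio = 1 / 1.5)
  expect_false(detect_acidified_regions(shallow$channel_a,
                                        shallow$channel_b,
                                        shallow$truth$network_mask)$flag)
  # exactly at the boundary the reference includes the region itself, so
  # the region falls just short of the threshold and is not flagged
  boundary <- generate_acidified_image(network_ratio = 1,
                                       acidified_ratio = 0.5,
                                       noise_sd = 0)
  expect_false(detect_acidified_regions(boundary$channel_a,
                                        boundary$channel_b,
                                        boundary$truth$network_mask)$flag)
  none <- generate_acidified_image(n_regions = 0)
  expect_false(detect_acidified_regions(none$channel_a, none$channel_b,
                                        none$truth$network_mask)$flag)
  expect_error(detect_acidified_regions(deep$channel_a, deep$channel_b,
                                        array(FALSE, dim(deep$channel_a))),
               "degenerate")
})

test_that("cell-body fractions count mitochondria-positive voxels", {
  d <- c(4, 8, 8)
  mito <- array(0, d)
  mito[, 1:4, ] <- 100   # positive half
  all_roi <- array(TRUE, d)
  expect_equal(cell_body_fraction(mito, all_roi, threshold = 50), 1)
  half_roi <- array(FALSE, d); half_roi[, 1:2, ] <- TRUE
  expect_equal(cell_body_fraction(mito, half_roi, threshold = 50), 0.5)
  expect_equal(cell_body_fraction(mito, array(FALSE, d), threshold = 50), 0)
  expect_error(cell_body_fraction(array(0, d), all_roi, threshold = 50),
               "no mitochondria")
})

test_that("volume formulas match their closed forms and a Monte-Carlo
           voxel-integration oracle", {
  expect_equal(ellipsoid_volume(1, 1, 1), 4 / 3 * pi)
  expect_equal(sphere_volume(2), 4 / 3 * pi)
  expect_equal(ellipsoid_volume(3, 3, 3), sphere_volume(6))
  expect_equal(ellipsoid_volume(30, 15, 15), 28274.3, tolerance = 1e-5)
  expect_equal(sphere_volume(8.2), 288.696, tolerance = 1e-5)
  expect_equal(sphere_volume(4), 8 * sphere_volume(2))
  expect_error(ellipsoid_volume(0, 1, 1), "radii")
  expect_error(sphere_volume(-1), "diameter")
  # Monte-Carlo integration oracle: fraction of a bounding box inside
  set.seed(27)
  a <- 3; b <- 2; c_ <- 1.5
  n <- 4e5
  x <- runif(n, -a, a); y <- runif(n, -b, b); z <- runif(n, -c_, c_)
  inside <- (x / a)^2 + (y / b)^2 + (z / c_)^2 <= 1
  mc_vol <- mean(inside) * 8 * a * b * c_
  expect_equal(ellipsoid_volume(a, b, c_), mc_vol, tolerance = 0.005)
})

test_that("image stacks survive a TIFF round trip with truth sidecars", {
  set.seed(28)
  stk <- generate_foci_image(n_foci = 8, snr = 30, dim3 = c(8, 32, 32))
  dir <- withr::local_tempdir()
  base <- file.path(dir, "stack")
  write_image_stack(stk, base)
  expect_true(file.exists(paste0(base, "_a.tif")))
  expect_true(file.exists(paste0(base, "_truth_foci.csv")))
  back <- read_image_stack(base)
  expect_equal(dim(back$channel_a), dim(stk$channel_a))
  # 16-bit quantization: relative error well below measurement noise
  expect_lt(max(abs(back$channel_a - stk$channel_a)) /
              max(stk$channel_a), 1e-4)
  expect_equal(back$truth$foci$z, stk$truth$foci$z)
  expect_equal(back$voxel_size, stk$voxel_size)
  # counting on the re-read stack gives the same answer
  fc0 <- count_foci_3d(stk$channel_a,
                       colocalization_mask(stk$channel_a, stk$channel_b))
  fc1 <- count_foci_3d(back$channel_a,
                       colocalization_mask(back$channel_a, back$channel_b))
  expect_equal(fc1$n_foci, fc0$n_foci)
})

test_that("stack constructors validate dimensions, finiteness and truth
           coordinates", {
  a <- array(1, c(2, 4, 4))
  expect_error(image_stack(a, array(1, c(2, 4, 5))), "dimensions")
  expect_error(image_stack(a, array(-1, c(2, 4, 4))), "finite")
  expect_error(image_stack(a, a, truth = list(
    foci = data.frame(z = 3, y = 1, x = 1))), "outside")
})
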