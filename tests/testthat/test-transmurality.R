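# one shared noise-free phantom pipeline for the profile tests
local({
  fib <<- tiny_fiber(nz = 6)
  dwi <- synthesize_dwi(fib)
  eigs <- eigendecompose(fit_tensor_loglinear(dwi, mask = fib$mask),
                         frame = fib$frame)
  ha <<- helix_angle(primary_orientation(eigs), fib$frame)
  tdm <<- transmural_depth(fib$mask, fib$frame)
  prof <<- extract_profiles(ha, tdm, fib$frame)
})

test_that("profile extraction yields 20 rays per slice at 18-degree
          spacing on a full annulus", {
  s <- prof$samples
  per_slice <- table(unique(s[, c("slice", "ray")])$slice)
  expect_true(all(per_slice == 20))
  az <- sort(unique(s$azimuth_deg))
  expect_equal(az, seq(0, 342, by = 18))
  expect_equal(prof$dropped, 0)
  # every sample lies on the prescribed ramp HA = 60 - 1.2 TD, up to
  # nearest-voxel TD quantisation (a voxel of the 1200 um wall is
  # ~8.3 %TD, i.e. ~10 deg of HA) plus boundary-location jitter
  expect_lt(max(abs(s$ha - (60 - 1.2 * s$td))), 11)
  expect_lt(median(abs(s$ha - (60 - 1.2 * s$td))), 3)
})

test_that("profile slope fitting matches closed-form least squares", {
  # exact line
  td <- c(10, 30, 50, 70, 90)
  f <- fit_profile_slope(data.frame(td = td, ha = 60 - 1.2 * td))
  expect_equal(f$slope, -1.2, tolerance = 1e-12)
  expect_equal(f$intercept, 60, tolerance = 1e-10)
  # constant HA
  expect_equal(fit_profile_slope(data.frame(td = td, ha = rep(5, 5)))$slope,
               0)
  # three-point closed form: slope = -0.9 (plus one repeated point to meet
  # the minimum sample count)
  f3 <- fit_profile_slope(data.frame(td = c(0, 50, 100, 100),
                                     ha = c(50, 0, -40, -40)))
  td4 <- c(0, 50, 100, 100); ha4 <- c(50, 0, -40, -40)
  s_manual <- sum((td4 - mean(td4)) * (ha4 - mean(ha4))) /
    sum((td4 - mean(td4))^2)
  expect_equal(f3$slope, s_manual, tolerance = 1e-12)
  f3b <- fit_profile_slope(data.frame(td = c(0, 50, 100),
                                      ha = c(50, 0, -40)))
  expect_true(is.na(f3b$slope))  # fewer than 4 samples
  expect_match(f3b$rejected, "fewer")
  # degenerate TD spread rejected
  fd <- fit_profile_slope(data.frame(td = c(40, 42, 44, 46),
                                     ha = c(1, 2, 3, 4)))
  expect_true(is.na(fd$slope))
  expect_match(fd$rejected, "spread")
})

test_that("global HAT is the mean of accepted slopes", {
  fits <- data.frame(slice = 1, ray = 1:4, azimuth_deg = c(0, 90, 180, 270),
                     slope = c(-1.0, -1.4, -1.0, -1.4), intercept = 0,
                     n = 8, region = NA_integer_, infarct = FALSE)
  g <- global_hat(fits)
  expect_equal(g$global_signed, -1.2)
  expect_equal(g$global_abs, 1.2)
  fits$slope <- -1.2
  expect_equal(global_hat(fits)$global_signed, -1.2)
  expect_error(global_hat(fits[0, ]), "no accepted")
  # phantom recovery: noise-free ramp within 0.05 deg/%TD
  g2 <- global_hat(prof)
  expect_lt(abs(g2$global_signed - (-1.2)), 0.05)
})

test_that("AHA-16 binning is a partition with segment means near the
          global value on a uniform phantom", {
  fits <- fit_profiles(prof)
  seg <- aha16_bin(fits)
  expect_equal(seg$segment, 1:16)
  expect_equal(sum(seg$n), nrow(fits[is.finite(fits$slope), ]))
  g <- global_hat(fits)$global_signed
  expect_lt(max(abs(seg$hat - g), na.rm = TRUE), 0.02)
  expect_false(any(seg$omitted))
  # 20 rays fall into 6 basal segments, each ray exactly once
  basal <- fits[fits$slice <= 2, ]
  segidx <- floor((basal$azimuth_deg %% 360) / 60) + 1
  expect_equal(sort(unique(segidx)), 1:6)
  expect_equal(length(segidx), nrow(basal))
})

test_that("lesion-crossing segments are omitted without touching others", {
  les <- lesion_spec(azimuth = 0, halfwidth = 25, ring_width = 10,
                     ha_flatten = 0.3)
  fibL <- tiny_fiber(nz = 6, lesion = les)
  dwiL <- synthesize_dwi(fibL)
  dtiL <- analyze_dwi_path(dwiL)
  fitsL <- dtiL$hat$fits
  segL <- aha16_bin(fitsL)
  # only segments overlapping the lesion sector (around azimuth 0) omitted
  expect_true(any(segL$omitted))
  omitted_az <- segL$segment[segL$omitted]
  # basal/mid segments covering azimuth 0-60 and 300-360 contain the core
  expect_true(all(segL$omitted[c(2:5, 8:11)] == FALSE))
  # removing infarct profiles does not change remote-segment values
  fits_no_inf <- fitsL[!(fitsL$infarct %in% TRUE), ]
  seg2 <- aha16_bin(fits_no_inf)
  keep <- !segL$omitted & !is.na(segL$hat)
  expect_equal(segL$hat[keep], seg2$hat[keep])
})

test_that("radial segmentation spans 100 bins whose weighted mean equals
          global HAT", {
  fits <- fit_profiles(prof)
  rad <- radial_segment_bin(fits)
  expect_equal(nrow(rad), 100)
  expect_equal(rad$azimuth_mid[2] - rad$azimuth_mid[1], 3.6)
  filled <- !is.na(rad$hat)
  g <- global_hat(fits)$global_signed
  expect_equal(sum(rad$hat[filled] * rad$n[filled]) / sum(rad$n[filled]),
               g, tolerance = 1e-9)
  # uniform phantom: tiny variance across bins
  expect_lt(var(rad$hat[filled]), 0.01)
})

test_that("lesion bins show the flattened HAT", {
  les <- lesion_spec(azimuth = 180, halfwidth = 30, ring_width = 0,
                     ha_flatten = 0.4)
  fibL <- tiny_fiber(nz = 6, lesion = les)
  eigsL <- eigendecompose(fit_tensor_loglinear(synthesize_dwi(fibL),
                                               mask = fibL$mask),
                          frame = fibL$frame)
  haL <- helix_angle(primary_orientation(eigsL), fibL$frame)
  tdL <- transmural_depth(fibL$mask, fibL$frame)
  profL <- extract_profiles(haL, tdL, fibL$frame,
                            region = fibL$truth$labels)
  rad <- radial_segment_bin(profL, exclude_infarct = FALSE)
  core <- abs(cardiohelix:::wrap_angle_diff(rad$azimuth_mid, 180)) < 22
  remote <- abs(cardiohelix:::wrap_angle_diff(rad$azimuth_mid, 0)) < 60
  expect_equal(mean(rad$hat[core], na.rm = TRUE),
               0.4 * mean(rad$hat[remote], na.rm = TRUE),
               tolerance = 0.15)
})

test_that("MD zoning follows the printed thresholds", {
  md <- array(NA_real_, c(3, 1, 1))
  md[1:3] <- c(1.2, 1.0, 0.5)
  lab <- md_region_masks(md)
  expect_equal(as.integer(lab[1:3]), c(3L, 2L, 1L))  # infarct, peri, remote
  expect_equal(as.integer(md_region_masks(array(1.12, c(1, 1, 1)))), 2L)
  expect_warning(md_region_masks(array(c(0.5, 8), c(2, 1, 1))), "units")
})

test_that("peri-infarct HAT magnitude falls below remote on lesion
          phantoms across seeded noisy replicates", {
  wins <- 0L
  for (r in 1:5) {
    les <- lesion_spec(azimuth = 90, halfwidth = 30, ring_width = 14,
                       ha_flatten = 0.4)
    spec <- tiny_spec(lesion = les,
                      noise = list(type = "rician", sigma = 0.02),
                      seed = 400 + r)
    fibL <- make_fiber_field(make_lv_geometry(spec))
    dti <- analyze_dwi_path(synthesize_dwi(fibL))
    rh <- dti$region_hat
    peri <- rh$hat[rh$region == "peri_infarct"]
    remote <- rh$hat[rh$region == "remote"]
    if (is.finite(peri) && is.finite(remote) && abs(peri) < abs(remote)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 4L)
})
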