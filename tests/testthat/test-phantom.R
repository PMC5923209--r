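test_that("annular geometry matches its analytic area and centre", {
  spec <- phantom_spec(dim = c(64, 64, 3), spacing = c(1, 1, 1),
                       r_endo = 10, r_epi = 20, center = c(32, 32))
  geom <- make_lv_geometry(spec)
  per_slice <- sum(geom$myocardium[, , 1])
  expect_lt(abs(per_slice - pi * (20^2 - 10^2)) / (pi * 300), 0.02)
  w <- which(geom$myocardium[, , 2], arr.ind = TRUE)
  centroid <- unname(colMeans(w - 0.5))
  expect_equal(centroid, c(32, 32), tolerance = 0.1 / 32)
  # blood pool is the enclosed disc
  wp <- which(geom$blood_pool[, , 1], arr.ind = TRUE)
  rp <- sqrt(rowSums(sweep(wp - 0.5, 2, c(32, 32))^2))
  expect_true(all(rp < 10))
})

test_that("degenerate or invalid specs are rejected", {
  expect_error(phantom_spec(r_endo = 1500, r_epi = 1500), "degenerate")
  expect_error(phantom_spec(r_endo = 2000, r_epi = 1500), "degenerate")
  expect_error(phantom_spec(ha_endo = 95), "90")
  expect_error(phantom_spec(lambda = c(0.5, 0.7, 0.3)), "eigenvalues")
  expect_error(phantom_spec(lambda = c(0.7, 0.5, 0)), "eigenvalues")
})

test_that("fiber field ramps linearly and honours special cases", {
  # pure circumferential field
  fib0 <- tiny_fiber(ha_endo = 0, ha_epi = 0)
  expect_equal(fib0$truth$global_hat, 0)
  idx <- which(fib0$mask)
  expect_true(all(abs(fib0$orientation[, , , 3][idx]) < 1e-12))
  # +60 -> -60 ramp
  fib <- tiny_fiber()
  expect_equal(fib$truth$global_hat, -1.2)
  expect_equal(fib$truth$ha[which(fib$mask)],
               60 - 1.2 * fib$truth$td[which(fib$mask)])
  # fibers always unit and in the tangent plane (perpendicular to radial)
  ijk <- arrayInd(idx, dim(fib0$mask))
  f <- cbind(fib$orientation[, , , 1][idx], fib$orientation[, , , 2][idx],
             fib$orientation[, , , 3][idx])
  expect_equal(rowSums(f^2), rep(1, nrow(f)), tolerance = 1e-12)
  basis <- frame_basis(fib$frame, arrayInd(which(fib$mask), dim(fib$mask)))
  expect_lt(max(abs(rowSums(f * basis$r))), 1e-12)
})

test_that("lesion flattening zeroes HA inside and leaves outside unchanged", {
  les <- lesion_spec(azimuth = 0, halfwidth = 30, ring_width = 10,
                     ha_flatten = 0)
  fib <- tiny_fiber(lesion = les)
  ref <- tiny_fiber()
  lab <- fib$truth$labels
  expect_true(all(fib$truth$ha[lab == 3L] == 0))
  outside <- lab == 1L
  expect_equal(fib$truth$ha[outside], ref$truth$ha[outside])
  # labels partition the myocardium
  expect_true(all(lab[fib$mask] %in% 1:3))
  expect_true(all(lab[!fib$mask] == 0L))
})

test_that("DWI synthesis follows the single-tensor signal model", {
  fib <- tiny_fiber()
  dwi <- synthesize_dwi(fib)
  b0 <- dwi$data[, , , dwi$protocol$bvals == 0]
  expect_equal(b0[fib$mask], rep(1, sum(fib$mask)))
  # isotropic eigenvalues: every DW volume is S0 exp(-b d)
  spec_iso <- phantom_spec(dim = c(48, 48, 3), spacing = c(100, 100, 100),
                           r_endo = 600, r_epi = 1800,
                           lambda = c(0.9, 0.9, 0.9))
  fib_iso <- make_fiber_field(make_lv_geometry(spec_iso))
  dwi_iso <- synthesize_dwi(fib_iso)
  for (v in which(dwi_iso$protocol$bvals > 0)[c(1, 7)]) {
    expect_equal(dwi_iso$data[, , , v][fib_iso$mask],
                 rep(exp(-1000 * 1e-3 * 0.9), sum(fib_iso$mask)),
                 tolerance = 1e-12)
  }
  # fewer than 6 unique axes rejected
  bad <- dwi_protocol(c(0, rep(1000, 6)),
                      rbind(c(0, 0, 0), diag(3), -diag(3)))
  expect_error(synthesize_dwi(fib, bad), "underdetermined")
})

test_that("noise-free synthesis refits to the generating tensor exactly", {
  fib <- tiny_fiber(nz = 3)
  dwi <- synthesize_dwi(fib)
  tf <- fit_tensor_loglinear(dwi, mask = fib$mask)
  eigs <- eigendecompose(tf, frame = fib$frame)
  # eigenvalues recover the spec values
  expect_equal(max(abs(eigs$values[, 1] - 1.3)), 0, tolerance = 1e-8)
  expect_equal(max(abs(eigs$values[, 3] - 0.5)), 0, tolerance = 1e-8)
  # e1 recovers the fiber (axially)
  f <- cbind(fib$orientation[, , , 1][tf$idx],
             fib$orientation[, , , 2][tf$idx],
             fib$orientation[, , , 3][tf$idx])
  dots <- abs(rowSums(f * eigs$vectors[, 1:3]))
  expect_gt(min(dots), 1 - 1e-9)
})

test_that("Rician noise produces a Rayleigh background of mean sigma*sqrt(pi/2)", {
  spec <- phantom_spec(dim = c(64, 64, 8), r_endo = 900, r_epi = 1500,
                       noise = list(type = "rician", sigma = 0.05),
                       seed = 7)
  fib <- make_fiber_field(make_lv_geometry(spec))
  dwi <- synthesize_dwi(fib)
  bg <- !fib$mask & !fib$blood_pool
  expect_gt(sum(bg), 1e4)
  b0 <- dwi$data[, , , 1]
  expect_equal(mean(b0[bg]), 0.05 * sqrt(pi / 2), tolerance = 0.05)
})

test_that("synthesis is bit-reproducible for a fixed seed", {
  spec <- tiny_spec(noise = list(type = "rician", sigma = 0.03), seed = 11)
  fib <- make_fiber_field(make_lv_geometry(spec))
  d1 <- synthesize_dwi(fib)
  d2 <- synthesize_dwi(fib)
  expect_identical(d1$data, d2$data)
  o1 <- synthesize_optical(fib, optical_texture_params(wavelength = 400))
  o2 <- synthesize_optical(fib, optical_texture_params(wavelength = 400))
  expect_identical(o1$data, o2$data)
})

test_that("optical synthesis validates wavelength and handles zero contrast", {
  fib <- tiny_fiber(nz = 3)
  expect_error(synthesize_optical(fib,
                                  optical_texture_params(wavelength = 200)),
               "aliasing")
  flat <- synthesize_optical(fib, optical_texture_params(wavelength = 400,
                                                         contrast = 0,
                                                         radial_contrast = 0,
                                                         noise_sigma = 0,
                                                         background = 0.5))
  expect_equal(sd(flat$data), 0)  # constant image
  grads <- sobel_gradients(flat$data)
  st <- structure_tensor_orientation(grads, window_sigma = 2,
                                     spacing = fib$spec$spacing,
                                     mask = fib$mask)
  # no texture: orientation undefined everywhere
  expect_length(st$orientation$idx, 0)
})

test_that("optical texture round-trips a circumferential field through the
          structure tensor", {
  spec <- phantom_spec(dim = c(96, 96, 12), spacing = c(50, 50, 50),
                       r_endo = 600, r_epi = 1800, ha_endo = 0, ha_epi = 0,
                       seed = 3)
  fib <- make_fiber_field(make_lv_geometry(spec))
  # long fiber-aligned smearing: circumferential fibers are closed circles
  vol <- synthesize_optical(fib, optical_texture_params(wavelength = 300,
                                                        lic_length = 2400,
                                                        noise_sigma = 0))
  grads <- sobel_gradients(vol$data)
  st <- structure_tensor_orientation(grads, window_sigma = 4,
                                     spacing = spec$spacing,
                                     mask = fib$mask)
  ha <- helix_angle(st$orientation, fib$frame)
  idx <- which(fib$mask & !is.na(ha))
  # away from the wall boundaries
  td <- fib$truth$td[idx]
  interior <- td > 15 & td < 85
  expect_gt(mean(abs(ha[idx][interior]) <= 2), 0.95)
})
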