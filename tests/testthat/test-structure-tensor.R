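test_that("Sobel gradients reproduce ramps and vanish on constants", {
  n <- 12
  ramp <- array(rep(2.5 * seq_len(n), n * n), c(n, n, n))  # I = a x
  g <- sobel_gradients(ramp)
  core <- 2:(n - 1)
  expect_equal(g$fx[core, core, core],
               array(2.5, c(n - 2, n - 2, n - 2)), tolerance = 1e-12)
  expect_equal(max(abs(g$fy[core, core, core])), 0, tolerance = 1e-12)
  expect_equal(max(abs(g$fz[core, core, core])), 0, tolerance = 1e-12)
  const <- array(3, c(n, n, n))
  gc <- sobel_gradients(const)
  expect_equal(max(abs(gc$fx)), 0)
  # 45-degree ramp I = a (x + y)
  r45 <- outer(seq_len(n), seq_len(n), `+`)
  r45 <- array(rep(r45, n), c(n, n, n))
  g45 <- sobel_gradients(r45)
  expect_lt(max(abs(g45$fx[core, core, core] - g45$fy[core, core, core])),
            1e-10)
  expect_error(sobel_gradients(array(1, c(2, 5, 5))), "too small")
  expect_true(all(g$boundary[1, , ]))
})

test_that("structure tensor recovers stripe orientations within a degree", {
  for (ang in c(0, 30)) {
    img <- stripe_image(96, angle_deg = ang, wavelength = 8)
    st <- structure_tensor_orientation(sobel_gradients(img),
                                       window_sigma = 3)
    core <- st$theta[20:76, 20:76]
    err <- abs(cardiohelix:::wrap_angle_diff(2 * core, 2 * ang)) / 2
    expect_lt(median(err, na.rm = TRUE), 1)
  }
  # constant region: coherence 0, orientation undefined
  stc <- structure_tensor_orientation(sobel_gradients(matrix(1, 48, 48)),
                                      window_sigma = 3)
  expect_equal(max(stc$coherence), 0)
  expect_length(stc$idx, 0)
  expect_error(structure_tensor_orientation(sobel_gradients(stripe_image()),
                                            window_sigma = 0),
               "positive")
})

test_that("orientation is antipodal and equivariant under 90-degree rotation", {
  img <- stripe_image(96, angle_deg = 20, wavelength = 8)
  st <- structure_tensor_orientation(sobel_gradients(img), window_sigma = 3)
  # negating the image leaves the axial orientation unchanged
  st_neg <- structure_tensor_orientation(sobel_gradients(-img),
                                         window_sigma = 3)
  expect_equal(st$theta, st_neg$theta, tolerance = 1e-9)
  # rotating the image by 90 degrees rotates the orientation by 90 (mod 180)
  st_rot <- structure_tensor_orientation(sobel_gradients(t(img)[, 96:1]),
                                         window_sigma = 3)
  core <- 20:76
  d <- cardiohelix:::wrap_angle_diff(2 * st_rot$theta[core, core],
                                     2 * (st$theta[core, core] + 90)) / 2
  expect_lt(max(abs(d), na.rm = TRUE), 1.5)
})

test_that("2D analysis of a z-invariant texture agrees with 3D", {
  vol <- stripe_volume(64, 9, angle_deg = 30, wavelength = 8)
  st3 <- structure_tensor_orientation(sobel_gradients(vol), window_sigma = 3)
  th3 <- expand_theta <- array(NA_real_, dim(vol))
  th3[st3$orientation$idx] <-
    atan2(st3$orientation$vectors[, 2], st3$orientation$vectors[, 1]) * 180 / pi
  th3 <- cardiohelix:::wrap_axial(th3)
  st2 <- structure_tensor_orientation(sobel_gradients(vol[, , 5]),
                                      window_sigma = 3)
  core <- 16:48
  d <- cardiohelix:::wrap_angle_diff(2 * th3[core, core, 5],
                                     2 * st2$theta[core, core]) / 2
  expect_lt(median(abs(d), na.rm = TRUE), 2)
})

test_that("in-plane angle Theta uses the u/v interventricular frame", {
  fake <- list(idx = 1:3, dim = c(3, 1),
               vectors = rbind(c(0, 1), c(1, 0), c(sqrt(.5), sqrt(.5))))
  # v along +x (lv to rv), u along +y
  th <- inplane_angle(fake, lv_center = c(0, 0), rv_center = c(10, 0))
  expect_equal(th[1], 0)    # parallel to u
  expect_equal(th[2], 90)   # parallel to v
  expect_equal(th[3], 45, tolerance = 1e-9)
  expect_error(inplane_angle(fake, c(1, 1), c(1, 1)), "coincide")
})

test_that("stripe filter removes stripes, preserves texture, and is exact
          at strength zero", {
  n <- 96
  # oblique texture and axis-aligned stripes on exact frequency bins
  texture <- outer(seq_len(n), seq_len(n), function(i, j)
    cos(2 * pi * (10 * i + 12 * j) / n))
  stripes <- matrix(0.8 * cos(2 * pi * 16 * seq_len(n) / n),
                    n, n, byrow = TRUE)  # vary along y, constant along x
  noisy <- texture + stripes
  filt <- remove_stripes(noisy, artifact_axis = 1, strength = 1)
  # stripe power: project onto the stripe pattern
  stripe_amp <- function(img) mean(img * stripes) / mean(stripes^2)
  expect_gt(abs(stripe_amp(noisy)), 10 * abs(stripe_amp(filt)))
  # texture band: correlation with the clean texture stays high
  expect_gt(sum(filt * texture) / sum(texture^2), 0.9)
  # strength 0 is a bit-exact no-op
  expect_identical(remove_stripes(noisy, 1, strength = 0), noisy)
  # pure stripe image: residual RMS < 10%
  resid <- remove_stripes(stripes, artifact_axis = 1, strength = 1)
  expect_lt(sqrt(mean(resid^2)), 0.1 * sqrt(mean(stripes^2)))
  # artifact-free oblique texture passes through nearly unchanged
  passed <- remove_stripes(texture, artifact_axis = 1, strength = 1)
  expect_lt(sqrt(mean((passed - texture)^2)), 0.01 * sqrt(mean(texture^2)))
})

test_that("mirror-pair identity yields ICC 1 and zero bias over 20 radial
          segments", {
  # two identical synthetic sections analysed independently
  spec <- phantom_spec(dim = c(96, 96, 1), spacing = c(50, 50, 50),
                       r_endo = 600, r_epi = 1800, ha_endo = 0, ha_epi = 0,
                       seed = 12)
  fib <- make_fiber_field(make_lv_geometry(spec))
  vol <- synthesize_optical(fib, optical_texture_params(wavelength = 300,
                                                        noise_sigma = 0))
  analyse <- function(img) {
    st <- structure_tensor_orientation(sobel_gradients(img),
                                       window_sigma = 3)
    th <- inplane_angle(st, lv_center = spec$center / spec$spacing[1:2],
                        rv_center = spec$center / spec$spacing[1:2] +
                          c(60, 0))
    th[!fib$mask[, , 1]] <- NA
    # mean Theta over 20 radial segments
    idx <- which(fib$mask[, , 1] & !is.na(th))
    ij <- arrayInd(idx, dim(th))
    az <- atan2(ij[, 2] - spec$center[2] / 50, ij[, 1] - spec$center[1] / 50)
    seg <- floor((az %% (2 * pi)) / (2 * pi / 20)) + 1
    tapply(th[idx], seg, mean)
  }
  a <- analyse(vol$data[, , 1])
  b <- analyse(vol$data[, , 1])
  expect_length(a, 20)
  expect_equal(unname(icc(a, b)$icc), 1)
  expect_equal(bland_altman(a, b)$bias, 0)
  expect_equal(unname(bland_altman(a, b)$loa), c(0, 0))
})
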