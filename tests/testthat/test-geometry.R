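test_that("threshold segmentation keeps the annulus and finds the pool", {
  spec <- phantom_spec(dim = c(48, 48, 4), spacing = c(1, 1, 1),
                       r_endo = 8, r_epi = 18, center = c(24, 24))
  geom <- make_lv_geometry(spec)
  vol <- array(0, spec$dim)
  vol[geom$myocardium] <- 100
  seg <- myocardium_mask(vol, 50)
  expect_identical(seg$myocardium, geom$myocardium)
  expect_identical(seg$blood_pool, geom$blood_pool)
  expect_error(myocardium_mask(vol, 101), "empty")
  # a disconnected speck is discarded
  vol2 <- vol
  vol2[2, 2, 1] <- 100
  seg2 <- myocardium_mask(vol2, 50)
  expect_identical(seg2$myocardium, geom$myocardium)
})

test_that("frame centres, basis orthogonality and tangent direction", {
  spec <- tiny_spec()
  geom <- make_lv_geometry(spec)
  frame <- build_frame(geom$myocardium, geom$blood_pool, spec$spacing)
  expect_equal(frame$center[1, ], spec$center, tolerance = 0.1 * 100)
  # c_hat at (cx + R, cy) is +/- y
  i <- round(spec$center[1] / 100 + 10)
  j <- round(spec$center[2] / 100)
  b1 <- frame_basis(frame, cbind(i, j, 1))
  expect_equal(unname(abs(b1$c[1, 2])), 1, tolerance = 0.05)
  # orthonormality at many random myocardial voxels
  set.seed(2)
  ijk <- arrayInd(sample(which(geom$myocardium), 2000, replace = TRUE),
                  spec$dim)
  b <- frame_basis(frame, ijk)
  expect_lt(max(abs(rowSums(b$r * b$c))), 1e-6)
  expect_lt(max(abs(rowSums(b$r * b$l))), 1e-6)
  expect_lt(max(abs(rowSums(b$c * b$l))), 1e-6)
  expect_equal(rowSums(b$r^2), rep(1, nrow(ijk)), tolerance = 1e-9)
  # slice without blood pool warns and gets NA centre
  bp <- geom$blood_pool
  bp[, , 2] <- FALSE
  expect_warning(f2 <- build_frame(geom$myocardium, bp, spec$spacing),
                 "skipped")
  expect_true(all(is.na(f2$center[2, ])))
})

test_that("helix angle follows its geometric definition", {
  frame <- lv_frame(center = matrix(c(0, 0.5), 1, 2), dim = c(9, 9, 1),
                    spacing = c(1, 1, 1))
  # voxel (5,1,1) sits at (4.5, 0.5): radial = +x, c_hat = +y, l_hat = +z
  of <- function(v) structure(list(idx = 5L, vectors = matrix(v, 1),
                                   dim = c(9, 9, 1), spacing = c(1, 1, 1)),
                              class = "orientation_field")
  ha_of <- function(v) helix_angle(of(v), frame)[5, 1, 1]
  expect_equal(ha_of(c(0, 1, 0)), 0)            # circumferential
  expect_equal(ha_of(c(0, 0, 1)), 90)           # longitudinal
  expect_equal(ha_of(c(0, 1, 1) / sqrt(2)), 45)
  expect_equal(ha_of(c(0, 1, -1) / sqrt(2)), -45)
  expect_equal(ha_of(c(0, -1, -1) / sqrt(2)), 45)  # antipodal symmetry
  # nearly radial fiber flagged undefined
  expect_true(is.na(ha_of(c(0.999, 0.04, 0))))
})

test_that("transmural depth is correct, monotone and gap-aware", {
  spec <- phantom_spec(dim = c(64, 64, 2), spacing = c(1, 1, 1),
                       r_endo = 10, r_epi = 20, center = c(32, 32))
  geom <- make_lv_geometry(spec)
  frame <- build_frame(geom$myocardium, geom$blood_pool, c(1, 1, 1))
  tdm <- transmural_depth(geom$myocardium, frame)
  idx <- which(geom$myocardium[, , 1])
  ij <- arrayInd(idx, spec$dim[1:2])
  r <- sqrt((ij[, 1] - 0.5 - 32)^2 + (ij[, 2] - 0.5 - 32)^2)
  td1 <- tdm$td[, , 1][idx]
  # voxel at radius ~15 has TD ~50%
  mid <- abs(r - 15) < 0.3
  expect_equal(mean(td1[mid]), 50, tolerance = 3)
  # endocardial boundary voxels sit within half a voxel of TD 0
  inner <- r < 10.5
  expect_lt(max(td1[inner]), 100 * 1 / 10)
  # monotone along rays: TD increases with radius within each of the
  # azimuth bins the TD map itself assigns voxels to
  az <- atan2(ij[, 2] - 0.5 - 32, ij[, 1] - 0.5 - 32) %% (2 * pi)
  bin <- floor(az / (2 * pi / tdm$n_bins))
  bs <- unique(bin)
  for (b in bs[seq(1, length(bs), by = 7)]) {
    s <- bin == b
    if (sum(s) < 2) next
    o <- order(r[s])
    expect_true(all(diff(td1[s][o]) > -1e-9))
  }
})

test_that("TD stays monotone on an eccentric annulus", {
  spec <- phantom_spec(dim = c(64, 64, 1), spacing = c(1, 1, 1),
                       r_endo = 8, r_epi = 16, center = c(28, 30))
  geom <- make_lv_geometry(spec)
  frame <- build_frame(geom$myocardium, geom$blood_pool, c(1, 1, 1))
  # offset frame centre inside the pool: rays are still monotone
  frame$center[1, ] <- c(26, 29)
  tdm <- transmural_depth(geom$myocardium, frame)
  idx <- which(geom$myocardium[, , 1] & !is.na(tdm$td[, , 1]))
  ij <- arrayInd(idx, spec$dim[1:2])
  dx <- ij[, 1] - 0.5 - 26; dy <- ij[, 2] - 0.5 - 29
  r <- sqrt(dx^2 + dy^2)
  bin <- floor((atan2(dy, dx) %% (2 * pi)) / (2 * pi / tdm$n_bins))
  td1 <- tdm$td[, , 1][idx]
  for (b in unique(bin)) {
    s <- bin == b
    if (sum(s) < 2) next
    o <- order(r[s])
    expect_true(all(diff(td1[s][o]) > -1e-9))
  }
})

test_that("rays across a thinned (gapped) wall are flagged invalid", {
  spec <- phantom_spec(dim = c(64, 64, 1), spacing = c(1, 1, 1),
                       r_endo = 10, r_epi = 20, center = c(32, 32))
  geom <- make_lv_geometry(spec)
  myo <- geom$myocardium
  # carve a mid-wall gap in a sector around azimuth 0
  idx <- which(myo[, , 1])
  ij <- arrayInd(idx, spec$dim[1:2])
  r <- sqrt((ij[, 1] - 0.5 - 32)^2 + (ij[, 2] - 0.5 - 32)^2)
  az <- atan2(ij[, 2] - 0.5 - 32, ij[, 1] - 0.5 - 32) * 180 / pi
  gap <- abs(az) < 15 & r > 13 & r < 17
  myo[, , 1][idx[gap]] <- FALSE
  frame <- build_frame(myo, geom$blood_pool, c(1, 1, 1))
  tdm <- transmural_depth(myo, frame)
  bnd <- tdm$boundaries
  in_gap <- abs(cardiohelix:::wrap_angle_diff(bnd$azimuth_deg, 0)) < 12
  expect_true(mean(bnd$valid[in_gap]) < 0.2)
  expect_true(mean(bnd$valid[!in_gap]) > 0.9)
})

test_that("noise-free phantom HA is exact away from boundaries and
          rotation-invariant", {
  fib <- tiny_fiber(nz = 4)
  dwi <- synthesize_dwi(fib)
  eigs <- eigendecompose(fit_tensor_loglinear(dwi, mask = fib$mask),
                         frame = fib$frame)
  ha <- helix_angle(primary_orientation(eigs), fib$frame)
  err <- abs(ha - fib$truth$ha)
  expect_lt(max(err, na.rm = TRUE), 0.5)
  # rotate the whole dataset 90 degrees in-plane: HA map rotates with it
  rot <- function(a) {
    d <- dim(a)
    aperm(a, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  vec <- fib$orientation
  rv <- array(0, dim(vec))
  for (cmp in 1:3) rv[, , , cmp] <- rot(vec[, , , cmp])
  tmp <- rv[, , , 1]
  rv[, , , 1] <- -rv[, , , 2]   # vectors rotate too: (x,y) -> (-y,x)
  rv[, , , 2] <- tmp
  of_rot <- orientation_field(rv, fib$spec$spacing)
  ha_rot <- helix_angle(of_rot, fib$frame)  # square grid: same centre
  expect_lt(max(abs(ha_rot - rot(ha)), na.rm = TRUE), 1)
})
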