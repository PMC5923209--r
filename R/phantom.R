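#' Lesion specification for the synthetic ischemic phantom
#'
#' A transmural lesion occupying an angular sector of the wall, with an
#' elevated mean diffusivity and a locally flattened helix angle, plus a
#' surrounding peri-infarct ring with intermediate values. The default
#' multipliers are chosen so that, with the default baseline eigenvalues,
#' the core MD exceeds 1.12 um^2/ms and the ring falls between 0.9 and
#' 1.12 um^2/ms (the zoning thresholds used downstream).
#'
#' @param azimuth lesion centre azimuth in degrees (0 = +x axis).
#' @param halfwidth half angular width of the infarct core, degrees.
#' @param ring_width additional angular width of the peri-infarct ring,
#'   degrees, on each side of the core.
#' @param td_range transmural extent of the lesion as (min, max) %TD.
#' @param md_multiplier eigenvalue (hence MD) multiplier in the core.
#' @param ring_md_multiplier multiplier in the peri-infarct ring.
#' @param ha_flatten factor in [0, 1] multiplying the helix angle inside
#'   the core; the ring uses the midpoint (1 + ha_flatten)/2.
#' @return list of class `lesion_spec`.
#' @export
lesion_spec <- function(azimuth = 0, halfwidth = 30, ring_width = 14,
                        td_range = c(0, 100), md_multiplier = 1.5,
                        ring_md_multiplier = 1.25, ha_flatten = 0.4) {
  stopifnot(halfwidth > 0, ring_width >= 0,
            ha_flatten >= 0, ha_flatten <= 1,
            md_multiplier > 0, ring_md_multiplier > 0)
  structure(list(azimuth = azimuth, halfwidth = halfwidth,
                 ring_width = ring_width, td_range = td_range,
                 md_multiplier = md_multiplier,
                 ring_md_multiplier = ring_md_multiplier,
                 ha_flatten = ha_flatten),
            class = "lesion_spec")
}

#' Synthetic left-ventricle phantom specification
#'
#' Describes an annular LV myocardium around a blood pool with a
#' transmurally ramping helical fiber field. Helix angle ramps linearly
#' with transmural depth from `ha_endo` (0% TD, endocardium) to `ha_epi`
#' (100% TD, epicardium); the long axis is the third array axis, with
#' slices ordered base to apex.
#'
#' @param dim grid size (voxels) per axis.
#' @param spacing voxel size in um per axis.
#' @param r_endo,r_epi endocardial/epicardial radii in um (scalar or one
#'   value per slice).
#' @param center in-plane physical centre (x, y) in um; default the grid
#'   centre.
#' @param ha_endo,ha_epi helix angle (degrees) at endo-/epicardium.
#' @param lambda diffusion tensor eigenvalues (l1 >= l2 >= l3, um^2/ms).
#' @param s0 non-diffusion-weighted signal level.
#' @param d_pool isotropic diffusivity of the blood pool (um^2/ms).
#' @param lesion `NULL` or a [lesion_spec()].
#' @param noise list(type = "none"|"gaussian"|"rician", sigma) with sigma
#'   expressed as a fraction of `s0`.
#' @param seed integer seed for all stochastic synthesis.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 16), spacing = c(125, 125, 125),
                         r_endo = 900, r_epi = 2500, center = NULL,
                         ha_endo = 60, ha_epi = -60,
                         lambda = c(1.3, 0.7, 0.5), s0 = 1, d_pool = 2,
                         lesion = NULL,
                         noise = list(type = "none", sigma = 0),
                         seed = 1L) {
  dim <- as.integer(dim); stopifnot(length(dim) == 3, all(dim >= 1))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  nz <- dim[3]
  r_endo <- rep(as.numeric(r_endo), length.out = nz)
  r_epi <- rep(as.numeric(r_epi), length.out = nz)
  if (any(r_endo >= r_epi)) {
    stop("degenerate radii: endocardial radius must be smaller than ",
         "epicardial radius on every slice")
  }
  if (any(r_endo <= 0)) stop("endocardial radius must be positive")
  stopifnot(length(lambda) == 3)
  if (!(lambda[1] >= lambda[2] && lambda[2] >= lambda[3] && lambda[3] > 0)) {
    stop("eigenvalues must satisfy l1 >= l2 >= l3 > 0")
  }
  if (abs(ha_endo) > 90 || abs(ha_epi) > 90) {
    stop("|ha_endo| and |ha_epi| must be <= 90 degrees")
  }
  if (is.null(center)) center <- dim[1:2] * spacing[1:2] / 2
  if (!is.null(lesion) && !inherits(lesion, "lesion_spec")) {
    lesion <- do.call(lesion_spec, lesion)
  }
  noise$type <- match.arg(noise$type, c("none", "gaussian", "rician"))
  if (is.null(noise$sigma)) noise$sigma <- 0
  structure(list(dim = dim, spacing = spacing, r_endo = r_endo,
                 r_epi = r_epi, center = as.numeric(center),
                 ha_endo = ha_endo, ha_epi = ha_epi, lambda = lambda,
                 s0 = s0, d_pool = d_pool, lesion = lesion, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("LV phantom %dx%dx%d @ %s um; wall %g-%g um; HA %+g -> %+g deg%s\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              x$r_endo[1], x$r_epi[1], x$ha_endo, x$ha_epi,
              if (is.null(x$lesion)) "" else "; lesion present"))
  invisible(x)
}

#' Refine a phantom specification to a finer grid
#'
#' Returns the same physical phantom sampled at `factor`-times finer
#' resolution per axis (used to render the optical volume at higher
#' resolution than the DWI grid).
#'
#' @param spec a [phantom_spec()].
#' @param factor integer refinement per axis (scalar or length 3).
#' @return a [phantom_spec()] on the refined grid.
#' @export
refine_spec <- function(spec, factor = 3) {
  factor <- rep(as.integer(factor), length.out = 3)
  stopifnot(all(factor >= 1))
  s <- unclass(spec)
  s$dim <- spec$dim * factor
  s$spacing <- spec$spacing / factor
  s$r_endo <- rep(spec$r_endo, each = factor[3])
  s$r_epi <- rep(spec$r_epi, each = factor[3])
  class(s) <- "phantom_spec"
  s
}

# per-slice in-plane polar coordinates of all voxel centres
.polar_grid <- function(spec) {
  dx <- (seq_len(spec$dim[1]) - 0.5) * spec$spacing[1] - spec$center[1]
  dy <- (seq_len(spec$dim[2]) - 0.5) * spec$spacing[2] - spec$center[2]
  X <- matrix(dx, spec$dim[1], spec$dim[2])
  Y <- matrix(dy, spec$dim[1], spec$dim[2], byrow = TRUE)
  list(r = sqrt(X^2 + Y^2), theta = atan2(Y, X))
}

#' Generate the annular LV geometry of a phantom
#'
#' @param spec a [phantom_spec()].
#' @return list of class `lv_geometry`: logical arrays `myocardium` and
#'   `blood_pool`, the [lv_frame] (per-slice centres, long axis), and the
#'   spec.
#' @export
make_lv_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  pg <- .polar_grid(spec)
  myo <- array(FALSE, spec$dim)
  pool <- array(FALSE, spec$dim)
  for (k in seq_len(spec$dim[3])) {
    myo[, , k] <- pg$r >= spec$r_endo[k] & pg$r <= spec$r_epi[k]
    pool[, , k] <- pg$r < spec$r_endo[k]
  }
  if (!any(myo)) stop("empty myocardium: check radii against the grid extent")
  frame <- lv_frame(center = matrix(spec$center, spec$dim[3], 2, byrow = TRUE),
                    dim = spec$dim, spacing = spec$spacing)
  structure(list(myocardium = myo, blood_pool = pool, frame = frame,
                 spec = spec),
            class = "lv_geometry")
}

# region label codes used throughout
REGION_BACKGROUND <- 0L
REGION_REMOTE <- 1L
REGION_PERI <- 2L
REGION_INFARCT <- 3L

#' Generate the helical fiber field and ground truth of a phantom
#'
#' At each myocardial voxel the helix angle ramps linearly in transmural
#' depth between the prescribed endo- and epicardial values, and the fiber
#' lies in the local circumferential-longitudinal tangent plane at that
#' angle from the circumferential direction. Lesion core voxels have the
#' helix angle multiplied by the flattening factor, ring voxels by the
#' midpoint factor.
#'
#' @param geometry an `lv_geometry` from [make_lv_geometry()].
#' @return list of class `fiber_field`: `orientation` (4D array, unit
#'   vectors, zero outside the myocardium), `mask`, `frame`, `spec`, and
#'   `truth` (HA map, TD map, region labels, true global HAT, signed).
#' @export
make_fiber_field <- function(geometry) {
  stopifnot(inherits(geometry, "lv_geometry"))
  spec <- geometry$spec
  d <- spec$dim
  pg <- .polar_grid(spec)
  ha <- array(NA_real_, d)
  td <- array(NA_real_, d)
  labels <- array(REGION_BACKGROUND, d)
  orient <- array(0, c(d, 3))
  les <- spec$lesion
  for (k in seq_len(d[3])) {
    m <- geometry$myocardium[, , k]
    if (!any(m)) next
    r <- pg$r[m]; th <- pg$theta[m]
    tdk <- 100 * (r - spec$r_endo[k]) / (spec$r_epi[k] - spec$r_endo[k])
    hak <- spec$ha_endo + (spec$ha_epi - spec$ha_endo) * tdk / 100
    lab <- rep(REGION_REMOTE, length(r))
    if (!is.null(les)) {
      dth <- abs(wrap_angle_diff(rad2deg(th), les$azimuth))
      in_td <- tdk >= les$td_range[1] & tdk <= les$td_range[2]
      core <- dth <= les$halfwidth & in_td
      ring <- dth > les$halfwidth & dth <= les$halfwidth + les$ring_width & in_td
      hak[core] <- hak[core] * les$ha_flatten
      hak[ring] <- hak[ring] * (1 + les$ha_flatten) / 2
      lab[core] <- REGION_INFARCT
      lab[ring] <- REGION_PERI
    }
    # local basis: r_hat in-plane, c_hat = l_hat x r_hat, l_hat = +z
    ct <- cos(th); st <- sin(th)
    har <- deg2rad(hak)
    fx <- cos(har) * (-st)
    fy <- cos(har) * ct
    fz <- sin(har)
    hs <- ha[, , k]; hs[m] <- hak; ha[, , k] <- hs
    ts <- td[, , k]; ts[m] <- tdk; td[, , k] <- ts
    ls <- labels[, , k]; ls[m] <- lab; labels[, , k] <- ls
    for (cmp in 1:3) {
      os <- orient[, , k, cmp]
      os[m] <- switch(cmp, fx, fy, fz)
      orient[, , k, cmp] <- os
    }
  }
  structure(list(orientation = orient, mask = geometry$myocardium,
                 blood_pool = geometry$blood_pool, frame = geometry$frame,
                 spec = spec,
                 truth = list(ha = ha, td = td, labels = labels,
                              global_hat = (spec$ha_epi - spec$ha_endo) / 100)),
            class = "fiber_field")
}

# distinct gradient axes (antipodal pairs counted once)
.n_unique_axes <- function(protocol, tol = 1e-6) {
  g <- protocol$bvecs[protocol$bvals > 0, , drop = FALSE]
  if (nrow(g) == 0) return(0L)
  keep <- rep(TRUE, nrow(g))
  for (i in seq_len(nrow(g))) {
    if (!keep[i]) next
    if (i < nrow(g)) {
      for (j in (i + 1):nrow(g)) {
        if (abs(abs(sum(g[i, ] * g[j, ])) - 1) < tol) keep[j] <- FALSE
      }
    }
  }
  sum(keep)
}

#' Synthesize a diffusion-weighted image stack from a fiber field
#'
#' Uses the single-tensor signal model S = S0 exp(-b g' D g) with D built
#' from the spec eigenvalues: l1 along the fiber, l2 in the tangent plane
#' perpendicular to it, l3 along the radial direction. Lesion voxels have
#' all eigenvalues scaled by the lesion MD multipliers; the blood pool is
#' isotropic at `d_pool`. Rician or Gaussian noise is applied with the
#' spec's seed.
#'
#' @param fiber a `fiber_field`.
#' @param protocol a [dwi_protocol()]; default the reference 12-direction,
#'   b = 1000 s/mm^2 scheme plus one b = 0 volume.
#' @return list of class `dwi_stack`: `data` (4D array x,y,z,volume),
#'   `protocol`, `spacing` (um), `spec`.
#' @export
synthesize_dwi <- function(fiber, protocol = default_protocol12()) {
  stopifnot(inherits(fiber, "fiber_field"), inherits(protocol, "dwi_protocol"))
  spec <- fiber$spec
  if (.n_unique_axes(protocol) < 6) {
    stop("protocol has fewer than 6 unique gradient directions: ",
         "the tensor fit would be underdetermined")
  }
  d <- spec$dim
  idx <- which(fiber$mask)
  n <- length(idx)
  ijk <- arrayInd(idx, d)
  # fiber, radial and second transverse directions at myocardial voxels
  f <- cbind(fiber$orientation[, , , 1][idx],
             fiber$orientation[, , , 2][idx],
             fiber$orientation[, , , 3][idx])
  ctr <- fiber$frame$center[ijk[, 3], , drop = FALSE]
  rv <- cbind((ijk[, 1] - 0.5) * spec$spacing[1] - ctr[, 1],
              (ijk[, 2] - 0.5) * spec$spacing[2] - ctr[, 2], 0)
  rv <- unit_rows(rv)
  e2 <- cbind(rv[, 2] * f[, 3] - rv[, 3] * f[, 2],
              rv[, 3] * f[, 1] - rv[, 1] * f[, 3],
              rv[, 1] * f[, 2] - rv[, 2] * f[, 1])
  e2 <- unit_rows(e2)
  mult <- rep(1, n)
  lab <- fiber$truth$labels[idx]
  if (!is.null(spec$lesion)) {
    mult[lab == REGION_INFARCT] <- spec$lesion$md_multiplier
    mult[lab == REGION_PERI] <- spec$lesion$ring_md_multiplier
  }
  l <- spec$lambda
  comps <- cbind(
    l[1] * f[, 1]^2 + l[2] * e2[, 1]^2 + l[3] * rv[, 1]^2,
    l[1] * f[, 2]^2 + l[2] * e2[, 2]^2 + l[3] * rv[, 2]^2,
    l[1] * f[, 3]^2 + l[2] * e2[, 3]^2 + l[3] * rv[, 3]^2,
    l[1] * f[, 1] * f[, 2] + l[2] * e2[, 1] * e2[, 2] + l[3] * rv[, 1] * rv[, 2],
    l[1] * f[, 1] * f[, 3] + l[2] * e2[, 1] * e2[, 3] + l[3] * rv[, 1] * rv[, 3],
    l[1] * f[, 2] * f[, 3] + l[2] * e2[, 2] * e2[, 3] + l[3] * rv[, 2] * rv[, 3]
  ) * mult
  pool_idx <- which(fiber$blood_pool)
  nvol <- length(protocol$bvals)
  data <- array(0, c(d, nvol))
  nv <- prod(d)
  for (v in seq_len(nvol)) {
    b <- protocol$bvals[v]
    g <- protocol$bvecs[v, ]
    vol <- array(0, d)
    if (b == 0) {
      vol[idx] <- spec$s0
      vol[pool_idx] <- spec$s0
    } else {
      quad <- comps[, 1] * g[1]^2 + comps[, 2] * g[2]^2 + comps[, 3] * g[3]^2 +
        2 * (comps[, 4] * g[1] * g[2] + comps[, 5] * g[1] * g[3] +
               comps[, 6] * g[2] * g[3])
      # b in s/mm^2, D in um^2/ms -> b*D = (b/1000)*D dimensionless
      vol[idx] <- spec$s0 * exp(-b * 1e-3 * quad)
      vol[pool_idx] <- spec$s0 * exp(-b * 1e-3 * spec$d_pool)
    }
    data[, , , v] <- vol
  }
  if (spec$noise$type != "none" && spec$noise$sigma > 0) {
    sig <- spec$noise$sigma * spec$s0
    data <- with_seed(spec$seed, {
      if (spec$noise$type == "gaussian") {
        data + array(rnorm(length(data), sd = sig), dim(data))
      } else {
        n1 <- array(rnorm(length(data), sd = sig), dim(data))
        n2 <- array(rnorm(length(data), sd = sig), dim(data))
        sqrt((data + n1)^2 + n2^2)
      }
    })
  }
  structure(list(data = data, protocol = protocol, spacing = spec$spacing,
                 spec = spec),
            class = "dwi_stack")
}

#' Texture parameters for the synthetic optical volume
#'
#' @param wavelength characteristic stripe spacing perpendicular to the
#'   fibers, in um; must resolve to at least 3 voxels.
#' @param contrast relative contrast of the fibrous texture (0 disables).
#' @param base mean myocardial intensity (volume kept in [0, 1]).
#' @param radial_contrast relative contrast of the radial (laminar)
#'   modulation.
#' @param lic_length half-length (um) of the line-integral smoothing along
#'   the fiber.
#' @param shadow_axis axis (1 = x, 2 = y) along which light-sheet shadow
#'   stripes run; stripes are constant along this axis.
#' @param shadow_amplitude additive amplitude of the shadow stripes.
#' @param shadow_wavelength spatial period of the shadow stripes, um.
#' @param noise_sigma additive Gaussian noise level.
#' @param background background intensity outside the tissue.
#' @return list of class `optical_texture_params`.
#' @export
optical_texture_params <- function(wavelength = 250, contrast = 0.4,
                                   base = 0.5, radial_contrast = 0.15,
                                   lic_length = 2 * wavelength,
                                   shadow_axis = 1, shadow_amplitude = 0,
                                   shadow_wavelength = 600,
                                   noise_sigma = 0.01, background = 0.05) {
  structure(as.list(environment()), class = "optical_texture_params")
}

#' Synthesize a high-resolution optical volume from a fiber field
#'
#' Renders fibrous texture by line-integral convolution: seeded white
#' noise is pre-smoothed to the stripe wavelength and then smeared along
#' the local fiber direction, so intensity gradients are perpendicular to
#' the fiber everywhere. An optional radial modulation emulates laminar
#' sheets, and optional global shadow stripes emulate light-sheet
#' illumination artifacts.
#'
#' @param fiber a `fiber_field` (typically on a refined grid, see
#'   [refine_spec()]).
#' @param texture an [optical_texture_params()].
#' @return list of class `optical_volume`: `data` (3D array in [0, 1]),
#'   `spacing` (um), `mask`, `params`.
#' @export
synthesize_optical <- function(fiber, texture = optical_texture_params()) {
  stopifnot(inherits(fiber, "fiber_field"))
  spec <- fiber$spec
  d <- spec$dim
  live_axes <- which(d > 1)
  min_sp <- min(spec$spacing[live_axes])
  if (texture$wavelength < 3 * min_sp) {
    stop("stripe wavelength below 3 voxels (", signif(3 * min_sp, 4),
         " um at this resolution): aliasing")
  }
  vol <- array(texture$background, d)
  idx <- which(fiber$mask)
  vol[idx] <- texture$base
  if (texture$contrast > 0) {
    noise <- with_seed(spec$seed + 101L,
                       array(rnorm(prod(d)), d))
    sig_vox <- texture$wavelength / 6 / spec$spacing
    sig_vox[d == 1] <- 0
    blob <- gauss_smooth(noise, sig_vox)
    step <- 0.5 * min_sp
    nst <- max(1L, as.integer(round(texture$lic_length / step)))
    lic <- lic3d(as.numeric(blob), as.numeric(fiber$orientation),
                 as.integer(d), as.numeric(spec$spacing), step, nst)
    lic <- array(lic, d)
    mu <- mean(lic[idx]); s <- sd(lic[idx])
    if (s > 0) {
      z <- (lic[idx] - mu) / s
      vol[idx] <- vol[idx] * (1 + texture$contrast * z)
    }
    if (texture$radial_contrast > 0) {
      pg <- .polar_grid(spec)
      rr <- array(rep(pg$r, d[3]), d)
      vol[idx] <- vol[idx] +
        texture$base * texture$radial_contrast *
        cos(2 * pi * rr[idx] / texture$wavelength)
    }
  }
  if (texture$shadow_amplitude > 0) {
    perp <- if (texture$shadow_axis == 1) 2L else 1L
    coord <- (seq_len(d[perp]) - 0.5) * spec$spacing[perp]
    stripe <- texture$shadow_amplitude *
      cos(2 * pi * coord / texture$shadow_wavelength)
    sl <- rep(list(quote(expr = )), 3)
    stripe_arr <- array(0, d)
    if (perp == 2L) {
      stripe_arr <- array(rep(rep(stripe, each = d[1]), d[3]), d)
    } else {
      stripe_arr <- array(rep(stripe, times = d[2] * d[3]), d)
    }
    vol <- vol + stripe_arr
  }
  if (texture$noise_sigma > 0) {
    vol <- vol + with_seed(spec$seed + 202L,
                           array(rnorm(prod(d), sd = texture$noise_sigma), d))
  }
  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  structure(list(data = vol, spacing = spec$spacing, mask = fiber$mask,
                 params = texture, spec = spec),
            class = "optical_volume")
}
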