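#' Remove light-sheet stripe artifacts by a frequency-domain notch
#'
#' Shadow stripes run along the illumination (artifact) axis, so their
#' spectral energy concentrates in the narrow band of near-zero frequency
#' along that axis (excluding the DC term). Each slice perpendicular to
#' the stack axis is Fourier transformed and coefficients inside the band
#' are attenuated by a Gaussian notch scaled by `strength`; everything
#' outside the notch is preserved exactly.
#'
#' @param volume 2D matrix or 3D array.
#' @param artifact_axis in-plane axis (1 = x, 2 = y) along which the
#'   stripes run.
#' @param strength attenuation in [0, 1]; 0 returns the input unchanged.
#' @param notch_width Gaussian width of the notch in frequency bins.
#' @param protect Gaussian width (bins) of the protected low-frequency
#'   region along the perpendicular axis, so large-scale anatomy at
#'   near-zero stripe-axis frequency is not removed with the stripes.
#' @return filtered array of the same shape.
#' @export
remove_stripes <- function(volume, artifact_axis = 1, strength = 1,
                           notch_width = 2, protect = 4) {
  stopifnot(artifact_axis %in% c(1, 2), strength >= 0, strength <= 1)
  if (strength == 0) return(volume)
  d <- dim(volume)
  two_d <- length(d) == 2
  if (two_d) { volume <- array(volume, c(d, 1)); d <- dim(volume) }
  n1 <- d[1]; n2 <- d[2]
  bin <- function(n) {
    b <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    if (n == 1) b <- 0
    b[seq_len(n)]
  }
  ba <- bin(n1); bb <- bin(n2)
  if (artifact_axis == 1) {
    damp <- 1 - strength *
      outer(exp(-0.5 * (ba / notch_width)^2),
            1 - exp(-0.5 * (bb / protect)^2))
  } else {
    damp <- 1 - strength *
      outer(1 - exp(-0.5 * (ba / protect)^2),
            exp(-0.5 * (bb / notch_width)^2))
  }
  damp[1, 1] <- 1  # DC
  out <- volume
  for (k in seq_len(d[3])) {
    f <- stats::fft(volume[, , k])
    out[, , k] <- Re(stats::fft(f * damp, inverse = TRUE)) / (n1 * n2)
  }
  if (two_d) out <- out[, , 1]
  out
}

#' Sobel image gradients
#'
#' Standard separable Sobel kernels: central difference (-1, 0, 1)/2 along
#' the gradient axis and (1, 2, 1)/4 smoothing along the others, so a unit
#' intensity ramp yields a unit gradient (per voxel length). Boundaries
#' are handled by reflection and the one-voxel boundary layer is flagged.
#'
#' @param volume 2D matrix or 3D array, at least 3 voxels per (used) axis.
#' @return list of class `gradient_field`: `fx`, `fy` (and `fz` for 3D)
#'   arrays, `boundary` logical array, `dim`, `mode` ("2D" or "3D").
#' @export
sobel_gradients <- function(volume) {
  d <- dim(volume)
  if (is.null(d) || length(d) < 2) stop("volume must be a 2D or 3D array")
  two_d <- length(d) == 2 || d[3] == 1
  used <- if (two_d) d[1:2] else d
  if (any(used < 3)) stop("volume too small: need >= 3 voxels per axis")
  deriv <- c(-0.5, 0, 0.5)
  smooth <- c(0.25, 0.5, 0.25)
  grad_along <- function(x, axis) {
    nd <- length(dim(x))
    g <- conv_axis(x, deriv, axis)
    for (other in setdiff(seq_len(nd), axis)) {
      if (dim(x)[other] >= 3) g <- conv_axis(g, smooth, other)
    }
    g
  }
  boundary <- array(FALSE, d)
  if (length(d) == 2) {
    fx <- grad_along(volume, 1); fy <- grad_along(volume, 2)
    boundary[c(1, d[1]), ] <- TRUE; boundary[, c(1, d[2])] <- TRUE
    out <- list(fx = fx, fy = fy, fz = NULL, boundary = boundary,
                dim = d, mode = "2D")
  } else {
    fx <- grad_along(volume, 1); fy <- grad_along(volume, 2)
    fz <- if (two_d) NULL else grad_along(volume, 3)
    boundary[c(1, d[1]), , ] <- TRUE; boundary[, c(1, d[2]), ] <- TRUE
    if (!two_d) boundary[, , c(1, d[3])] <- TRUE
    out <- list(fx = fx, fy = fy, fz = fz, boundary = boundary,
                dim = d, mode = if (two_d) "2D" else "3D")
  }
  structure(out, class = "gradient_field")
}

#' Fiber orientation from the windowed structure tensor
#'
#' Gradient outer products are averaged with an isotropic Gaussian window
#' and the orientation is the eigenvector of the smallest eigenvalue (the
#' second of two in 2D, the third of three in 3D), which points along the
#' texture. Gradients are scaled to physical units before tensor formation
#' so anisotropic voxels do not bias through-plane angles. The coherence
#' score (lmax - lmin)/(lmax + lmin) is 0 for a vanishing tensor; voxels
#' below `coherence_threshold` are flagged undefined.
#'
#' @param grads a `gradient_field` from [sobel_gradients()].
#' @param window_sigma Gaussian window width in voxels (>= 1).
#' @param spacing voxel size in um per axis.
#' @param mask optional logical array restricting the eigenanalysis.
#' @param coherence_threshold coherence below which orientation is NA.
#' @return For 3D input, a list of class `st_orientation` with
#'   `orientation` (an `orientation_field`), `coherence` (array),
#'   `window_sigma`. For 2D input, the same but with `theta` (in-plane
#'   axial angle vs +x, degrees in (-90, 90]) and `vectors` (n x 2).
#' @export
structure_tensor_orientation <- function(grads, window_sigma = 4,
                                         spacing = c(1, 1, 1), mask = NULL,
                                         coherence_threshold = 0.1) {
  stopifnot(inherits(grads, "gradient_field"))
  if (window_sigma <= 0) stop("window_sigma must be positive")
  if (window_sigma < 1) stop("window_sigma below 1 voxel is unreliable")
  spacing <- rep(spacing, length.out = 3)
  d <- grads$dim
  if (grads$mode == "3D") {
    fx <- grads$fx / spacing[1]
    fy <- grads$fy / spacing[2]
    fz <- grads$fz / spacing[3]
    sm <- function(x) gauss_smooth(x, window_sigma)
    txx <- sm(fx * fx); tyy <- sm(fy * fy); tzz <- sm(fz * fz)
    txy <- sm(fx * fy); txz <- sm(fx * fz); tyz <- sm(fy * fz)
    idx <- if (is.null(mask)) seq_len(prod(d)) else which(mask)
    comps <- cbind(txx[idx], tyy[idx], tzz[idx],
                   txy[idx], txz[idx], tyz[idx])
    es <- eig_sym3_batch(comps)
    tr_lo <- es$values[, 1] + es$values[, 3]
    coh <- ifelse(tr_lo > 0, (es$values[, 1] - es$values[, 3]) / tr_lo, 0)
    ok <- is.finite(coh) & coh >= coherence_threshold
    orient <- structure(list(idx = idx[ok],
                             vectors = es$vectors[ok, 7:9, drop = FALSE],
                             dim = d, spacing = spacing),
                        class = "orientation_field")
    coh_arr <- expand_to_array(coh, idx, d)
    structure(list(orientation = orient, coherence = coh_arr,
                   window_sigma = window_sigma, mode = "3D"),
              class = "st_orientation")
  } else {
    d2 <- d[1:2]
    as2 <- function(x) if (length(dim(x)) == 3) x[, , 1] else x
    fx <- as2(grads$fx) / spacing[1]
    fy <- as2(grads$fy) / spacing[2]
    sm <- function(x) gauss_smooth(x, window_sigma)
    a <- sm(fx * fx); b <- sm(fx * fy); c2 <- sm(fy * fy)
    # principal (largest-eigenvalue) direction; texture = +90 degrees
    phi <- 0.5 * atan2(2 * b, a - c2)
    theta <- wrap_axial(rad2deg(phi + pi / 2))
    disc <- sqrt((a - c2)^2 + 4 * b^2)
    tr <- a + c2
    coh <- ifelse(tr > 0, disc / tr, 0)
    idx <- if (is.null(mask)) seq_len(prod(d2)) else which(as2(mask))
    ok <- is.finite(coh[idx]) & coh[idx] >= coherence_threshold
    theta_arr <- array(NA_real_, d2)
    theta_arr[idx[ok]] <- theta[idx[ok]]
    th <- deg2rad(theta_arr[idx[ok]])
    structure(list(theta = theta_arr,
                   idx = idx[ok],
                   vectors = cbind(cos(th), sin(th)),
                   coherence = array(coh, d2),
                   window_sigma = window_sigma, mode = "2D",
                   dim = d2),
              class = "st_orientation")
  }
}

#' In-plane cardiomyocyte angle relative to the interventricular axis
#'
#' The reference frame is built from the centres of mass of the left and
#' right ventricular cavities: axis v joins the two centres, axis u is
#' orthogonal to v. Theta is the signed axial angle in (-90, 90] between
#' the (sign-free) texture orientation and u, measured toward v.
#'
#' @param st2d a 2D `st_orientation` (from
#'   [structure_tensor_orientation()]), or a list with `idx`, `vectors`
#'   (n x 2), `dim`.
#' @param lv_center,rv_center in-plane centres (same length unit as the
#'   pixel grid).
#' @return matrix of Theta in degrees (NA where orientation undefined).
#' @export
inplane_angle <- function(st2d, lv_center, rv_center) {
  dvec <- rv_center - lv_center
  if (sqrt(sum(dvec^2)) < .Machine$double.eps^0.5) {
    stop("LV and RV centres coincide: axis v undefined")
  }
  v <- dvec / sqrt(sum(dvec^2))
  u <- c(-v[2], v[1])
  o <- st2d$vectors
  theta <- rad2deg(atan2(o[, 1] * v[1] + o[, 2] * v[2],
                         o[, 1] * u[1] + o[, 2] * u[2]))
  theta <- wrap_axial(theta)
  out <- array(NA_real_, st2d$dim[1:2])
  out[st2d$idx] <- theta
  out
}
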