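# Shared fixtures: all synthetic, built in code at test time.

# small annular phantom (isotropic 100 um voxels)
tiny_spec <- function(ha_endo = 60, ha_epi = -60, nz = 6, seed = 1,
                      lesion = NULL, noise = list(type = "none", sigma = 0)) {
  phantom_spec(dim = c(48, 48, nz), spacing = c(100, 100, 100),
               r_endo = 600, r_epi = 1800, ha_endo = ha_endo,
               ha_epi = ha_epi, lesion = lesion, noise = noise, seed = seed)
}

tiny_fiber <- function(...) make_fiber_field(make_lv_geometry(tiny_spec(...)))

# independent log-linear tensor-fit oracle: explicit normal equations per
# voxel (solve(t(X) X) t(X) y), kept separate from the package's QR path
oracle_fit_voxel <- function(signals, bvals, bvecs) {
  b <- bvals * 1e-3
  g <- bvecs
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  beta <- solve(t(X) %*% X, t(X) %*% log(signals))
  beta[2:7]
}

# random symmetric positive-definite tensor with eigenvalues in [lo, hi]
random_spd <- function(lo = 0.3, hi = 2) {
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  L <- diag(sort(runif(3, lo, hi), decreasing = TRUE))
  Q %*% L %*% t(Q)
}

tensor_signals <- function(D, protocol, s0 = 1) {
  vapply(seq_along(protocol$bvals), function(v) {
    g <- protocol$bvecs[v, ]
    s0 * exp(-protocol$bvals[v] * 1e-3 * drop(t(g) %*% D %*% g))
  }, numeric(1))
}

# plane-wave stripe image: intensity varies along the normal of the
# texture orientation `angle_deg` (so the texture runs at angle_deg)
stripe_image <- function(n = 96, angle_deg = 0, wavelength = 8) {
  a <- angle_deg * pi / 180
  outer(seq_len(n), seq_len(n), function(i, j)
    cos(2 * pi * (-sin(a) * i + cos(a) * j) / wavelength))
}

# 3D version; `z_amp` adds a through-plane modulation so the 3D structure
# tensor has a unique smallest eigenvector (the in-plane texture axis)
stripe_volume <- function(n = 64, nz = 9, angle_deg = 0, wavelength = 8,
                          z_amp = 0) {
  sl <- stripe_image(n, angle_deg, wavelength)
  vol <- array(rep(sl, nz), c(n, n, nz))
  if (z_amp > 0) {
    zmod <- z_amp * cos(2 * pi * seq_len(nz) / 6)
    vol <- vol + array(rep(zmod, each = n * n), c(n, n, nz))
  }
  vol
}

# ICC oracle through a separate route: two-way ANOVA mean squares from lm()
oracle_icc <- function(x, y) {
  n <- length(x)
  df <- data.frame(val = c(x, y),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  an <- anova(lm(val ~ subj + rater, data = df))
  msr <- an["subj", "Mean Sq"]
  msc <- an["rater", "Mean Sq"]
  mse <- an["Residuals", "Mean Sq"]
  k <- 2
  list(a1 = (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)),
       c1 = (msr - mse) / (msr + (k - 1) * mse))
}
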