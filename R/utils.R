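#' @useDynLib cardiohelix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm sd var cor cor.test lm wilcox.test t.test coef
#' @importFrom stats aggregate setNames
#' @importFrom utils write.table read.table
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Evaluate an expression with a fixed RNG seed, restoring the caller's state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# reflect out-of-range 1-based indices back into 1..n
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  idx <- (idx - 1L) %% period
  idx[idx < 0L] <- idx[idx < 0L] + period
  over <- idx > (n - 1L)
  idx[over] <- period - idx[over]
  idx + 1L
}

#' Convolve an array along one axis with reflective boundaries
#'
#' Shift-and-add separable convolution; the kernel is applied centred
#' (odd length required).
#' @keywords internal
conv_axis <- function(x, kernel, axis) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  nd <- length(d)
  stopifnot(axis >= 1, axis <= nd, length(kernel) %% 2 == 1)
  half <- (length(kernel) - 1L) %/% 2L
  n <- d[axis]
  out <- array(0, dim = d)
  base <- seq_len(n)
  for (t in seq_along(kernel)) {
    w <- kernel[t]
    if (w == 0) next
    idx <- reflect_index(base + (t - 1L - half), n)
    args <- rep(list(quote(expr = )), nd)
    args[[axis]] <- idx
    shifted <- do.call(`[`, c(list(x), args, list(drop = FALSE)))
    out <- out + w * shifted
  }
  out
}

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(1)
  k <- exp(-0.5 * ((-radius):radius / sigma)^2)
  k / sum(k)
}

#' Isotropic (per-axis) Gaussian smoothing of a 2D/3D array
#'
#' @param x numeric array.
#' @param sigma standard deviation in voxels; scalar or one value per axis.
#' @return smoothed array of identical shape.
#' @keywords internal
gauss_smooth <- function(x, sigma) {
  d <- dim(x)
  sigma <- rep(sigma, length.out = length(d))
  for (ax in seq_along(d)) {
    if (sigma[ax] > 0 && d[ax] > 1) {
      x <- conv_axis(x, gaussian_kernel(sigma[ax]), ax)
    }
  }
  x
}

# wrap an angle in degrees into (-90, 90] (axial symmetry)
wrap_axial <- function(deg) {
  out <- (deg + 90) %% 180 - 90
  out[out == -90] <- 90
  out
}

# signed shortest angular difference a - b in (-180, 180]
wrap_angle_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  d[d == -180] <- 180
  d
}

unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Trilinear interpolation of a 3D array at fractional voxel positions
#'
#' Positions are in continuous voxel coordinates where the centre of voxel
#' (i, j, k) (1-based) is at (i, j, k). Points outside the grid return
#' `outside`.
#' @keywords internal
trilinear_interp <- function(vol, pts, outside = NA_real_) {
  d <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ok <- x0 >= 1 & x0 + 1 <= d[1] & y0 >= 1 & y0 + 1 <= d[2] &
    z0 >= 1 & z0 + 1 <= d[3]
  # allow points within half a voxel of the boundary by clamping
  okc <- x >= 0.5 & x <= d[1] + 0.5 & y >= 0.5 & y <= d[2] + 0.5 &
    z >= 0.5 & z <= d[3] + 0.5
  x0 <- pmin(pmax(x0, 1), d[1] - 1); y0 <- pmin(pmax(y0, 1), d[2] - 1)
  z0 <- pmin(pmax(z0, 1), max(d[3] - 1, 1))
  fx <- pmin(pmax(x - x0, 0), 1); fy <- pmin(pmax(y - y0, 0), 1)
  fz <- pmin(pmax(z - z0, 0), 1)
  if (d[3] == 1) { z0 <- rep(1, length(x)); fz <- rep(0, length(x)) }
  lin <- function(i, j, k) vol[cbind(i, j, k)]
  z1 <- pmin(z0 + 1, d[3])
  v <- (1 - fz) * ((1 - fy) * ((1 - fx) * lin(x0, y0, z0) + fx * lin(x0 + 1, y0, z0)) +
                     fy * ((1 - fx) * lin(x0, y0 + 1, z0) + fx * lin(x0 + 1, y0 + 1, z0))) +
    fz * ((1 - fy) * ((1 - fx) * lin(x0, y0, z1) + fx * lin(x0 + 1, y0, z1)) +
            fy * ((1 - fx) * lin(x0, y0 + 1, z1) + fx * lin(x0 + 1, y0 + 1, z1)))
  v[!(ok | okc)] <- outside
  v
}

# expand a masked per-voxel matrix/vector back to a full array (NA outside)
expand_to_array <- function(values, idx, dim) {
  out <- array(NA_real_, dim = dim)
  out[idx] <- values
  out
}
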