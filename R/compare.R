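#' Block-average downsampling to a coarser grid
#'
#' Resamples a volume to the target spacing by exact partial-volume
#' weighted averaging: along each axis a weight matrix is built from the
#' overlap lengths of source and target cells (so non-integer ratios are
#' handled by physical-coordinate averaging), and the volume is contracted
#' axis by axis. Means are preserved, so total intensity (mean x physical
#' volume) is conserved over the common extent. NA voxels are excluded
#' with renormalised weights; a target voxel with less than half its
#' weight valid becomes NA.
#'
#' @param volume 3D numeric array (logical masks are averaged; see
#'   `majority`).
#' @param spacing source voxel size (um).
#' @param target_spacing target voxel size (um), >= source per axis.
#' @param majority if TRUE, threshold the averaged volume at 0.5
#'   (majority vote) and return a logical array.
#' @return list: `data` (array), `spacing` (the realised target spacing).
#' @export
downsample_to <- function(volume, spacing, target_spacing,
                          majority = FALSE) {
  spacing <- rep(spacing, length.out = 3)
  target_spacing <- rep(target_spacing, length.out = 3)
  if (any(target_spacing < spacing - 1e-9)) {
    stop("target spacing must be >= source spacing on every axis")
  }
  d <- dim(volume)
  storage.mode(volume) <- "double"
  wmats <- vector("list", 3)
  ndim <- integer(3)
  for (ax in 1:3) {
    ext <- d[ax] * spacing[ax]
    nt <- max(1L, round(ext / target_spacing[ax]))
    ndim[ax] <- nt
    ts <- ext / nt  # realised spacing: cover the extent exactly
    W <- matrix(0, nt, d[ax])
    src_lo <- (seq_len(d[ax]) - 1) * spacing[ax]
    src_hi <- src_lo + spacing[ax]
    for (t in seq_len(nt)) {
      lo <- (t - 1) * ts; hi <- t * ts
      ov <- pmax(0, pmin(hi, src_hi) - pmax(lo, src_lo))
      W[t, ] <- ov / ts
    }
    wmats[[ax]] <- W
    target_spacing[ax] <- ts
  }
  valid <- is.finite(volume)
  v0 <- volume
  v0[!valid] <- 0
  contract <- function(arr, W, ax) {
    da <- dim(arr)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = da[ax])
    res <- W %*% m
    out <- array(res, c(nrow(W), da[perm[2]], da[perm[3]]))
    aperm(out, order(perm))
  }
  num <- v0
  den <- array(as.double(valid), d)
  for (ax in 1:3) {
    num <- contract(num, wmats[[ax]], ax)
    den <- contract(den, wmats[[ax]], ax)
  }
  out <- num / den
  out[den < 0.5] <- NA_real_
  if (majority) out <- !is.na(out) & out > 0.5
  list(data = out, spacing = target_spacing)
}

# trilinear resample of `vol` at physical points (n x 3, um)
.sample_physical <- function(vol, spacing, pts, outside = NA_real_) {
  vx <- sweep(pts, 2, spacing, `/`) + 0.5
  trilinear_interp(vol, vx, outside = outside)
}

# rigid+scale transform: p' = s R (p - c) + c + t, R from xyz Euler angles
.make_transform <- function(par, center) {
  t <- par[1:3]
  ang <- par[4:6]
  s <- if (length(par) >= 7) par[7] else 1
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  list(R = s * R, offset = center + t - (s * R) %*% center, par = par,
       center = center)
}

.apply_transform_pts <- function(tf, pts) {
  sweep(pts %*% t(tf$R), 2, as.numeric(tf$offset), `+`)
}

# negative mutual information between fixed binary values and the moving
# volume sampled at transformed fixed points (soft 2x2 histogram)
.neg_mi <- function(fixed_vals, moving, moving_spacing, pts, tf) {
  mv <- .sample_physical(moving, moving_spacing, .apply_transform_pts(tf, pts),
                         outside = 0)
  mv[!is.finite(mv)] <- 0
  mv <- pmin(pmax(mv, 0), 1)
  f <- fixed_vals
  n <- length(f)
  p11 <- sum(f * mv) / n
  p10 <- sum(f * (1 - mv)) / n
  p01 <- sum((1 - f) * mv) / n
  p00 <- 1 - p11 - p10 - p01
  pf1 <- p11 + p10; pm1 <- p11 + p01
  term <- function(p, a, b) if (p > 1e-12 && a > 1e-12 && b > 1e-12)
    p * log(p / (a * b)) else 0
  -(term(p11, pf1, pm1) + term(p10, pf1, 1 - pm1) +
      term(p01, 1 - pf1, pm1) + term(p00, 1 - pf1, 1 - pm1))
}

#' Mutual-information mask registration (affine: rigid + isotropic scale)
#'
#' Aligns a moving binary mask to a fixed one: initialised from the
#' centroid offset, then refined by Nelder-Mead maximisation of the
#' mutual information between the fixed mask and the linearly interpolated
#' moving mask (soft two-by-two joint histogram). The optimised transform
#' maps fixed-space physical points into moving space (resampling
#' convention). Dice overlap after registration below 0.5 raises a hard
#' warning.
#'
#' @param moving,fixed logical 3D arrays.
#' @param moving_spacing,fixed_spacing voxel sizes (um).
#' @param scale if TRUE include an isotropic scale parameter.
#' @param subsample use at most this many fixed-region points for the
#'   metric.
#' @return list of class `mask_registration`: `transform` (R 3x3, offset,
#'   parameters), `dice`, `mi`, and `resample(vol, interpolation)` to pull
#'   a moving-space volume onto the fixed grid.
#' @export
register_masks <- function(moving, fixed, moving_spacing = c(1, 1, 1),
                           fixed_spacing = c(1, 1, 1), scale = FALSE,
                           subsample = 20000) {
  if (!any(moving)) stop("moving mask is empty")
  if (!any(fixed)) stop("fixed mask is empty")
  moving_spacing <- rep(moving_spacing, length.out = 3)
  fixed_spacing <- rep(fixed_spacing, length.out = 3)
  centroid <- function(mask, sp) {
    w <- arrayInd(which(mask), dim(mask))
    colMeans(sweep(w - 0.5, 2, sp, `*`))
  }
  cf <- centroid(fixed, fixed_spacing)
  cm <- centroid(moving, moving_spacing)
  # sample points: fixed foreground plus a dilated shell of background
  fi <- which(fixed | gauss_smooth(array(as.double(fixed), dim(fixed)),
                                   2) > 0.01)
  if (length(fi) > subsample) {
    fi <- fi[seq(1, length(fi), length.out = subsample)]
  }
  ijk <- arrayInd(fi, dim(fixed))
  pts <- sweep(ijk - 0.5, 2, fixed_spacing, `*`)
  fvals <- as.double(fixed[fi])
  mvol <- array(as.double(moving), dim(moving))
  par0 <- c(cm - cf, 0, 0, 0, if (scale) 1)
  obj <- function(par) {
    .neg_mi(fvals, mvol, moving_spacing, pts, .make_transform(par, cf))
  }
  sc <- c(rep(max(fixed_spacing), 3), rep(0.05, 3), if (scale) 0.05)
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-10,
                                     parscale = sc))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12,
                                     parscale = sc / 5))
  tf <- .make_transform(opt$par, cf)
  resample <- function(vol, interpolation = c("linear", "nearest"),
                       outside = NA_real_) {
    interpolation <- match.arg(interpolation)
    dfix <- dim(fixed)
    all_ijk <- arrayInd(seq_len(prod(dfix)), dfix)
    p <- sweep(all_ijk - 0.5, 2, fixed_spacing, `*`)
    q <- .apply_transform_pts(tf, p)
    if (interpolation == "nearest") {
      vx <- floor(sweep(q, 2, moving_spacing, `/`)) + 1L
      ok <- vx[, 1] >= 1 & vx[, 1] <= dim(vol)[1] &
        vx[, 2] >= 1 & vx[, 2] <= dim(vol)[2] &
        vx[, 3] >= 1 & vx[, 3] <= dim(vol)[3]
      out <- rep(outside, nrow(vx))
      out[ok] <- vol[vx[ok, , drop = FALSE]]
    } else {
      out <- .sample_physical(vol, moving_spacing, q, outside = outside)
    }
    array(out, dfix)
  }
  warped <- resample(mvol, "nearest", outside = 0)
  dice <- 2 * sum(warped > 0.5 & fixed) / (sum(warped > 0.5) + sum(fixed))
  if (is.finite(dice) && dice < 0.5) {
    warning("registration Dice overlap ", signif(dice, 3),
            " below 0.5: alignment unreliable", call. = FALSE)
  }
  structure(list(transform = tf, dice = dice, mi = -opt$value,
                 resample = resample),
            class = "mask_registration")
}

#' Bland-Altman agreement
#'
#' Differences are taken as x - y (printed in the output); bias is their
#' mean and the 95% limits of agreement are bias +/- 1.96 times the
#' sample (n - 1) standard deviation.
#'
#' @param x,y paired measurements (n >= 2).
#' @return list: `bias`, `loa` (lower, upper), `sd`, `n`, `order`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("Bland-Altman needs at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       sd = s, n = length(d), order = "x - y")
}

#' Intraclass correlation for two paired raters
#'
#' Two-way mixed single-measure ICC from the standard ANOVA mean squares
#' (n subjects, k = 2 raters): both the absolute-agreement form ICC(A,1)
#' and the consistency form ICC(C,1) are returned, with ICC(A,1) as the
#' headline value.
#'
#' @param x,y paired measurements (n >= 3).
#' @return list: `icc` (= `icc_a1`), `icc_a1`, `icc_c1`, mean squares
#'   `msr`, `msc`, `mse`, `n`, `defined`.
#' @export
icc <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("ICC needs at least 3 pairs")
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  mse <- sum((m - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2) / ((n - 1) * (k - 1))
  if (msr == 0 && msc == 0 && mse == 0) {
    return(list(icc = NA_real_, icc_a1 = NA_real_, icc_c1 = NA_real_,
                msr = msr, msc = msc, mse = mse, n = n, defined = FALSE))
  }
  icc_a1 <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  icc_c1 <- (msr - mse) / (msr + (k - 1) * mse)
  list(icc = icc_a1, icc_a1 = icc_a1, icc_c1 = icc_c1,
       msr = msr, msc = msc, mse = mse, n = n, defined = TRUE)
}

#' Full method-agreement summary
#'
#' Bland-Altman bias and limits of agreement, ICC (absolute agreement and
#' consistency), Spearman rho with its two-sided p (midranks for ties),
#' and the R^2 of the ordinary least-squares line, plus optional group
#' tests: Wilcoxon rank-sum (independent groups), Wilcoxon signed-rank or
#' paired t (paired designs). Significance level alpha = 0.05, two-sided.
#'
#' @param x,y paired measurements.
#' @param tests character subset of "wilcoxon" (rank-sum), "signed_rank",
#'   "paired_t".
#' @return list of class `agreement_stats`.
#' @export
agreement_suite <- function(x, y, tests = character()) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  ba <- bland_altman(x, y)
  ic <- if (length(x) >= 3) icc(x, y) else NULL
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  rho_p <- tryCatch(
    suppressWarnings(cor.test(x, y, method = "spearman",
                              exact = FALSE)$p.value),
    error = function(e) NA_real_)
  fit <- lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  res <- list(n = length(x), bland_altman = ba, icc = ic,
              spearman_rho = rho, spearman_p = rho_p, r_squared = r2,
              slope = unname(coef(fit)[2]),
              intercept = unname(coef(fit)[1]), alpha = 0.05)
  if ("wilcoxon" %in% tests) {
    w <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    res$wilcoxon_p <- w$p.value
  }
  if ("signed_rank" %in% tests) {
    res$signed_rank_p <- if (all(x == y)) 1 else
      suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                   exact = FALSE)$p.value)
  }
  if ("paired_t" %in% tests) {
    res$paired_t_p <- t.test(x, y, paired = TRUE)$p.value
  }
  class(res) <- "agreement_stats"
  res
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs (differences: x - y)\n", x$n))
  cat(sprintf("  Bland-Altman bias %+.4g, LoA [%.4g, %.4g]\n",
              x$bland_altman$bias, x$bland_altman$loa[1],
              x$bland_altman$loa[2]))
  if (!is.null(x$icc)) {
    cat(sprintf("  ICC(A,1) %.4f, ICC(C,1) %.4f\n", x$icc$icc_a1,
                x$icc$icc_c1))
  }
  cat(sprintf("  Spearman rho %.4f (p = %.3g), R^2 = %.4f\n",
              x$spearman_rho, x$spearman_p, x$r_squared))
  invisible(x)
}
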