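#' Cardiac coordinate frame
#'
#' Per-slice LV blood-pool centres plus the long axis (the slice-stacking
#' axis, +z ordered base to apex). The local basis at a voxel is: radial
#' r_hat from the slice centre to the voxel (in-plane), longitudinal
#' l_hat = +z, circumferential c_hat = l_hat x r_hat.
#'
#' @param center nz x 2 matrix of physical in-plane centres (um); rows may
#'   be NA for slices without a usable blood pool.
#' @param dim grid size.
#' @param spacing voxel size (um).
#' @param long_axis unit long-axis vector (fixed to +z).
#' @return list of class `lv_frame`.
#' @export
lv_frame <- function(center, dim, spacing, long_axis = c(0, 0, 1)) {
  center <- as.matrix(center)
  stopifnot(ncol(center) == 2, nrow(center) == dim[3])
  structure(list(center = center, dim = as.integer(dim),
                 spacing = rep(as.numeric(spacing), length.out = 3),
                 long_axis = long_axis),
            class = "lv_frame")
}

#' Local orthonormal basis at voxels
#'
#' @param frame an [lv_frame()].
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @return list of n x 3 matrices `r`, `c`, `l` (radial, circumferential,
#'   longitudinal unit vectors).
#' @export
frame_basis <- function(frame, ijk) {
  ctr <- frame$center[ijk[, 3], , drop = FALSE]
  dx <- (ijk[, 1] - 0.5) * frame$spacing[1] - ctr[, 1]
  dy <- (ijk[, 2] - 0.5) * frame$spacing[2] - ctr[, 2]
  nrm <- sqrt(dx^2 + dy^2)
  nrm[nrm == 0] <- NA_real_
  r <- cbind(dx / nrm, dy / nrm, 0)
  cc <- cbind(-r[, 2], r[, 1], 0)  # z x r
  l <- matrix(rep(c(0, 0, 1), each = nrow(ijk)), ncol = 3)
  list(r = r, c = cc, l = l)
}

# flood fill of `open` (logical matrix) from the image border; returns the
# connected background reachable from outside (4-connectivity)
.flood_from_border <- function(open) {
  d <- dim(open)
  reach <- matrix(FALSE, d[1], d[2])
  reach[c(1, d[1]), ] <- open[c(1, d[1]), ]
  reach[, c(1, d[2])] <- reach[, c(1, d[2])] | open[, c(1, d[2])]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-d[1], ]
    grown[-d[1], ] <- grown[-d[1], ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -d[2]]
    grown[, -d[2]] <- grown[, -d[2]] | reach[, -1]
    grown <- grown & open
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

# largest 6-connected 3D component of a logical array
.largest_component <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) <= 1) return(mask)
  rank_arr <- array(0L, d)
  rank_arr[idx] <- seq_along(idx)
  pos <- arrayInd(idx, d)
  elist <- list()
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    nb <- sweep(pos, 2, off, `+`)
    ok <- nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    nbr <- rank_arr[nb[ok, , drop = FALSE]]
    sel <- nbr > 0L
    if (any(sel)) {
      elist[[length(elist) + 1L]] <- cbind(which(ok)[sel], nbr[sel])
    }
  }
  if (length(elist) == 0) {
    out <- array(FALSE, d)
    out[idx[1]] <- TRUE
    return(out)
  }
  ed <- do.call(rbind, elist)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(ed)))
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  out <- array(FALSE, d)
  out[idx[keep]] <- TRUE
  out
}

#' Threshold-based myocardium segmentation
#'
#' Voxels at or above the threshold are kept, reduced to the largest
#' connected component; the enclosed per-slice cavity is returned as the
#' blood pool.
#'
#' @param volume scalar 3D array.
#' @param threshold intensity cutoff.
#' @return list `myocardium` (logical array), `blood_pool` (logical array).
#' @export
myocardium_mask <- function(volume, threshold) {
  stopifnot(length(dim(volume)) == 3)
  mask <- volume >= threshold
  if (!any(mask)) stop("empty mask: threshold ", threshold,
                       " exceeds the maximum intensity")
  mask <- .largest_component(mask)
  pool <- array(FALSE, dim(mask))
  for (k in seq_len(dim(mask)[3])) {
    open <- !mask[, , k]
    if (!any(mask[, , k])) next
    outside <- .flood_from_border(open)
    pool[, , k] <- open & !outside
  }
  list(myocardium = mask, blood_pool = pool)
}

#' Build the cardiac frame from masks
#'
#' Per-slice centre = blood-pool centroid (physical um); slices without a
#' blood pool are skipped with a warning and get NA centres.
#'
#' @param mask myocardium logical array.
#' @param blood_pool blood-pool logical array.
#' @param spacing voxel size (um).
#' @return an [lv_frame()].
#' @export
build_frame <- function(mask, blood_pool, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  spacing <- rep(spacing, length.out = 3)
  ctr <- matrix(NA_real_, d[3], 2)
  skipped <- 0L
  for (k in seq_len(d[3])) {
    bp <- blood_pool[, , k]
    if (!any(bp)) {
      if (any(mask[, , k])) skipped <- skipped + 1L
      next
    }
    w <- which(bp, arr.ind = TRUE)
    ctr[k, ] <- c(mean((w[, 1] - 0.5) * spacing[1]),
                  mean((w[, 2] - 0.5) * spacing[2]))
  }
  if (skipped > 0) {
    warning(skipped, " slice(s) with myocardium but no blood pool skipped")
  }
  lv_frame(center = ctr, dim = d, spacing = spacing)
}

#' Helix-angle map from an orientation field
#'
#' Projects each fiber vector onto the local circumferential-longitudinal
#' tangent plane; HA is the signed angle of that projection from the
#' circumferential direction toward the longitudinal one, in (-90, 90].
#' The sign is canonicalized through the axial symmetry: the
#' circumferential component of the projection is made non-negative (and
#' if it is ~0 the longitudinal one is made positive, giving HA = 90).
#' Positive HA = right-handed (subendocardial-type) helix. Fibers that are
#' nearly radial (tangent-plane projection norm < `min_proj`) are flagged
#' undefined.
#'
#' @param orientation an `orientation_field`.
#' @param frame an [lv_frame()].
#' @param min_proj minimum tangent-plane projection norm.
#' @return numeric 3D array of HA in degrees (NA where undefined).
#' @export
helix_angle <- function(orientation, frame, min_proj = 0.1) {
  stopifnot(inherits(orientation, "orientation_field"),
            inherits(frame, "lv_frame"))
  ijk <- arrayInd(orientation$idx, orientation$dim)
  basis <- frame_basis(frame, ijk)
  f <- orientation$vectors
  fc <- rowSums(f * basis$c)
  fl <- rowSums(f * basis$l)
  pn <- sqrt(fc^2 + fl^2)
  ha <- rep(NA_real_, length(fc))
  ok <- is.finite(pn) & pn >= min_proj
  fc2 <- fc[ok]; fl2 <- fl[ok]
  neg <- fc2 < 0
  fc2[neg] <- -fc2[neg]; fl2[neg] <- -fl2[neg]
  ties <- abs(fc2) < 1e-12
  fl2[ties] <- abs(fl2[ties])
  ha[ok] <- rad2deg(atan2(fl2, fc2))
  ha[ok][ha[ok] <= -90] <- 90
  expand_to_array(ha, orientation$idx, orientation$dim)
}

#' Transmural-depth map by in-plane radial rays
#'
#' For each slice, rays are cast from the slice centre at fine azimuthal
#' steps; the endocardial and epicardial crossings are found by scanning
#' the nearest-voxel mask along the ray at sub-voxel steps and refined to
#' the transition midpoints. Each myocardial voxel takes the boundaries of
#' its azimuthal bin: TD = 100 (r - r_endo) / (r_epi - r_endo), clamped to
#' [0, 100]. Rays whose wall run contains gaps (for example infarct
#' thinning) are flagged invalid and their voxels excluded.
#'
#' @param mask myocardium logical array.
#' @param frame an [lv_frame()].
#' @param n_bins number of azimuthal bins per slice.
#' @param gap_tol minimum fraction of masked samples between the crossings
#'   for a ray to be accepted.
#' @return list of class `td_map`: `td` (3D array, NA outside/invalid),
#'   `boundaries` (data.frame slice, azimuth_deg, r_endo, r_epi, valid),
#'   `n_bins`.
#' @export
transmural_depth <- function(mask, frame, n_bins = 360, gap_tol = 0.95) {
  d <- dim(mask)
  sp <- frame$spacing
  dr <- 0.25 * min(sp[1:2])
  max_r <- sqrt(sum((d[1:2] * sp[1:2])^2)) / 2
  rs <- seq(dr / 2, max_r, by = dr)
  az <- (seq_len(n_bins) - 1) * 2 * pi / n_bins
  td <- array(NA_real_, d)
  bnd <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    if (!any(mask[, , k]) || any(is.na(frame$center[k, ]))) next
    ctr <- frame$center[k, ]
    msl <- mask[, , k]
    re <- rep(NA_real_, n_bins); rp <- rep(NA_real_, n_bins)
    ok <- rep(FALSE, n_bins)
    for (b in seq_len(n_bins)) {
      px <- ctr[1] + rs * cos(az[b])
      py <- ctr[2] + rs * sin(az[b])
      i <- floor(px / sp[1]) + 1L
      j <- floor(py / sp[2]) + 1L
      ins <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
      hit <- rep(FALSE, length(rs))
      hit[ins] <- msl[cbind(i[ins], j[ins])]
      w <- which(hit)
      if (length(w) < 2) next
      first <- w[1]; last <- w[length(w)]
      frac <- length(w) / (last - first + 1)
      re[b] <- rs[first] - dr / 2
      rp[b] <- rs[last] + dr / 2
      ok[b] <- frac >= gap_tol
    }
    bnd[[k]] <- data.frame(slice = k, azimuth_deg = rad2deg(az),
                           r_endo = re, r_epi = rp, valid = ok)
    # assign voxels
    w <- which(msl, arr.ind = TRUE)
    dx <- (w[, 1] - 0.5) * sp[1] - ctr[1]
    dy <- (w[, 2] - 0.5) * sp[2] - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx) %% (2 * pi)
    bin <- floor(th / (2 * pi / n_bins)) + 1L
    bin[bin > n_bins] <- 1L
    good <- ok[bin] & !is.na(re[bin])
    val <- 100 * (r - re[bin]) / (rp[bin] - re[bin])
    val <- pmin(pmax(val, 0), 100)
    val[!good] <- NA_real_
    sl <- td[, , k]
    sl[w] <- val
    td[, , k] <- sl
  }
  structure(list(td = td, boundaries = do.call(rbind, bnd), n_bins = n_bins),
            class = "td_map")
}
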