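#' Extract radial HA-vs-TD profiles
#'
#' Per slice, `n_rays` equally spaced azimuths (starting at
#' `ref_azimuth`); along each ray the helix angle is sampled by
#' nearest-voxel lookup at `n_stations` equally spaced transmural-depth
#' stations (station k at TD = (k - 1/2) * 100 / n_stations), using the
#' wall boundaries of the [transmural_depth()] map. Profiles retaining
#' fewer than `min_samples` valid stations are dropped and counted.
#'
#' @param ha helix-angle 3D array (degrees, NA = undefined).
#' @param td a `td_map` from [transmural_depth()].
#' @param frame the [lv_frame()].
#' @param n_rays rays per slice (default 20, i.e. 18 degrees apart).
#' @param n_stations transmural stations per ray (default 8 blocks).
#' @param ref_azimuth reference azimuth of ray 1, degrees from +x.
#' @param region optional integer array of region labels sampled alongside.
#' @param min_samples minimum valid stations to keep a profile.
#' @return list of class `radial_profiles`: `samples` (data.frame slice,
#'   ray, azimuth_deg, td, ha, region), `n_rays`, `n_stations`,
#'   `dropped`, `ref_azimuth`.
#' @export
extract_profiles <- function(ha, td, frame, n_rays = 20, n_stations = 8,
                             ref_azimuth = 0, region = NULL,
                             min_samples = 4) {
  stopifnot(inherits(td, "td_map"), inherits(frame, "lv_frame"))
  d <- dim(ha)
  sp <- frame$spacing
  bnd <- td$boundaries
  az_step <- 360 / n_rays
  td_stations <- (seq_len(n_stations) - 0.5) * 100 / n_stations
  rows <- list()
  dropped <- 0L
  for (k in sort(unique(bnd$slice))) {
    bk <- bnd[bnd$slice == k, ]
    ctr <- frame$center[k, ]
    if (any(is.na(ctr))) next
    for (j in seq_len(n_rays)) {
      az <- (ref_azimuth + (j - 1) * az_step) %% 360
      bin <- (round(az / 360 * td$n_bins) %% td$n_bins) + 1L
      if (!isTRUE(bk$valid[bin]) || is.na(bk$r_endo[bin])) {
        dropped <- dropped + 1L
        next
      }
      rk <- bk$r_endo[bin] + td_stations / 100 * (bk$r_epi[bin] - bk$r_endo[bin])
      px <- ctr[1] + rk * cos(deg2rad(az))
      py <- ctr[2] + rk * sin(deg2rad(az))
      i <- floor(px / sp[1]) + 1L
      jj <- floor(py / sp[2]) + 1L
      ins <- i >= 1 & i <= d[1] & jj >= 1 & jj <= d[2]
      hav <- rep(NA_real_, n_stations)
      hav[ins] <- ha[cbind(i[ins], jj[ins], k)]
      reg <- rep(NA_integer_, n_stations)
      if (!is.null(region)) reg[ins] <- region[cbind(i[ins], jj[ins], k)]
      ok <- is.finite(hav)
      if (sum(ok) < min_samples) {
        dropped <- dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(slice = k, ray = j, azimuth_deg = az,
                   td = td_stations[ok], ha = hav[ok],
                   region = if (is.null(region)) NA_integer_ else reg[ok])
    }
  }
  samples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice = integer(), ray = integer(), azimuth_deg = numeric(),
               td = numeric(), ha = numeric(), region = integer())
  structure(list(samples = samples, n_rays = n_rays,
                 n_stations = n_stations, dropped = dropped,
                 ref_azimuth = ref_azimuth),
            class = "radial_profiles")
}

#' Ordinary least-squares slope of one HA-vs-TD profile
#'
#' Fits HA = a + s TD; returns the slope s in degrees per %TD. Profiles
#' with fewer than 4 samples or a TD spread under 10 %TD are rejected
#' (NA slope).
#'
#' @param profile data.frame with columns `td` and `ha` (or a numeric
#'   vector of TD with `ha` supplied separately).
#' @param ha helix angles if `profile` is a numeric TD vector.
#' @return list with `slope`, `intercept`, `n`, `rejected` (character or
#'   NA).
#' @export
fit_profile_slope <- function(profile, ha = NULL) {
  if (is.data.frame(profile)) {
    td <- profile$td; hav <- profile$ha
  } else {
    td <- profile; hav <- ha
  }
  ok <- is.finite(td) & is.finite(hav)
  td <- td[ok]; hav <- hav[ok]
  if (length(td) < 4) {
    return(list(slope = NA_real_, intercept = NA_real_, n = length(td),
                rejected = "fewer than 4 samples"))
  }
  if (diff(range(td)) < 10) {
    return(list(slope = NA_real_, intercept = NA_real_, n = length(td),
                rejected = "TD spread below 10 %TD"))
  }
  s <- sum((td - mean(td)) * (hav - mean(hav))) / sum((td - mean(td))^2)
  list(slope = s, intercept = mean(hav) - s * mean(td), n = length(td),
       rejected = NA_character_)
}

#' Fit slopes for all profiles
#'
#' @param profiles a `radial_profiles`.
#' @return data.frame of class `profile_fits`: slice, ray, azimuth_deg,
#'   slope, intercept, n, region (majority non-infarct label), infarct
#'   (TRUE if any sample lies in the infarct label).
#' @export
fit_profiles <- function(profiles) {
  stopifnot(inherits(profiles, "radial_profiles"))
  s <- profiles$samples
  keyed <- split(s, list(s$slice, s$ray), drop = TRUE)
  out <- do.call(rbind, lapply(keyed, function(p) {
    f <- fit_profile_slope(p)
    regs <- p$region[!is.na(p$region)]
    infarct <- any(regs == REGION_INFARCT)
    non_inf <- regs[regs != REGION_INFARCT]
    maj <- if (length(non_inf)) {
      as.integer(names(which.max(table(non_inf))))
    } else NA_integer_
    data.frame(slice = p$slice[1], ray = p$ray[1],
               azimuth_deg = p$azimuth_deg[1], slope = f$slope,
               intercept = f$intercept, n = f$n,
               region = maj, infarct = infarct)
  }))
  out <- out[order(out$slice, out$ray), ]
  rownames(out) <- NULL
  class(out) <- c("profile_fits", "data.frame")
  out
}

.as_fits <- function(x) {
  if (inherits(x, "radial_profiles")) fit_profiles(x)
  else if (inherits(x, "profile_fits") || is.data.frame(x)) x
  else stop("expected radial_profiles or profile_fits")
}

#' Global helix-angle transmurality
#'
#' Global HAT is the unweighted arithmetic mean of the accepted
#' per-profile slopes (degrees per %TD); the signed value and its
#' magnitude are both reported, along with per-slice means. With the
#' right-handed-positive endocardial convention the signed slope of a
#' normal heart is negative.
#'
#' @param x `radial_profiles` or `profile_fits`.
#' @param exclude_infarct drop profiles whose samples cross the infarct
#'   label before averaging.
#' @return list of class `hat_result`: `fits`, `global_signed`,
#'   `global_abs`, `per_slice`, `n_profiles`.
#' @export
global_hat <- function(x, exclude_infarct = TRUE) {
  fits <- .as_fits(x)
  keep <- is.finite(fits$slope)
  if (exclude_infarct) keep <- keep & !(fits$infarct %in% TRUE)
  acc <- fits[keep, ]
  if (nrow(acc) == 0) stop("no accepted profiles: cannot compute global HAT")
  gs <- mean(acc$slope)
  per_slice <- aggregate(slope ~ slice, data = acc, FUN = mean)
  structure(list(fits = fits, global_signed = gs, global_abs = abs(gs),
                 per_slice = per_slice, n_profiles = nrow(acc)),
            class = "hat_result")
}

#' @export
print.hat_result <- function(x, ...) {
  cat(sprintf("Global HAT: %+.4f deg/%%TD (|HAT| = %.4f) from %d profiles\n",
              x$global_signed, x$global_abs, x$n_profiles))
  invisible(x)
}

# AHA-16 azimuthal segment index for one level given azimuth (deg from the
# package's reference axis); basal/mid use six 60-degree sectors, apical
# four 90-degree sectors.
.aha_segment <- function(level, azimuth) {
  az <- azimuth %% 360
  if (level == "basal") floor(az / 60) + 1
  else if (level == "mid") floor(az / 60) + 7
  else floor(az / 90) + 13
}

#' AHA 16-segment regional HAT
#'
#' Slices are labelled basal/mid/apical by thirds of the analysed
#' long-axis extent (slice 1 = base); within each level, profiles are
#' binned azimuthally into the standard 6/6/4 partition (segment 1
#' anchored at the package's reference azimuth; real-data use should
#' supply the RV-insertion anchor via `ref_azimuth` of
#' [extract_profiles()]). A segment containing any infarct-crossing
#' profile is omitted (NA with `omitted = TRUE`), never zero-filled.
#'
#' @param x `radial_profiles` or `profile_fits`.
#' @return data.frame: segment (1-16), level, hat, n, omitted.
#' @export
aha16_bin <- function(x) {
  fits <- .as_fits(x)
  slices <- sort(unique(fits$slice))
  ns <- length(slices)
  third <- ceiling(seq_along(slices) / (ns / 3))
  third[third > 3] <- 3
  level_of <- setNames(c("basal", "mid", "apical")[third], slices)
  fits$level <- level_of[as.character(fits$slice)]
  fits$segment <- mapply(.aha_segment, fits$level, fits$azimuth_deg)
  out <- data.frame(segment = 1:16,
                    level = c(rep("basal", 6), rep("mid", 6),
                              rep("apical", 4)),
                    hat = NA_real_, n = 0L, omitted = FALSE)
  for (sgm in 1:16) {
    m <- fits[fits$segment == sgm, ]
    if (nrow(m) == 0) next
    if (any(m$infarct %in% TRUE)) {
      out$omitted[sgm] <- TRUE
      next
    }
    sl <- m$slope[is.finite(m$slope)]
    if (length(sl)) {
      out$hat[sgm] <- mean(sl)
      out$n[sgm] <- length(sl)
    }
  }
  out
}

#' Radial (3.6-degree) segmental HAT
#'
#' Pools profile slopes across slices into azimuthal bins of
#' `bin_width` degrees (default 3.6, i.e. 100 segments spanning 360
#' degrees) and averages within each bin. Empty bins are NA.
#'
#' @param x `radial_profiles` or `profile_fits`.
#' @param bin_width azimuthal bin width in degrees.
#' @param exclude_infarct drop infarct-crossing profiles first.
#' @return data.frame: bin, azimuth_mid, hat, n.
#' @export
radial_segment_bin <- function(x, bin_width = 3.6, exclude_infarct = TRUE) {
  fits <- .as_fits(x)
  n_bins <- round(360 / bin_width)
  keep <- is.finite(fits$slope)
  if (exclude_infarct) keep <- keep & !(fits$infarct %in% TRUE)
  fits <- fits[keep, ]
  bin <- floor((fits$azimuth_deg %% 360) / bin_width) + 1L
  bin[bin > n_bins] <- n_bins
  out <- data.frame(bin = seq_len(n_bins),
                    azimuth_mid = (seq_len(n_bins) - 0.5) * bin_width,
                    hat = NA_real_, n = 0L)
  if (nrow(fits)) {
    agg <- aggregate(slope ~ bin, data = cbind(fits, bin = bin), FUN = mean)
    cnt <- table(bin)
    out$hat[agg$bin] <- agg$slope
    out$n[as.integer(names(cnt))] <- as.integer(cnt)
  }
  out
}

#' Mean-diffusivity infarct zoning
#'
#' Labels the myocardium by the published MD thresholds: infarct
#' MD > 1.12 um^2/ms, peri-infarct 0.9 < MD <= 1.12, remote MD <= 0.9.
#' Infarct voxels are excluded from all HAT statistics downstream.
#'
#' @param md MD array in um^2/ms (NA outside the fit).
#' @param mask optional myocardium mask; default voxels with finite MD.
#' @param infarct_threshold,peri_threshold zone cutoffs in um^2/ms.
#' @return integer array: 0 background, 1 remote, 2 peri-infarct,
#'   3 infarct.
#' @export
md_region_masks <- function(md, mask = NULL, infarct_threshold = 1.12,
                            peri_threshold = 0.9) {
  if (is.null(mask)) mask <- is.finite(md)
  vals <- md[mask]
  if (any(is.finite(vals) & (vals < 0 | vals > 4))) {
    warning("MD values outside [0, 4] um^2/ms: check units")
  }
  labels <- array(REGION_BACKGROUND, dim(md))
  labels[mask & is.finite(md) & md <= peri_threshold] <- REGION_REMOTE
  labels[mask & is.finite(md) & md > peri_threshold &
           md <= infarct_threshold] <- REGION_PERI
  labels[mask & is.finite(md) & md > infarct_threshold] <- REGION_INFARCT
  labels
}

#' HAT by infarct zone
#'
#' Mean profile slope for peri-infarct and remote profiles (profile zone =
#' majority non-infarct label of its samples; infarct-crossing profiles
#' excluded).
#'
#' @param x `radial_profiles` or `profile_fits` extracted with a `region`
#'   array.
#' @return data.frame: region ("remote", "peri_infarct"), hat, n.
#' @export
region_hat <- function(x) {
  fits <- .as_fits(x)
  fits <- fits[is.finite(fits$slope) & !(fits$infarct %in% TRUE) &
                 !is.na(fits$region), ]
  out <- data.frame(region = c("remote", "peri_infarct"),
                    hat = NA_real_, n = 0L)
  for (i in 1:2) {
    code <- c(REGION_REMOTE, REGION_PERI)[i]
    m <- fits[fits$region == code, ]
    if (nrow(m)) {
      out$hat[i] <- mean(m$slope)
      out$n[i] <- nrow(m)
    }
  }
  out
}
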