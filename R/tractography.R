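#' Sub-voxel seed grid for tractography
#'
#' Places `subdivisions`^3 uniformly spaced seeds inside every masked
#' voxel (the reference configuration of 10 subdivisions gives 1000
#' sub-voxels per voxel); `subdivisions = 1` gives voxel centres.
#'
#' @param mask logical 3D array.
#' @param spacing voxel size in um.
#' @param subdivisions per-axis subdivision count.
#' @return n x 3 matrix of physical seed coordinates (um).
#' @export
seed_grid <- function(mask, spacing = c(1, 1, 1), subdivisions = 10) {
  stopifnot(subdivisions >= 1)
  spacing <- rep(spacing, length.out = 3)
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask: nothing to seed")
  ijk <- arrayInd(idx, dim(mask))
  off <- ((seq_len(subdivisions) - 0.5) / subdivisions) - 0.5
  grid <- as.matrix(expand.grid(ox = off, oy = off, oz = off))
  seeds <- matrix(NA_real_, nrow(ijk) * nrow(grid), 3)
  row <- 1L
  for (v in seq_len(nrow(ijk))) {
    ctr <- (ijk[v, ] - 0.5) * spacing
    block <- sweep(grid, 2, spacing, `*`)
    seeds[row:(row + nrow(grid) - 1L), ] <- sweep(block, 2, ctr, `+`)
    row <- row + nrow(grid)
  }
  seeds
}

# one direction of FACT integration from a start point
.fact_one_way <- function(pos, dir0, e1x, e1y, e1z, mask, spacing, step,
                          cos_thresh, max_steps) {
  d <- dim(mask)
  pts <- matrix(NA_real_, max_steps + 1L, 3)
  pts[1, ] <- pos
  vox <- floor(pos / spacing) + 1L
  prev <- dir0
  reason <- "max length"
  np <- 1L
  for (s in seq_len(max_steps)) {
    v <- cbind(vox[1], vox[2], vox[3])
    dirv <- c(e1x[v], e1y[v], e1z[v])
    if (!all(is.finite(dirv)) || sum(dirv^2) == 0) {
      reason <- "mask exit"
      break
    }
    if (sum(dirv * prev) < 0) dirv <- -dirv
    ct <- sum(dirv * prev)
    if (!is.null(prev) && ct < cos_thresh && s > 1) {
      reason <- "angle threshold"
      break
    }
    pos <- pos + step * dirv
    vox <- floor(pos / spacing) + 1L
    if (any(vox < 1) || any(vox > d)) {
      reason <- "mask exit"
      np <- np + 1L
      pts[np, ] <- pos
      break
    }
    if (!mask[vox[1], vox[2], vox[3]]) {
      reason <- "mask exit"
      np <- np + 1L
      pts[np, ] <- pos
      break
    }
    np <- np + 1L
    pts[np, ] <- pos
    prev <- dirv
  }
  list(points = pts[seq_len(np), , drop = FALSE], reason = reason)
}

#' FACT streamline tractography
#'
#' Fiber Assignment by Continuous Tracking: from each seed the streamline
#' steps along the primary eigenvector of the voxel it currently occupies
#' (the orientation is constant within a voxel), bidirectionally, with the
#' vector sign chosen per step to keep the turning angle at or below 90
#' degrees. Tracking terminates on mask exit, an inter-voxel turning
#' angle above `angle_threshold`, or `max_steps`. Deterministic: no
#' randomness is involved.
#'
#' @param orientation an `orientation_field` (unit e1 per voxel).
#' @param seeds n x 3 matrix of physical start points (um), e.g. from
#'   [seed_grid()]; seeds outside the mask are skipped.
#' @param mask tracking mask (default: voxels carrying an orientation).
#' @param step step length in um (default half the smallest voxel
#'   dimension).
#' @param angle_threshold maximum inter-voxel turning angle, degrees.
#' @param max_steps maximum steps per direction.
#' @param frame optional [lv_frame()]; when given, per-point helix angles
#'   are attached.
#' @return list of class `streamline_set`; each element has `points`
#'   (m x 3 um), `reasons` (termination reason of each end), and `ha`
#'   (per-point helix angle when a frame was supplied).
#' @export
fact_track <- function(orientation, seeds, mask = NULL, step = NULL,
                       angle_threshold = 60, max_steps = 5000,
                       frame = NULL) {
  stopifnot(inherits(orientation, "orientation_field"))
  d <- orientation$dim
  spacing <- orientation$spacing
  if (is.null(step)) step <- 0.5 * min(spacing)
  if (step > min(spacing)) stop("step must not exceed the voxel size")
  e1x <- expand_to_array(orientation$vectors[, 1], orientation$idx, d)
  e1y <- expand_to_array(orientation$vectors[, 2], orientation$idx, d)
  e1z <- expand_to_array(orientation$vectors[, 3], orientation$idx, d)
  if (is.null(mask)) {
    mask <- array(FALSE, d)
    mask[orientation$idx] <- TRUE
  }
  cos_thresh <- cos(deg2rad(angle_threshold))
  out <- list()
  for (i in seq_len(nrow(seeds))) {
    pos <- seeds[i, ]
    vox <- floor(pos / spacing) + 1L
    if (any(vox < 1) || any(vox > d) || !mask[vox[1], vox[2], vox[3]]) next
    dir0 <- c(e1x[vox[1], vox[2], vox[3]], e1y[vox[1], vox[2], vox[3]],
              e1z[vox[1], vox[2], vox[3]])
    if (!all(is.finite(dir0)) || sum(dir0^2) == 0) next
    fwd <- .fact_one_way(pos, dir0, e1x, e1y, e1z, mask, spacing, step,
                         cos_thresh, max_steps)
    bwd <- .fact_one_way(pos, -dir0, e1x, e1y, e1z, mask, spacing, step,
                         cos_thresh, max_steps)
    pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))[-1]), , drop = FALSE],
                 fwd$points)
    sl <- list(points = pts, reasons = c(backward = bwd$reason,
                                         forward = fwd$reason), seed = pos)
    if (!is.null(frame)) {
      vz <- pmin(pmax(floor(pts / matrix(spacing, nrow(pts), 3,
                                         byrow = TRUE)) + 1L, 1L),
                 matrix(d, nrow(pts), 3, byrow = TRUE))
      # per-point HA from the step directions
      dirs <- diff(pts)
      dirs <- rbind(dirs, dirs[nrow(dirs), , drop = FALSE])
      dirs <- unit_rows(dirs)
      basis <- frame_basis(frame, vz)
      fc <- rowSums(dirs * basis$c)
      fl <- rowSums(dirs * basis$l)
      neg <- fc < 0 & !is.na(fc)
      fc[neg] <- -fc[neg]; fl[neg] <- -fl[neg]
      sl$ha <- rad2deg(atan2(fl, fc))
    }
    out[[length(out) + 1L]] <- sl
  }
  structure(out, class = "streamline_set")
}

#' Write streamlines as JSON lines
#'
#' One JSON object per line with the point list (um), per-point HA when
#' present, and termination reasons. Coordinates are physical: 0-based
#' voxel index * spacing + spacing/2.
#'
#' @param streamlines a `streamline_set`.
#' @param path output file.
#' @export
write_streamlines_json <- function(streamlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sl in streamlines) {
    rec <- list(points = unname(apply(sl$points, 1, as.numeric,
                                      simplify = FALSE)),
                reasons = as.list(sl$reasons))
    if (!is.null(sl$ha)) rec$ha <- as.numeric(sl$ha)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
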