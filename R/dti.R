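#' Log-linear least-squares diffusion tensor fit
#'
#' Solves ln S = ln S0 - b g' D g per voxel by ordinary least squares over
#' the seven unknowns (six tensor components plus ln S0), exactly as an
#' unweighted log-linear fit. The b-matrix is b g g' with no imaging
#' cross-term correction. Non-positive signals are clamped to a floor of
#' 1e-6 times the maximum b = 0 signal before taking the log; voxels with
#' at least half their signals non-positive are masked out rather than
#' fitted.
#'
#' @param dwi a `dwi_stack` (or a 4D array with volumes last).
#' @param protocol a [dwi_protocol()]; taken from `dwi` if absent.
#' @param mask logical array of voxels to fit; default voxels whose b = 0
#'   mean exceeds zero.
#' @return list of class `tensor_field`: `comps` (n x 6 matrix, um^2/ms,
#'   order xx, yy, zz, xy, xz, yz), `log_s0`, `idx` (linear voxel indices),
#'   `valid`, `dim`, `spacing`.
#' @export
fit_tensor_loglinear <- function(dwi, protocol = NULL, mask = NULL) {
  if (inherits(dwi, "dwi_stack")) {
    if (is.null(protocol)) protocol <- dwi$protocol
    spacing <- dwi$spacing
    data <- dwi$data
  } else {
    data <- dwi
    spacing <- c(1, 1, 1)
  }
  stopifnot(inherits(protocol, "dwi_protocol"), length(dim(data)) == 4)
  d <- dim(data)[1:3]
  nvol <- dim(data)[4]
  if (nvol != length(protocol$bvals)) {
    stop(sprintf("stack has %d volumes but protocol lists %d", nvol,
                 length(protocol$bvals)))
  }
  if (.n_unique_axes(protocol) < 6) {
    stop("fewer than 6 non-collinear diffusion directions: tensor fit is ",
         "underdetermined")
  }
  b <- protocol$bvals * 1e-3  # s/mm^2 -> ms/um^2 so D comes out in um^2/ms
  g <- protocol$bvecs
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  qx <- qr(X)
  if (qx$rank < 7) {
    stop("rank-deficient design matrix: the direction set does not span ",
         "the six tensor components (rank ", qx$rank, " of 7)")
  }
  S <- matrix(aperm(data, c(4, 1, 2, 3)), nrow = nvol)
  b0mean <- colMeans(S[protocol$bvals == 0, , drop = FALSE])
  if (is.null(mask)) mask <- array(b0mean > 0, d)
  idx <- which(mask)
  S <- S[, idx, drop = FALSE]
  nonpos <- colSums(S <= 0)
  valid <- nonpos < nvol / 2
  floorv <- 1e-6 * max(S[protocol$bvals == 0, , drop = FALSE], 0)
  if (floorv <= 0) floorv <- .Machine$double.xmin
  S[S < floorv] <- floorv
  coefs <- qr.coef(qx, log(S))
  comps <- t(coefs[2:7, , drop = FALSE])
  colnames(comps) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  valid <- valid & apply(is.finite(comps), 1, all)
  structure(list(comps = comps, log_s0 = coefs[1, ], idx = idx,
                 valid = valid, dim = d, spacing = spacing),
            class = "tensor_field")
}

#' Eigendecomposition of a tensor field
#'
#' Eigenvalues are returned in descending order with orthonormal
#' eigenvectors. The primary eigenvector is canonicalized to the
#' hemisphere with a non-negative dot product against the local
#' circumferential direction when a frame is supplied, otherwise against
#' +x. Nearly isotropic voxels are flagged degenerate.
#'
#' @param tensors a `tensor_field`.
#' @param frame optional [lv_frame] for sign canonicalization.
#' @param degenerate_tol relative eigenvalue spread below which a voxel is
#'   flagged degenerate.
#' @return list of class `eigen_system`: `values` (n x 3), `vectors`
#'   (n x 9: e1, e2, e3), `idx`, `valid`, `degenerate`, `dim`, `spacing`.
#' @export
eigendecompose <- function(tensors, frame = NULL, degenerate_tol = 1e-6) {
  stopifnot(inherits(tensors, "tensor_field"))
  comps <- tensors$comps
  bad <- !apply(is.finite(comps), 1, all)
  comps[bad, ] <- 0
  es <- eig_sym3_batch(comps)
  values <- es$values
  vectors <- es$vectors
  valid <- tensors$valid & !bad
  spread <- (values[, 1] - values[, 3]) / pmax(abs(values[, 1]), .Machine$double.eps)
  degen <- valid & spread < degenerate_tol
  e1 <- vectors[, 1:3, drop = FALSE]
  refdir <- if (!is.null(frame)) {
    ijk <- arrayInd(tensors$idx, tensors$dim)
    frame_basis(frame, ijk)$c
  } else {
    matrix(rep(c(1, 0, 0), each = nrow(e1)), ncol = 3)
  }
  dp <- rowSums(e1 * refdir)
  flip <- dp < 0
  vectors[flip, 1:3] <- -vectors[flip, 1:3, drop = FALSE]
  structure(list(values = values, vectors = vectors, idx = tensors$idx,
                 valid = valid, degenerate = degen, dim = tensors$dim,
                 spacing = tensors$spacing),
            class = "eigen_system")
}

#' Mean diffusivity map
#'
#' MD = (l1 + l2 + l3) / 3 per voxel, as a 3D array (NA outside the fitted
#' voxels and at invalid fits).
#'
#' @param eigs an `eigen_system`.
#' @return numeric 3D array in um^2/ms.
#' @export
mean_diffusivity <- function(eigs) {
  stopifnot(inherits(eigs, "eigen_system"))
  md <- rowMeans(eigs$values)
  md[!eigs$valid] <- NA_real_
  expand_to_array(md, eigs$idx, eigs$dim)
}

#' Primary-eigenvector orientation field
#'
#' Extracts e1 as an axial orientation field for helix-angle analysis.
#' Invalid or degenerate voxels are excluded.
#'
#' @param eigs an `eigen_system`.
#' @return list of class `orientation_field`: `idx`, `vectors` (n x 3),
#'   `dim`, `spacing`.
#' @export
primary_orientation <- function(eigs) {
  stopifnot(inherits(eigs, "eigen_system"))
  keep <- eigs$valid & !eigs$degenerate
  structure(list(idx = eigs$idx[keep],
                 vectors = eigs$vectors[keep, 1:3, drop = FALSE],
                 dim = eigs$dim, spacing = eigs$spacing),
            class = "orientation_field")
}

#' Build an orientation field from a 4D vector array
#'
#' @param vec 4D array (x, y, z, component); zero vectors mark voxels
#'   without orientation.
#' @param spacing voxel size in um.
#' @return an `orientation_field`.
#' @export
orientation_field <- function(vec, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(vec)) == 4, dim(vec)[4] == 3)
  d <- dim(vec)[1:3]
  m <- cbind(as.numeric(vec[, , , 1]), as.numeric(vec[, , , 2]),
             as.numeric(vec[, , , 3]))
  nrm <- sqrt(rowSums(m^2))
  idx <- which(nrm > 0 & is.finite(nrm))
  structure(list(idx = idx, vectors = unit_rows(m[idx, , drop = FALSE]),
                 dim = d, spacing = rep(spacing, length.out = 3)),
            class = "orientation_field")
}
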