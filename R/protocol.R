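#' Diffusion-weighting protocol
#'
#' Bundles per-volume b-values (s/mm^2) and unit gradient directions. The
#' direction of a b = 0 entry is the zero vector.
#'
#' @param bvals numeric vector, one b-value per volume.
#' @param bvecs 3 x n or n x 3 matrix of gradient directions.
#' @return object of class `dwi_protocol` with elements `bvals` and
#'   `bvecs` (n x 3, rows unit-norm for b > 0).
#' @export
dwi_protocol <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3 && ncol(bvecs) != 3) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3) stop("bvecs must be a 3 x n or n x 3 matrix")
  if (length(bvals) != nrow(bvecs)) {
    stop(sprintf("protocol mismatch: %d b-values but %d directions",
                 length(bvals), nrow(bvecs)))
  }
  nb0 <- sum(bvals == 0)
  if (nb0 < 1) stop("protocol needs at least one b = 0 volume")
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(abs(nrm[dw] - 1) > 1e-4)) {
    stop("non-unit gradient direction for a b > 0 volume (norm ",
         paste(signif(nrm[dw][abs(nrm[dw] - 1) > 1e-4], 4), collapse = ", "), ")")
  }
  bvecs[!dw, ] <- 0
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "dwi_protocol")
}

#' @export
print.dwi_protocol <- function(x, ...) {
  cat("DWI protocol:", length(x$bvals), "volumes (",
      sum(x$bvals == 0), "b=0,", sum(x$bvals > 0), "diffusion-weighted)\n")
  cat("  b-values:", paste(unique(x$bvals), collapse = ", "), "s/mm^2\n")
  invisible(x)
}

#' Electrostatic-repulsion gradient direction set
#'
#' Generates `n` unit vectors on the hemisphere by minimising the
#' antipodally symmetric Coulomb energy (sum over pairs of 1/d^2 for both
#' the point and its antipode), starting from a Fibonacci hemisphere
#' lattice. Fully deterministic: no random numbers are used.
#'
#' @param n number of directions.
#' @param iters descent iterations.
#' @param lr step size of the projected gradient descent.
#' @return n x 3 matrix of unit directions.
#' @export
electrostatic_directions <- function(n, iters = 400, lr = 0.01) {
  stopifnot(n >= 3)
  i <- seq_len(n) - 0.5
  z <- i / n                       # upper hemisphere
  phi <- i * pi * (3 - sqrt(5))    # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  p <- cbind(r * cos(phi), r * sin(phi), z)
  for (it in seq_len(iters)) {
    g <- matrix(0, n, 3)
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        for (s in c(1, -1)) {
          d <- p[a, ] - s * p[b, ]
          dd <- sum(d^2)
          if (dd < 1e-12) next
          f <- d / dd^2            # gradient of 1/d^2 up to constant
          g[a, ] <- g[a, ] + f
          g[b, ] <- g[b, ] - s * f
        }
      }
    }
    p <- p + lr * g
    p <- unit_rows(p)
  }
  # canonical hemisphere and stable ordering
  flip <- p[, 3] < 0 | (p[, 3] == 0 & p[, 1] < 0)
  p[flip, ] <- -p[flip, ]
  p[order(p[, 3], atan2(p[, 2], p[, 1])), , drop = FALSE]
}

#' Reference 12-direction protocol
#'
#' One b = 0 volume followed by twelve diffusion-weighted volumes at the
#' given b-value, with directions from [electrostatic_directions()].
#'
#' @param b diffusion weighting in s/mm^2 (default 1000).
#' @param n_dirs number of diffusion directions (default 12).
#' @return a [dwi_protocol()].
#' @export
default_protocol12 <- function(b = 1000, n_dirs = 12) {
  key <- paste0("dirs_", n_dirs)
  dirs <- .protocol_cache[[key]]
  if (is.null(dirs)) {
    dirs <- electrostatic_directions(n_dirs)
    .protocol_cache[[key]] <- dirs
  }
  dwi_protocol(c(0, rep(b, n_dirs)), rbind(c(0, 0, 0), dirs))
}

.protocol_cache <- new.env(parent = emptyenv())
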