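#' Diffusion gradient scheme
#'
#' A gradient scheme pairs one b-value (s/mm^2) with one unit gradient
#' direction per acquired volume. Directions for b = 0 volumes are ignored
#' (stored as zero vectors).
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs numeric n x 3 matrix of gradient directions (world frame);
#'   rows with b > 0 must have unit norm.
#' @return An object of class `gradient_scheme` with elements `bvals` and
#'   `bvecs`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stop("bvecs must be an n x 3 matrix")
  if (length(bvals) != nrow(bvecs)) {
    stop("bvals and bvecs describe different numbers of volumes")
  }
  if (!any(bvals == 0)) stop("scheme must contain at least one b = 0 volume")
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-6
  if (any(bad)) {
    stop("non-unit gradient direction for b > 0 volume(s): ",
         paste(which(bad), collapse = ", "))
  }
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("gradient_scheme:", length(x$bvals), "volumes (",
      sum(x$bvals == 0), "b=0,", sum(x$bvals > 0), "DW ), b =",
      paste(unique(x$bvals[x$bvals > 0]), collapse = "/"), "s/mm^2\n")
  invisible(x)
}

#' Evenly distributed gradient directions by electrostatic repulsion
#'
#' Starts from a Fibonacci-spiral hemisphere and relaxes the point set by
#' minimizing the antipodally symmetric Coulomb energy
#' sum over pairs of 1/|d_i - d_j| + 1/|d_i + d_j|. Fully deterministic.
#'
#' @param n number of unique directions.
#' @param n_iter relaxation iterations.
#' @return n x 3 matrix of unit directions.
#' @export
repulsion_directions <- function(n, n_iter = 200L) {
  stopifnot(n >= 3)
  # Fibonacci hemisphere start
  i <- seq_len(n) - 0.5
  z <- i / n                       # upper hemisphere
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(r * cos(phi), r * sin(phi), z)
  lr <- 0.05
  for (it in seq_len(n_iter)) {
    frc <- matrix(0, n, 3)
    for (k in seq_len(n)) {
      dif1 <- sweep(d[-k, , drop = FALSE], 2, d[k, ], "-")
      dif2 <- sweep(-d[-k, , drop = FALSE], 2, d[k, ], "-")
      r1 <- pmax(rowSums(dif1^2), 1e-8)
      r2 <- pmax(rowSums(dif2^2), 1e-8)
      frc[k, ] <- -colSums(dif1 / r1^1.5) - colSums(dif2 / r2^1.5)
    }
    d <- d + lr * frc
    d <- d / sqrt(rowSums(d^2))
    lr <- lr * 0.985
  }
  # canonical orientation: positive z (axes are sign-invariant)
  flip <- d[, 3] < 0
  d[flip, ] <- -d[flip, ]
  d
}

#' Default single-shell acquisition scheme
#'
#' b = 1000 s/mm^2 with 40 unique repulsion-optimized directions plus
#' 3 interleaved b = 0 volumes (b0 first).
#'
#' @param n_dirs number of diffusion-weighted directions.
#' @param n_b0 number of b = 0 volumes.
#' @param bval shell b-value (s/mm^2).
#' @return A [gradient_scheme()].
#' @export
default_scheme <- function(n_dirs = 40L, n_b0 = 3L, bval = 1000) {
  d <- repulsion_directions(n_dirs)
  bvals <- c(rep(0, n_b0), rep(bval, n_dirs))
  bvecs <- rbind(matrix(0, n_b0, 3), d)
  gradient_scheme(bvals, bvecs)
}

#' Read and write FSL-dialect gradient tables
#'
#' The bvec file holds 3 rows by n columns (x, y, z components); the bval
#' file one row of n b-values.
#'
#' @param bvec_path,bval_path file paths.
#' @return [read_gradients()] returns a [gradient_scheme()].
#' @export
read_gradients <- function(bvec_path, bval_path) {
  bvec <- as.matrix(read.table(bvec_path))
  bval <- as.numeric(read.table(bval_path))
  if (nrow(bvec) != 3L) {
    stop("malformed bvec file '", bvec_path, "': expected 3 rows, found ",
         nrow(bvec))
  }
  if (ncol(bvec) != length(bval)) {
    stop("bvec/bval length mismatch: '", bvec_path, "' has ", ncol(bvec),
         " columns but '", bval_path, "' has ", length(bval), " values")
  }
  gradient_scheme(bval, t(bvec))
}

#' @param scheme a [gradient_scheme()].
#' @rdname read_gradients
#' @export
write_gradients <- function(scheme, bvec_path, bval_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  write.table(t(scheme$bvecs), bvec_path, row.names = FALSE,
              col.names = FALSE)
  cat(paste(scheme$bvals, collapse = " "), "\n", file = bval_path, sep = "")
  invisible(c(bvec_path, bval_path))
}
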