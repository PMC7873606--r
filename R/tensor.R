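# design matrix rows: [1, -b gx^2, -b gy^2, -b gz^2, -2b gxgy, -2b gxgz,
# -2b gygz]; fitted coefficients are [log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]
.tensor_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Diffusion tensor fit by iteratively reweighted linear least squares
#'
#' Iteration 0 is the ordinary log-linear least-squares fit; each further
#' iteration reweights every measurement by its squared model-predicted
#' signal, down-weighting the heavily attenuated measurements whose
#' log-transformed noise is largest. Signals at or below zero are clamped
#' to `signal_floor` before the log (the log-linear fit requires
#' positivity).
#'
#' @param dwi 4D array (x, y, z, volume) or n_meas x n_vox matrix.
#' @param scheme a [gradient_scheme()] matching the 4th dimension.
#' @param n_iter reweighting iterations (default 2).
#' @param mask optional logical array/vector; voxels outside are not fit.
#' @param signal_floor positive clamp applied before the log; default
#'   `1e-6 * max(signal)`.
#' @return Object of class `tensor_field`: `beta` (7 x n_vox), eigenvalues
#'   `evals` (3 x n_vox, descending), principal eigenvector `evec1`,
#'   logical `valid`, and the spatial `dim` (NULL for matrix input).
#' @export
fit_tensor_irls <- function(dwi, scheme, n_iter = 2L, mask = NULL,
                            signal_floor = NULL) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  nm <- length(scheme$bvals)
  if (nm < 7L) stop("need at least 7 volumes to fit a tensor")
  if (sum(scheme$bvals == 0) < 1L) stop("need at least one b = 0 volume")
  spatial_dim <- NULL
  if (is.array(dwi) && length(dim(dwi)) == 4L) {
    spatial_dim <- dim(dwi)[1:3]
    S <- matrix(dwi, prod(spatial_dim), dim(dwi)[4])
    S <- t(S)
  } else {
    S <- as.matrix(dwi)
  }
  if (nrow(S) != nm) stop("signal volumes do not match the gradient scheme")
  nv <- ncol(S)
  keep <- if (is.null(mask)) rep(TRUE, nv) else as.logical(mask)
  if (length(keep) != nv) stop("mask does not match the volume")
  if (is.null(signal_floor)) signal_floor <- 1e-6 * max(S, 1e-300)

  X <- .tensor_design(scheme)
  if (qr(X)$rank < 7L) {
    stop("rank-deficient tensor design: gradient directions span ",
         qr(X)$rank, " of 7 required components")
  }
  fit <- .tensor_irls_cpp(S[, keep, drop = FALSE], X, as.integer(n_iter),
                          signal_floor)
  eig <- .tensor_eigs_cpp(fit$beta)

  beta <- matrix(NA_real_, 7, nv)
  evals <- matrix(NA_real_, 3, nv)
  evec1 <- matrix(NA_real_, 3, nv)
  beta[, keep] <- fit$beta
  evals[, keep] <- eig$evals
  evec1[, keep] <- eig$evec1
  valid <- rep(FALSE, nv)
  valid[keep] <- fit$ok & colSums(is.na(eig$evals)) == 0
  # negative eigenvalues (noise) are retained but flagged
  negative_evals <- valid & colSums(evals < 0, na.rm = TRUE) > 0
  structure(list(beta = beta, evals = evals, evec1 = evec1, valid = valid,
                 negative_evals = negative_evals, dim = spatial_dim,
                 n_iter = n_iter),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("tensor_field:", ncol(x$beta), "voxels,", sum(x$valid), "valid\n")
  invisible(x)
}

.as_scalar_map <- function(values, tf) {
  if (!is.null(tf$dim)) array(values, tf$dim) else values
}

#' Apparent diffusion coefficient (mean diffusivity)
#'
#' `ADC = (lambda1 + lambda2 + lambda3) / 3` in mm^2/s. Masked/invalid
#' voxels propagate as `NA`.
#'
#' @param tf a [fit_tensor_irls()] result.
#' @return Scalar map (array if the input was 4D, else vector).
#' @export
compute_adc <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  adc <- colMeans(tf$evals)
  adc[!tf$valid] <- NA_real_
  .as_scalar_map(adc, tf)
}

#' Fractional anisotropy
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`,
#' in `[0, 1]` for positive-definite tensors. Zero tensors yield `NA`.
#'
#' @param tf a [fit_tensor_irls()] result.
#' @return Scalar map (array if the input was 4D, else vector).
#' @export
compute_fa <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  fa <- .fa_from_evals(tf$evals)
  fa[!tf$valid] <- NA_real_
  .as_scalar_map(fa, tf)
}
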