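#' Estimate the single-fiber response function
#'
#' Signals of the selected single-fiber voxels are reoriented so the
#' principal diffusion-tensor axis aligns with +z, b0-normalized,
#' averaged, and projected onto the zonal (m = 0) spherical harmonics.
#'
#' @param dwi 4D DWI array or n_meas x n_vox matrix.
#' @param scheme a [gradient_scheme()].
#' @param single_fiber_mask logical array/vector selecting >= 20 voxels
#'   (ground-truth single-fiber voxels, or top-FA voxels).
#' @param lmax maximum even order of the response.
#' @return Object of class `response_function`: zonal coefficients `rl`
#'   (one per even l), `lmax`, shell `bval`, mean `b0`.
#' @export
estimate_response <- function(dwi, scheme, single_fiber_mask, lmax = 8L) {
  mask <- as.logical(single_fiber_mask)
  if (sum(mask) < 1L) stop("empty single-fiber mask")
  if (sum(mask) < 20L) {
    warning("single-fiber mask selects fewer than 20 voxels")
  }
  if (is.array(dwi) && length(dim(dwi)) == 4L) {
    S <- t(matrix(dwi, prod(dim(dwi)[1:3]), dim(dwi)[4]))
  } else {
    S <- as.matrix(dwi)
  }
  S <- S[, mask, drop = FALSE]
  tf <- fit_tensor_irls(S, scheme)
  dw <- scheme$bvals > 0
  g <- scheme$bvecs[dw, , drop = FALSE]
  b0 <- colMeans(S[!dw, , drop = FALSE])

  lorders <- seq(0L, lmax, by = 2L)
  zonal_cols <- cumsum(c(1L, 2L * lorders + 1L))[seq_along(lorders)] +
    lorders   # index of m = 0 within each l block
  # per voxel: express gradients in a frame whose z-axis is the principal
  # eigenvector, fit the zonal series to the b0-normalized signal, average
  rl_mat <- vapply(seq_len(ncol(S)), function(v) {
    e1 <- tf$evec1[, v]
    aux <- if (abs(e1[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
    ea <- pracma_cross(e1, aux)
    ea <- ea / sqrt(sum(ea^2))
    eb <- pracma_cross(e1, ea)
    grot <- cbind(g %*% ea, g %*% eb, g %*% e1)
    B <- sh_basis(grot, lmax)[, zonal_cols, drop = FALSE]
    as.numeric(qr.solve(B, S[dw, v] / b0[v]))
  }, numeric(length(lorders)))
  rl <- rowMeans(matrix(rl_mat, nrow = length(lorders)))
  structure(list(rl = rl, lmax = as.integer(lmax),
                 bval = unique(scheme$bvals[dw]), b0 = mean(b0),
                 n_voxels = ncol(S)),
            class = "response_function")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.response_function <- function(x, ...) {
  cat("response_function: lmax", x$lmax, "zonal coefficients",
      paste(signif(x$rl, 3), collapse = " "), "\n")
  invisible(x)
}

# Forward convolution matrix mapping FOD SH coefficients to DW signals:
# by the spherical convolution theorem each order-l coefficient is scaled
# by sqrt(4 pi / (2l + 1)) * r_l.
.csd_forward <- function(response, dirs, lmax) {
  lo <- sh_lorders(lmax)
  rl <- response$rl[match(lo, seq(0L, response$lmax, by = 2L))]
  rl[is.na(rl)] <- 0
  scale <- sqrt(4 * pi / (2 * lo + 1)) * rl
  sweep(sh_basis(dirs, lmax), 2, scale, "*")
}

#' Constrained spherical deconvolution
#'
#' Least-squares deconvolution of the single-fiber response from the
#' b0-normalized DW signals with an iterated hard non-negativity
#' constraint: constraint-mesh amplitudes below `tau * mean(initial
#' amplitude)` are driven towards zero by a quadratic penalty of weight
#' `lambda^2`, re-fitting until the constraint set is stable or `n_iter`
#' is reached (non-converged voxels are returned with a warning flag).
#'
#' @param signals n_dw x n_vox matrix of DW signals normalized by b0
#'   (b > 0 shell only), or a single voxel's vector.
#' @param response a [estimate_response()] result.
#' @param scheme a [gradient_scheme()] (provides the DW directions).
#' @param lmax maximum even order of the FOD (default 8).
#' @param mesh constraint [sphere_mesh()]; its hemisphere representatives
#'   (~321 directions at the default subdivision) form the constraint set.
#' @param lambda constraint weight.
#' @param tau amplitude threshold fraction.
#' @param n_iter maximum constraint iterations.
#' @return Object of class `fod_fit`: `coeffs` (ncoef x n_vox),
#'   `iterations`, `converged`, `lmax`, `basis = "tractfd-rsh-even-1"`.
#' @export
csd_fit <- function(signals, response, scheme, lmax = 8L,
                    mesh = sphere_mesh(3L), lambda = 1, tau = 0.1,
                    n_iter = 50L) {
  stopifnot(inherits(response, "response_function"))
  if (max(abs(response$rl)) < 1e-10) {
    stop("degenerate (flat/zero) response function: deconvolution is ",
         "ill-conditioned")
  }
  if (response$lmax >= 2 &&
      abs(response$rl[2]) < 1e-3 * abs(response$rl[1])) {
    warning("near-isotropic response: deconvolution is ill-conditioned")
  }
  dw <- scheme$bvals > 0
  dirs <- scheme$bvecs[dw, , drop = FALSE]
  S <- as.matrix(signals)
  if (nrow(S) == sum(!dw) + sum(dw) && nrow(S) != sum(dw)) {
    stop("signals must contain only the b > 0 volumes")
  }
  if (nrow(S) != sum(dw)) stop("signals do not match the DW directions")
  Fm <- .csd_forward(response, dirs, lmax)
  hemi <- mesh_hemisphere(mesh)
  Bm <- sh_basis(mesh$vertices[hemi, , drop = FALSE], lmax)
  n_init <- sh_ncoef(min(4L, lmax))
  fit <- .csd_fit_cpp(S, Fm, Bm, n_init, lambda, tau, as.integer(n_iter))
  if (!all(fit$converged)) {
    warning(sum(!fit$converged), " of ", ncol(S),
            " voxels did not reach a stable constraint set")
  }
  coeffs <- .clip_negative_lobes(fit$coeffs, mesh, lmax)
  structure(list(coeffs = coeffs, iterations = fit$iterations,
                 converged = fit$converged, lmax = as.integer(lmax),
                 basis = "tractfd-rsh-even-1"),
            class = "fod_fit")
}

# Final non-negativity projection: alternate clipping the mesh
# amplitudes at zero with weighted least-squares re-projection onto the
# band-limited basis.  The constrained deconvolution leaves small
# negative residual lobes (an intrinsic penalty-equilibrium effect);
# this alternating projection removes them at negligible cost to the
# positive lobes.
.clip_negative_lobes <- function(coeffs, mesh, lmax, tol_frac = 1e-3,
                                 max_iter = 50L) {
  B <- sh_basis(mesh$vertices, lmax)
  BW <- B * mesh$weights
  proj <- solve(t(B) %*% BW, t(BW))
  amps <- B %*% coeffs
  scale <- pmax(apply(amps, 2, max), .Machine$double.eps)
  for (k in seq_len(max_iter)) {
    bad <- apply(amps, 2, min) < -tol_frac * pmin(scale, 1)
    if (!any(bad)) break
    coeffs[, bad] <- proj %*% pmax(amps[, bad, drop = FALSE], 0)
    amps[, bad] <- B %*% coeffs[, bad, drop = FALSE]
  }
  coeffs
}

#' Fit FODs across a masked volume
#'
#' Convenience wrapper: b0-normalizes the DWI, restricts to `mask`, runs
#' [csd_fit()], and returns a spatial FOD field (coefficients are zero
#' outside the mask, so FOD amplitude vanishes there).
#'
#' @param dwi 4D DWI array.
#' @param scheme a [gradient_scheme()].
#' @param response a [estimate_response()] result.
#' @param grid the [voxel_grid()] of `dwi`.
#' @param mask logical array of voxels to fit.
#' @param ... passed to [csd_fit()].
#' @return Object of class `fod_field`: `coeffs` (ncoef x n_vox, zeros
#'   outside mask), `grid`, `lmax`, `basis`, `mask`.
#' @export
csd_fit_volume <- function(dwi, scheme, response, grid, mask, ...) {
  stopifnot(all(dim(dwi)[1:3] == grid$shape))
  nv <- prod(grid$shape)
  S <- t(matrix(dwi, nv, dim(dwi)[4]))
  dw <- scheme$bvals > 0
  b0 <- colMeans(S[!dw, , drop = FALSE])
  keep <- as.logical(mask) & b0 > 0
  Sn <- sweep(S[dw, keep, drop = FALSE], 2, b0[keep], "/")
  fit <- csd_fit(Sn, response, scheme, ...)
  coeffs <- matrix(0, nrow(fit$coeffs), nv)
  coeffs[, keep] <- fit$coeffs
  structure(list(coeffs = coeffs, grid = grid, lmax = fit$lmax,
                 basis = fit$basis, mask = array(keep, grid$shape),
                 converged = fit$converged),
            class = "fod_field")
}

#' @export
print.fod_field <- function(x, ...) {
  cat("fod_field: lmax", x$lmax, "on", paste(x$grid$shape, collapse = "x"),
      "grid,", sum(x$mask), "fitted voxels\n")
  invisible(x)
}
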