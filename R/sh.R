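#' Real symmetric spherical-harmonic basis
#'
#' The package uses one fixed convention throughout (FOD files and fixel
#' sidecars name it `tractfd-rsh-even-1`): even orders `l = 0, 2, ...,
#' lmax`; within each `l`, `m = -l, ..., l`; `m = 0` terms are the
#' orthonormal zonal harmonics, `m > 0` terms carry `sqrt(2) cos(m phi)`
#' and `m < 0` terms `sqrt(2) sin(|m| phi)`, with associated Legendre
#' functions without the Condon-Shortley phase. The basis is orthonormal
#' on the sphere; coefficient count is `(lmax+1)(lmax+2)/2`.
#'
#' @param dirs n x 3 matrix of directions (normalized internally).
#' @param lmax maximum (even) harmonic order.
#' @return n x ncoef basis matrix.
#' @export
sh_basis <- function(dirs, lmax = 8L) {
  .sh_basis_cpp(as.matrix(dirs), as.integer(lmax))
}

#' @rdname sh_basis
#' @export
sh_ncoef <- function(lmax) {
  (lmax + 1L) * (lmax + 2L) / 2L
}

#' @rdname sh_basis
#' @return `sh_lorders` returns the harmonic order `l` of each coefficient.
#' @export
sh_lorders <- function(lmax = 8L) {
  unlist(lapply(seq(0L, lmax, by = 2L), function(l) rep(l, 2L * l + 1L)))
}

#' Least-squares forward spherical-harmonic transform
#'
#' Fits coefficients to amplitudes sampled at `dirs`.
#'
#' @param amps numeric vector (or n x k matrix, one column per function).
#' @param dirs n x 3 sample directions.
#' @param lmax maximum even order.
#' @return Coefficient vector (or ncoef x k matrix).
#' @export
sh_fit <- function(amps, dirs, lmax = 8L) {
  B <- sh_basis(dirs, lmax)
  qr.solve(B, amps)
}

#' Evaluate an FOD at given directions
#'
#' Antipodally symmetric by construction (even-order basis).
#'
#' @param coeffs coefficient vector (or ncoef x k matrix).
#' @param dirs n x 3 unit directions.
#' @param lmax basis order; inferred from the coefficient count if `NULL`.
#' @return n-vector (or n x k matrix) of amplitudes.
#' @export
fod_amplitude <- function(coeffs, dirs, lmax = NULL) {
  coeffs <- as.matrix(coeffs)
  if (is.null(lmax)) {
    nc <- nrow(coeffs)
    lmax <- (sqrt(8 * nc + 1) - 3) / 2
    if (abs(lmax - round(lmax)) > 1e-9) {
      stop("coefficient count does not match an even-order basis")
    }
    lmax <- as.integer(round(lmax))
  }
  out <- sh_basis(dirs, lmax) %*% coeffs
  if (ncol(out) == 1L) as.numeric(out) else out
}
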