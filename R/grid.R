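#' Voxel grid with voxel-to-world affine
#'
#' Voxel indices are 0-based with the voxel center at the integer index;
#' `affine` maps homogeneous voxel indices to world mm.
#'
#' @param shape integer vector of length 3.
#' @param affine 4 x 4 voxel-index -> world-mm transform.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  structure(list(shape = shape, affine = affine,
                 inverse = solve(affine)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$shape, collapse = " x "), " spacing ",
      paste(signif(grid_spacing(x), 4), collapse = "/"), "mm\n")
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid a `voxel_grid`.
#' @export
grid_spacing <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' Isotropic grid centered on the world origin
#'
#' @param shape integer length-3 grid shape.
#' @param spacing isotropic voxel size (mm).
#' @return A [voxel_grid()].
#' @export
centered_grid <- function(shape = c(40L, 48L, 40L), spacing = 2) {
  shape <- as.integer(shape)
  affine <- diag(c(rep(spacing, 3), 1))
  affine[1:3, 4] <- -(shape - 1) / 2 * spacing
  voxel_grid(shape, affine)
}

#' Grid covering the same field of view at a new isotropic spacing
#'
#' @param grid source [voxel_grid()] (must be axis-aligned isotropic).
#' @param spacing new voxel size (mm).
#' @return A [voxel_grid()].
#' @export
regrid <- function(grid, spacing) {
  old <- grid_spacing(grid)
  fov <- grid$shape * old
  shape <- pmax(1L, as.integer(ceiling(fov / spacing)))
  center <- vox2world(grid, matrix((grid$shape - 1) / 2, 1))
  affine <- diag(c(rep(spacing, 3), 1))
  affine[1:3, 4] <- as.numeric(center) - (shape - 1) / 2 * spacing
  voxel_grid(shape, affine)
}

#' Convert between voxel indices and world coordinates
#'
#' @param grid a [voxel_grid()].
#' @param pts n x 3 matrix (0-based fractional voxel indices, or world mm).
#' @return n x 3 matrix.
#' @export
vox2world <- function(grid, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  t(grid$affine %*% pts)[, 1:3, drop = FALSE]
}

#' @rdname vox2world
#' @export
world2vox <- function(grid, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  t(grid$inverse %*% pts)[, 1:3, drop = FALSE]
}

#' World coordinates of every voxel center
#'
#' @param grid a [voxel_grid()].
#' @return (prod(shape)) x 3 matrix in column-major voxel order.
#' @export
grid_coords <- function(grid) {
  s <- grid$shape
  idx <- cbind(
    rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
    rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  )
  vox2world(grid, idx)
}

#' Trilinear interpolation of a 3D volume at world points
#'
#' Values are interpolated in voxel space (voxel center at integer index);
#' points outside the volume, and points whose 8-voxel neighborhood
#' contains a missing value, yield `NA`.
#'
#' @param vol 3D array.
#' @param grid the [voxel_grid()] of `vol`.
#' @param pts n x 3 world-mm coordinates.
#' @return numeric vector of n interpolated values.
#' @export
interp_trilinear <- function(vol, grid, pts) {
  stopifnot(all(dim(vol) == grid$shape))
  v <- world2vox(grid, pts)
  .trilinear_cpp(as.numeric(vol), grid$shape, v)
}
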