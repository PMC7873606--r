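#' Segment FODs into fixels
#'
#' FOD amplitudes are evaluated at the vertices of a symmetric sphere
#' mesh; local maxima become fixel directions, every vertex with positive
#' amplitude is assigned to a maximum by steepest ascent along mesh edges,
#' and the apparent fiber density (FD) of a fixel is the quadrature
#' integral of its lobe, `sum(A(v) w_v)`. Maxima below
#' `peak_frac * global max` are merged into the adjacent lobe with the
#' strongest peak; antipodal lobe pairs are reported once as an axis with
#' FD equal to the mean of the paired lobe integrals.
#'
#' @param fod a [csd_fit_volume()] FOD field, or an ncoef x n_vox
#'   coefficient matrix.
#' @param mesh a [sphere_mesh()].
#' @param peak_frac relative peak threshold in `(0, 1)`.
#' @param voxels optional integer vector of (1-based, column-major) voxel
#'   indices to segment; default: all masked voxels.
#' @return Object of class `fixel_set`: data frame `fixels` with columns
#'   `voxel`, `dir.x/y/z`, `fd`, `peak`; `offsets` (length n_vox + 1
#'   0-based row offsets per voxel, C-style); `n_vox`; `mesh_subdiv`.
#' @export
segment_fod_lobes <- function(fod, mesh = sphere_mesh(3L),
                              peak_frac = 0.1, voxels = NULL) {
  if (peak_frac <= 0 || peak_frac >= 1) stop("peak_frac must be in (0,1)")
  coeffs <- if (inherits(fod, "fod_field")) fod$coeffs else as.matrix(fod)
  nv <- ncol(coeffs)
  if (is.null(voxels)) {
    voxels <- if (inherits(fod, "fod_field")) which(fod$mask) else seq_len(nv)
  }
  lmx <- if (inherits(fod, "fod_field")) fod$lmax else {
    nc <- nrow(coeffs)
    as.integer(round((sqrt(8 * nc + 1) - 3) / 2))
  }
  B <- sh_basis(mesh$vertices, lmx)
  amps <- B %*% coeffs[, voxels, drop = FALSE]
  res <- .fixel_segment_cpp(amps, mesh$neighbors, mesh$weights,
                            mesh$vertices, mesh$antipode, peak_frac)
  ks <- vapply(res, function(r) length(r$fd), integer(1))
  fix <- data.frame(
    voxel = rep(voxels, ks),
    dir.x = unlist(lapply(res, function(r) r$dir[, 1])),
    dir.y = unlist(lapply(res, function(r) r$dir[, 2])),
    dir.z = unlist(lapply(res, function(r) r$dir[, 3])),
    fd = unlist(lapply(res, function(r) r$fd)),
    peak = unlist(lapply(res, function(r) r$peak))
  )
  # order rows by voxel index and build per-voxel offsets
  ord <- order(fix$voxel)
  fix <- fix[ord, , drop = FALSE]
  rownames(fix) <- NULL
  counts <- integer(nv)
  tb <- table(fix$voxel)
  counts[as.integer(names(tb))] <- as.integer(tb)
  offsets <- c(0L, cumsum(counts))
  structure(list(fixels = fix, offsets = offsets, n_vox = nv,
                 mesh_subdiv = mesh$subdiv,
                 grid = if (inherits(fod, "fod_field")) fod$grid else NULL),
            class = "fixel_set")
}

#' @export
print.fixel_set <- function(x, ...) {
  cat("fixel_set:", nrow(x$fixels), "fixels in",
      length(unique(x$fixels$voxel)), "voxels\n")
  invisible(x)
}

#' Tract fixel density (fixel TDI)
#'
#' Every streamline step (midpoint voxel, tangent axis) is assigned to the
#' angularly nearest fixel of that voxel when within `max_angle`;
#' traversal counts are accumulated per fixel.
#'
#' @param tractogram a [track()] result.
#' @param fixel_set a [segment_fod_lobes()] result with a grid.
#' @param max_angle assignment angle limit (radians), default 45 degrees.
#' @return Integer vector of traversal counts, one per fixel row.
#' @export
tract_fixel_density <- function(tractogram, fixel_set,
                                max_angle = pi / 4) {
  stopifnot(inherits(tractogram, "tractogram"),
            inherits(fixel_set, "fixel_set"))
  if (max_angle <= 0 || max_angle > pi / 2) {
    stop("max_angle must be in (0, pi/2]")
  }
  grid <- fixel_set$grid
  if (is.null(grid)) stop("fixel set has no grid")
  steps <- .streamline_steps(tractogram, grid)
  .fixel_tdi_cpp(steps$vox, steps$tangent, fixel_set$offsets,
                 as.matrix(fixel_set$fixels[, c("dir.x", "dir.y", "dir.z")]),
                 max_angle)
}

# midpoint voxel (0-based linear, -1 outside) and unit tangent per step
.streamline_steps <- function(tractogram, grid) {
  mids <- list(); tans <- list()
  for (i in seq_along(tractogram$streamlines)) {
    sl <- tractogram$streamlines[[i]]
    if (nrow(sl) < 2) next
    d <- diff(sl)
    len <- sqrt(rowSums(d^2))
    ok <- len > 0
    mids[[length(mids) + 1]] <- (sl[-nrow(sl), , drop = FALSE] +
                                   sl[-1, , drop = FALSE])[ok, , drop = FALSE] / 2
    tans[[length(tans) + 1]] <- d[ok, , drop = FALSE] / len[ok]
  }
  mid <- do.call(rbind, mids)
  v <- round(world2vox(grid, mid))
  inb <- v[, 1] >= 0 & v[, 1] < grid$shape[1] &
    v[, 2] >= 0 & v[, 2] < grid$shape[2] &
    v[, 3] >= 0 & v[, 3] < grid$shape[3]
  lin <- rep(-1L, nrow(v))
  lin[inb] <- as.integer(v[inb, 1] + grid$shape[1] *
                           (v[inb, 2] + grid$shape[2] * v[inb, 3]))
  list(vox = lin, tangent = do.call(rbind, tans))
}

#' Threshold fixels by tract traversal count
#'
#' Keeps exactly the fixels with `count >= min_count`, removing
#' crossing-bundle fixels not traversed by the tract. The default
#' `min_count` is `max(1, 0.05 * max(count))`.
#'
#' @param fixel_set a [segment_fod_lobes()] result.
#' @param density traversal counts from [tract_fixel_density()].
#' @param min_count minimum traversal count (>= 1).
#' @return A filtered `fixel_set` (offsets recomputed).
#' @export
threshold_fixels <- function(fixel_set, density, min_count = NULL) {
  stopifnot(inherits(fixel_set, "fixel_set"),
            length(density) == nrow(fixel_set$fixels))
  if (is.null(min_count)) min_count <- max(1, 0.05 * max(density, 0))
  if (min_count < 1) stop("min_count must be >= 1")
  keep <- density >= min_count
  out <- fixel_set
  out$fixels <- fixel_set$fixels[keep, , drop = FALSE]
  rownames(out$fixels) <- NULL
  counts <- integer(fixel_set$n_vox)
  tb <- table(out$fixels$voxel)
  counts[as.integer(names(tb))] <- as.integer(tb)
  out$offsets <- c(0L, cumsum(counts))
  out$min_count <- min_count
  out
}

#' Mean fiber density map of retained fixels
#'
#' Voxel value = arithmetic mean of the retained fixel FDs; voxels with no
#' retained fixel are `NA` (missing, not zero).
#'
#' @param fixel_set a (thresholded) `fixel_set` with a grid.
#' @param grid optional [voxel_grid()] override.
#' @return 3D array.
#' @export
mean_fd_map <- function(fixel_set, grid = fixel_set$grid) {
  stopifnot(inherits(fixel_set, "fixel_set"))
  if (is.null(grid)) stop("no grid available")
  out <- array(NA_real_, grid$shape)
  if (nrow(fixel_set$fixels) > 0) {
    m <- tapply(fixel_set$fixels$fd, fixel_set$fixels$voxel, mean)
    out[as.integer(names(m))] <- as.numeric(m)
  }
  out
}

#' FD values along resampled streamlines
#'
#' Step (iv) of the along-tract FD procedure: interpolates the tract-masked
#' mean-FD map at the 100 resampled points of each streamline
#' (missing-voxel values propagate as `NA`).
#'
#' @param resampled_points S x n x 3 array from [resample_tractogram()].
#' @param fd_map 3D array from [mean_fd_map()].
#' @param grid the [voxel_grid()] of `fd_map`.
#' @return S x n matrix of FD values.
#' @export
fd_along_tract <- function(resampled_points, fd_map, grid) {
  sample_map_along(resampled_points, fd_map, grid)
}
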