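#' Tractography parameters
#'
#' Defaults follow common FOD-tractography practice: amplitude cutoff 0.1,
#' minimum streamline length 5x and maximum 100x the voxel size, step size
#' half a voxel, and a per-step angle limit derived from the step size and
#' a 1 mm curvature-radius floor, `2 asin(step / (2 r_c))`.
#'
#' @param voxel_size tracking-grid voxel size (mm).
#' @param cutoff FOD amplitude cutoff.
#' @param n_streamlines accepted streamline target per run.
#' @param step step size (mm).
#' @param max_angle per-step angle limit (radians).
#' @param min_len,max_len streamline length bounds (mm).
#' @param curvature_radius curvature radius floor (mm).
#' @param attempt_factor attempt ceiling as a multiple of the target.
#' @param n_candidates candidate directions per step.
#' @param n_init_candidates candidate directions for seeding.
#' @return List of class `track_params`.
#' @export
track_params <- function(voxel_size, cutoff = 0.1, n_streamlines = 5000L,
                         step = 0.5 * voxel_size, max_angle = NULL,
                         min_len = 5 * voxel_size,
                         max_len = 100 * voxel_size,
                         curvature_radius = 1,
                         attempt_factor = 50, n_candidates = 12L,
                         n_init_candidates = 64L) {
  if (is.null(max_angle)) {
    max_angle <- 2 * asin(min(1, step / (2 * curvature_radius)))
  }
  structure(list(voxel_size = voxel_size, cutoff = cutoff,
                 n_streamlines = as.integer(n_streamlines), step = step,
                 max_angle = max_angle, min_len = min_len,
                 max_len = max_len, attempt_factor = attempt_factor,
                 n_candidates = as.integer(n_candidates),
                 n_init_candidates = as.integer(n_init_candidates)),
            class = "track_params")
}

#' Probabilistic FOD tractography
#'
#' Streamlines grow bidirectionally from uniform random seed points inside
#' the seed mask. At each step, candidate directions are drawn uniformly
#' within the curvature cone and one is selected with probability
#' proportional to the product of FOD amplitudes at the midpoint and
#' endpoint of the candidate step (a two-point arc approximation of
#' arc-wise probabilistic tracking). Growth terminates when no candidate
#' clears the amplitude cutoff, at the length cap, or on leaving the
#' volume. A candidate streamline is accepted iff its length is within
#' `[min_len, max_len]` and it intersects the inclusion mask; generation
#' continues to the accepted-count target or the attempt ceiling.
#'
#' @param fod a [csd_fit_volume()] FOD field.
#' @param seed_mask logical array on the FOD grid.
#' @param include_mask logical array on the FOD grid.
#' @param params a [track_params()].
#' @param seed RNG seed; identical seeds give identical tractograms.
#' @return Object of class `tractogram`: `streamlines` (list of n x 3
#'   world-mm matrices), `step`, `grid`, `meta` (attempts, rejection
#'   counts, seed voxel per streamline).
#' @export
track <- function(fod, seed_mask, include_mask, params, seed = 1L) {
  stopifnot(inherits(fod, "fod_field"), inherits(params, "track_params"))
  if (!all(dim(seed_mask) == fod$grid$shape) ||
      !all(dim(include_mask) == fod$grid$shape)) {
    stop("masks must be on the FOD grid")
  }
  if (!any(seed_mask)) stop("empty seed mask")
  seed_vox <- which(array(as.logical(seed_mask), fod$grid$shape),
                    arr.ind = TRUE) - 1L
  set.seed(seed)
  res <- .track_cpp(fod$coeffs, fod$grid$shape, fod$grid$inverse,
                    fod$grid$affine, seed_vox,
                    as.logical(include_mask), fod$lmax, params$step,
                    params$max_angle, params$cutoff, params$min_len,
                    params$max_len, params$n_streamlines,
                    params$attempt_factor, params$n_candidates,
                    params$n_init_candidates)
  if (res$n_accepted < params$n_streamlines) {
    warning("attempt ceiling reached: ", res$n_accepted, " of ",
            params$n_streamlines, " streamlines accepted")
  }
  structure(list(streamlines = res$streamlines, step = params$step,
                 grid = fod$grid, params = params, seed = seed,
                 meta = list(attempts = res$attempts,
                             n_accepted = res$n_accepted,
                             rejected = res$rejected,
                             seed_index = res$seed_index[
                               seq_len(res$n_accepted)])),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat("tractogram:", length(x$streamlines), "streamlines, step",
      signif(x$step, 3), "mm, mean", signif(mean(np), 4), "points\n")
  invisible(x)
}

#' Keep streamlines intersecting a mask
#'
#' A streamline is kept iff at least one of its points falls inside the
#' mask by nearest-voxel lookup.
#'
#' @param tractogram a [track()] result.
#' @param mask logical array.
#' @param grid the [voxel_grid()] of `mask` (default: tracking grid).
#' @return A filtered `tractogram`.
#' @export
filter_by_inclusion <- function(tractogram, mask, grid = tractogram$grid) {
  stopifnot(inherits(tractogram, "tractogram"))
  mask <- array(as.logical(mask), grid$shape)
  keep <- vapply(tractogram$streamlines, function(sl) {
    v <- round(world2vox(grid, sl))
    inb <- v[, 1] >= 0 & v[, 1] < grid$shape[1] &
      v[, 2] >= 0 & v[, 2] < grid$shape[2] &
      v[, 3] >= 0 & v[, 3] < grid$shape[3]
    if (!any(inb)) return(FALSE)
    v <- v[inb, , drop = FALSE] + 1
    any(mask[cbind(v[, 1], v[, 2], v[, 3])])
  }, logical(1))
  out <- tractogram
  out$streamlines <- tractogram$streamlines[keep]
  out$meta$seed_index <- tractogram$meta$seed_index[keep]
  out$meta$n_accepted <- sum(keep)
  out
}
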