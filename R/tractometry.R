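#' Resample a streamline to equally spaced arc-length points
#'
#' Output point `i` lies at arc-length fraction `(i - 1) / (n - 1)` of the
#' input polyline (endpoints preserved), with linear interpolation inside
#' segments.
#'
#' @param points m x 3 matrix of ordered streamline points (m >= 2).
#' @param n number of output points (default 100).
#' @return n x 3 matrix.
#' @export
resample_streamline <- function(points, n = 100L) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("streamline needs at least 2 points")
  seg <- sqrt(rowSums(diff(points)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total <= 0) stop("zero-length streamline")
  target <- seq(0, total, length.out = n)
  # right-continuous segment lookup; endpoints exact
  j <- findInterval(target, arc, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), nrow(points) - 1L)
  w <- (target - arc[j]) / seg[j]
  w[seg[j] == 0] <- 0
  points[j, , drop = FALSE] * (1 - w) + points[j + 1L, , drop = FALSE] * w
}

#' Resample every streamline of a tractogram
#'
#' @param tractogram a [track()] result (or list of point matrices).
#' @param n points per streamline.
#' @return S x n x 3 array of world coordinates.
#' @export
resample_tractogram <- function(tractogram, n = 100L) {
  sls <- if (inherits(tractogram, "tractogram")) {
    tractogram$streamlines
  } else {
    tractogram
  }
  out <- array(NA_real_, c(length(sls), n, 3))
  for (i in seq_along(sls)) out[i, , ] <- resample_streamline(sls[[i]], n)
  out
}

#' Sample a scalar map along resampled points
#'
#' Trilinear interpolation in voxel space; points outside the volume (or
#' adjacent to missing voxels) yield `NA`.
#'
#' @param points S x n x 3 array (or n x 3 matrix) of world coordinates.
#' @param map 3D array.
#' @param grid the [voxel_grid()] of `map`.
#' @return S x n matrix (or n-vector) of sampled values.
#' @export
sample_map_along <- function(points, map, grid) {
  if (is.matrix(points)) {
    return(interp_trilinear(map, grid, points))
  }
  stopifnot(length(dim(points)) == 3L, dim(points)[3] == 3L)
  S <- dim(points)[1]
  n <- dim(points)[2]
  flat <- matrix(points, S * n, 3)
  matrix(interp_trilinear(map, grid, flat), S, n)
}

#' Co-orient streamlines caudal to cortical
#'
#' Flips each streamline so that its first point is the end nearer the
#' centroid of the caudal reference mask. Idempotent.
#'
#' @param tractogram a [track()] result.
#' @param caudal_mask logical array marking the caudal (medulla) region.
#' @param grid the [voxel_grid()] of the mask (default: tracking grid).
#' @return The re-oriented `tractogram`.
#' @export
orient_streamlines <- function(tractogram, caudal_mask,
                               grid = tractogram$grid) {
  stopifnot(inherits(tractogram, "tractogram"))
  idx <- which(array(as.logical(caudal_mask), grid$shape),
               arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) stop("caudal mask is empty")
  centroid <- colMeans(vox2world(grid, idx))
  tractogram$streamlines <- lapply(tractogram$streamlines, function(sl) {
    d_first <- sum((sl[1, ] - centroid)^2)
    d_last <- sum((sl[nrow(sl), ] - centroid)^2)
    if (d_last < d_first) sl[rev(seq_len(nrow(sl))), , drop = FALSE] else sl
  })
  tractogram
}

#' Per-segment medians across streamlines
#'
#' @param values S x n matrix of per-point sampled values (`NA` = missing).
#' @return Object of class `segment_profile`: `median` (length n, `NA`
#'   where no streamline contributes), `n_streamlines` (per segment count
#'   of non-missing values), `missing` flags.
#' @export
segment_medians <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop("need at least one streamline")
  med <- apply(values, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else median(x)
  })
  cnt <- colSums(!is.na(values))
  structure(list(median = med, n_streamlines = cnt, missing = cnt == 0L),
            class = "segment_profile")
}

#' Peritumoral segment labels and interface bands
#'
#' Marks the contiguous lesional segment range, and derives the
#' tumor-healthy white-matter interface bands whose width corresponds to
#' `interface_voxels` voxels of tissue converted into segments via the
#' mean inter-point arc spacing.
#'
#' @param range integer `c(a, b)` with `1 <= a <= b <= n_segments`, or
#'   `NULL`/`c()` for no lesion.
#' @param n_segments number of segments (default 100).
#' @param voxel_size voxel size (mm) used for the interface width.
#' @param mean_segment_length mean arc length between consecutive
#'   resampled points (mm).
#' @param interface_voxels interface width in voxels (default 3).
#' @return List of class `peritumoral_labels`: logical `peritumoral`
#'   (length `n_segments`), integer vectors `interface_internal` /
#'   `interface_external`, and the band width in segments.
#' @export
label_peritumoral <- function(range, n_segments = 100L, voxel_size = 1.3,
                              mean_segment_length = 0.7,
                              interface_voxels = 3L) {
  peri <- rep(FALSE, n_segments)
  if (is.null(range) || length(range) == 0L) {
    return(structure(list(peritumoral = peri, interface_internal = integer(),
                          interface_external = integer(), width = 0L),
                     class = "peritumoral_labels"))
  }
  if (length(range) != 2L || range[1] > range[2]) {
    stop("range must be c(a, b) with a <= b")
  }
  if (range[1] < 1L || range[2] > n_segments) {
    stop("range must lie within [1, ", n_segments, "]")
  }
  a <- as.integer(range[1]); b <- as.integer(range[2])
  peri[a:b] <- TRUE
  width <- max(1L, as.integer(round(
    interface_voxels * voxel_size / mean_segment_length)))
  internal <- unique(c(seq(a, min(b, a + width - 1L)),
                       seq(max(a, b - width + 1L), b)))
  lo <- if (a > 1L) seq(max(1L, a - width), a - 1L) else integer()
  hi <- if (b < n_segments) seq(b + 1L, min(n_segments, b + width)) else integer()
  external <- setdiff(c(lo, hi), a:b)
  structure(list(peritumoral = peri,
                 interface_internal = sort(internal),
                 interface_external = sort(external),
                 width = width),
            class = "peritumoral_labels")
}
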