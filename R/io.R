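#' Read and write NIfTI volumes with a voxel grid
#'
#' Thin wrappers around RNifti keeping the package's `voxel_grid`
#' (0-based voxel index to world mm affine) in sync with the NIfTI
#' sform/qform.
#'
#' @param vol 3D or 4D array.
#' @param grid a [voxel_grid()] describing the spatial dimensions.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_nifti` returns `path`; `read_nifti` a list with `data`
#'   and `grid`.
#' @export
write_nifti <- function(vol, grid, path) {
  stopifnot(all(dim(vol)[1:3] == grid$shape))
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  d <- dim(img)
  grid <- voxel_grid(d[1:3], aff)
  list(data = array(as.numeric(img), d), grid = grid)
}

#' Write streamlines in the TCK track format
#'
#' Text header (`mrtrix tracks` magic, key: value fields, `file: . offset`
#' and `END`), then little-endian float32 xyz triplets with
#' `(NaN, NaN, NaN)` separators between streamlines and an
#' `(Inf, Inf, Inf)` terminator.
#'
#' @param tractogram a [track()] result or list of n x 3 matrices.
#' @param path output path.
#' @param step_size step size recorded in the header (mm).
#' @return `path`, invisibly.
#' @export
write_tck <- function(tractogram, path, step_size = NULL) {
  sls <- if (inherits(tractogram, "tractogram")) tractogram$streamlines
  else tractogram
  if (is.null(step_size) && inherits(tractogram, "tractogram")) {
    step_size <- tractogram$step
  }
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           paste0("count: ", length(sls)),
           if (!is.null(step_size)) paste0("step_size: ", step_size),
           "tractfd: 1")
  # the offset counts the header bytes including the "file" and END lines
  base <- sum(nchar(hdr, type = "bytes")) + length(hdr)   # + newlines
  fline <- function(off) paste0("file: . ", off)
  off <- base + nchar("END") + 1L
  off <- off + nchar(fline(off)) + 1L
  # one fixed-point pass in case the offset gained a digit
  off2 <- base + nchar("END") + 1L + nchar(fline(off)) + 1L
  off <- off2
  con <- file(path, "wb")
  on.exit(close(con))
  writLines <- function(x) writeBin(charToRaw(paste0(x, "\n")), con)
  for (h in hdr) writLines(h)
  writLines(fline(off))
  writLines("END")
  for (sl in sls) {
    m <- t(as.matrix(sl))
    writeBin(as.numeric(m), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @return `read_tck` returns a list with `streamlines` (list of n x 3
#'   matrices) and the parsed `header`.
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks")) {
    stop("malformed TCK file '", path, "': missing magic line")
  }
  header <- list()
  offset <- NA_integer_
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed TCK file: no END before EOF")
    if (line == "END") break
    kv <- regmatches(line, regexec("^([^:]+): ?(.*)$", line))[[1]]
    if (length(kv) == 3L) {
      header[[kv[2]]] <- kv[3]
      if (kv[2] == "file") {
        offset <- as.integer(sub("^\\. ", "", kv[3]))
      }
    }
  }
  if (is.na(offset)) stop("malformed TCK file: no 'file' field")
  dt <- header[["datatype"]]
  if (!is.null(dt) && !dt %in% c("Float32LE")) {
    stop("unsupported TCK datatype: ", dt)
  }
  seek(con, offset)
  raw <- readBin(con, numeric(), n = file.size(path), size = 4L,
                 endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  ends <- which(!is.finite(m[, 1]))
  sls <- list()
  start <- 1L
  for (e in ends) {
    if (is.nan(m[e, 1])) {
      if (e > start) {
        sls[[length(sls) + 1]] <- m[start:(e - 1L), , drop = FALSE]
      }
      start <- e + 1L
    } else break   # Inf terminator
  }
  list(streamlines = sls, header = header)
}

#' Write a per-subject segment table as TSV
#'
#' Columns: subject, hemisphere, metric, segment, median, n_streamlines,
#' peritumoral.
#'
#' @param records an [assemble_table()]-layout data frame (a
#'   `n_streamlines` column is added as NA when absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segment_tsv <- function(records, path) {
  if (!"n_streamlines" %in% names(records)) {
    records$n_streamlines <- NA_integer_
  }
  write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_segment_tsv
#' @export
read_segment_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a fixel set as a fixel-directory layout
#'
#' Mirrors the published fixel-format layout: an `index.nii` volume with
#' two volumes (per-voxel fixel count and 0-based first-fixel offset)
#' plus plain-text `directions.tsv` and `fd.tsv` tables.
#'
#' @param fixel_set a [segment_fod_lobes()] result with a grid.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_fixel_dir <- function(fixel_set, dir) {
  stopifnot(inherits(fixel_set, "fixel_set"))
  grid <- fixel_set$grid
  if (is.null(grid)) stop("fixel set has no grid")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- diff(fixel_set$offsets)
  idx <- array(0, c(grid$shape, 2))
  idx[, , , 1] <- array(counts, grid$shape)
  idx[, , , 2] <- array(fixel_set$offsets[-length(fixel_set$offsets)],
                        grid$shape)
  write_nifti(idx, grid, file.path(dir, "index.nii"))
  write.table(fixel_set$fixels[, c("dir.x", "dir.y", "dir.z")],
              file.path(dir, "directions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(fixel_set$fixels[, "fd", drop = FALSE],
              file.path(dir, "fd.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(dir)
}
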