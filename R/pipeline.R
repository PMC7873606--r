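#' Pipeline configuration
#'
#' All stage parameters in one serializable object. A single master seed
#' deterministically derives per-stage seeds: subject noise seeds are
#' drawn once inside [make_cohort_truth()], and tracking uses
#' `master_seed + 7919 * subject + 13 * hemisphere_index`.
#'
#' @param n_subjects cohort size.
#' @param seed master seed.
#' @param noise_sigma Rician channel SD; `NULL` = SNR(b0) 30; 0 = off.
#' @param crossing include the transverse crossing bundle.
#' @param upsample_to tracking/fitting voxel size (mm).
#' @param n_streamlines accepted streamlines per hemisphere.
#' @param lmax FOD spherical-harmonic order.
#' @param lesion a [lesion_spec()].
#' @param tissue a [tissue_params()].
#' @param tdi_max_angle fixel-assignment angle limit (radians).
#' @param stats a [stats_config()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 1L, seed = 1L, noise_sigma = NULL,
                            crossing = FALSE, upsample_to = 1.3,
                            n_streamlines = 5000L, lmax = 8L,
                            lesion = lesion_spec(),
                            tissue = tissue_params(),
                            tdi_max_angle = pi / 4,
                            stats = stats_config()) {
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), noise_sigma = noise_sigma,
                 crossing = crossing, upsample_to = upsample_to,
                 n_streamlines = as.integer(n_streamlines),
                 lmax = as.integer(lmax), lesion = lesion,
                 tissue = tissue, tdi_max_angle = tdi_max_angle,
                 stats = stats),
            class = "pipeline_config")
}

#' Serialize and restore a pipeline configuration
#'
#' YAML round-trip: `read_config(write_config(cfg, path))` reproduces the
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(y)) {
    v <- y[[nm]]
    if (nm %in% c("lesion", "tissue", "stats")) {
      template <- cfg[[nm]]
      for (k in names(v)) template[[k]] <- v[[k]]
      cfg[[nm]] <- template
    } else {
      cfg[[nm]] <- if (is.list(v)) v else v
    }
  }
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_streamlines <- as.integer(cfg$n_streamlines)
  cfg$lmax <- as.integer(cfg$lmax)
  cfg
}

#' Upsample a DWI series onto a finer grid
#'
#' Trilinear per volume; points outside the source field of view get the
#' background value 0.
#'
#' @param dwi 4D array.
#' @param grid source [voxel_grid()].
#' @param new_grid target [voxel_grid()].
#' @return 4D array on `new_grid`.
#' @export
upsample_dwi <- function(dwi, grid, new_grid) {
  pts <- grid_coords(new_grid)
  nvol <- dim(dwi)[4]
  out <- array(0, c(new_grid$shape, nvol))
  for (v in seq_len(nvol)) {
    x <- interp_trilinear(dwi[, , , v], grid, pts)
    x[is.na(x)] <- 0
    out[, , , v] <- x
  }
  out
}

#' Bundle processing mask from ground truth
#'
#' Voxels within `tube_radius + margin` of either centerline (plus the
#' crossing tube when enabled); the spatial extent on which FODs are fit.
#'
#' @param truth a [make_cohort_truth()] object.
#' @param grid target [voxel_grid()].
#' @param tissue a [tissue_params()].
#' @param margin extra radius (mm).
#' @param crossing include the crossing tube.
#' @return Logical array.
#' @export
bundle_mask <- function(truth, grid, tissue = tissue_params(), margin = 3,
                        crossing = FALSE) {
  co <- grid_coords(grid)
  inb <- rep(FALSE, nrow(co))
  for (side in c("left", "right")) {
    nd <- .polyline_nearest_cpp(co, truth$centerlines[[side]]$points)
    inb <- inb | nd$distance <= tissue$tube_radius + margin
  }
  if (crossing) {
    dc <- sqrt((co[, 2] - tissue$crossing_center[1])^2 +
                 (co[, 3] - tissue$crossing_center[2])^2)
    inb <- inb | (dc <= tissue$crossing_radius + margin & abs(co[, 1]) <= 36)
  }
  array(inb, grid$shape)
}

#' Ground-truth single-fiber mask
#'
#' Core bundle voxels (within `core_radius` of a centerline, away from the
#' tract ends and outside any crossing region): the deterministic voxel
#' selection used for response estimation.
#'
#' @param truth a [make_cohort_truth()] object.
#' @param grid target [voxel_grid()].
#' @param tissue a [tissue_params()].
#' @param core_radius core radius (mm).
#' @param crossing exclude the crossing-tube region.
#' @return Logical array.
#' @export
single_fiber_mask <- function(truth, grid, tissue = tissue_params(),
                              core_radius = 2, crossing = FALSE) {
  co <- grid_coords(grid)
  inb <- rep(FALSE, nrow(co))
  for (side in c("left", "right")) {
    cl <- truth$centerlines[[side]]
    nd <- .polyline_nearest_cpp(co, cl$points)
    s <- cl$s[nd$index]
    inb <- inb | (nd$distance <= core_radius & s > 0.1 & s < 0.9)
  }
  if (crossing) {
    dc <- sqrt((co[, 2] - tissue$crossing_center[1])^2 +
                 (co[, 3] - tissue$crossing_center[2])^2)
    inb <- inb & dc > tissue$crossing_radius + 2
  }
  array(inb, grid$shape)
}

#' Run the full imaging chain for one subject
#'
#' Upsamples the DWI, fits the tensor (FA/ADC maps), estimates the
#' response and FODs, tracks both hemispheres, resamples and orients
#' streamlines, computes tract-masked fixel FD, and reduces everything to
#' per-hemisphere 100-segment median profiles. Where a clinical
#' preprocessing chain would run (denoising, Gibbs removal, motion/eddy/
#' susceptibility correction, bias field, registration) this pipeline
#' applies a pass-through, since the phantom is artifact-free.
#'
#' @param cohort a [make_cohort()] result (with DWI materialized).
#' @param subject_index subject to process.
#' @param config a [pipeline_config()].
#' @return List: `profiles` (`healthy`/`pathological`, each with `fa`,
#'   `adc`, `fd` [segment_medians()] profiles), `tractograms`, `maps`,
#'   `fod`, `response`, `fixels` (per hemisphere), `grid` (upsampled).
#' @export
run_subject_chain <- function(cohort, subject_index = 1L,
                              config = pipeline_config()) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  sub <- cohort$subjects[[subject_index]]
  if (is.null(sub$dwi)) stop("subject has no materialized DWI")
  truth <- cohort$truth
  scheme <- cohort$scheme
  tissue <- cohort$tissue

  up <- regrid(cohort$grid, config$upsample_to)
  dwi <- upsample_dwi(sub$dwi, cohort$grid, up)
  vox <- grid_spacing(up)[1]

  tf <- fit_tensor_irls(dwi, scheme)
  fa_map <- compute_fa(tf)
  adc_map <- compute_adc(tf)

  masks <- roi_masks(truth, up)
  proc <- bundle_mask(truth, up, tissue, crossing = cohort$crossing)
  sf <- single_fiber_mask(truth, up, tissue, crossing = cohort$crossing)
  response <- estimate_response(dwi, scheme, sf, lmax = config$lmax)
  fod <- csd_fit_volume(dwi, scheme, response, up, proc, lmax = config$lmax)

  params <- track_params(vox, n_streamlines = config$n_streamlines)
  out <- list(profiles = list(), tractograms = list(), fixels = list())
  for (side in c("left", "right")) {
    hseed <- config$seed + 7919L * subject_index +
      13L * match(side, c("left", "right"))
    tr <- track(fod, masks$seed[[side]], masks$include, params,
                seed = hseed)
    tr <- orient_streamlines(tr, masks$caudal, up)
    pts <- resample_tractogram(tr, 100L)

    fx <- segment_fod_lobes(fod, voxels = sort(unique(
      .streamline_steps(tr, up)$vox)) + 1L)
    fx$grid <- up
    dens <- tract_fixel_density(tr, fx, config$tdi_max_angle)
    fx_kept <- threshold_fixels(fx, dens)
    fdmap <- mean_fd_map(fx_kept, up)

    prof <- list(
      fa = segment_medians(sample_map_along(pts, fa_map, up)),
      adc = segment_medians(sample_map_along(pts, adc_map, up)),
      fd = segment_medians(fd_along_tract(pts, fdmap, up))
    )
    hemi <- if (side == sub$truth$lesion_side) "pathological" else "healthy"
    out$profiles[[hemi]] <- prof
    out$tractograms[[hemi]] <- tr
    out$fixels[[hemi]] <- fx_kept
  }
  out$maps <- list(fa = fa_map, adc = adc_map)
  out$fod <- fod
  out$response <- response
  out$grid <- up
  out$masks <- masks
  out
}

#' Run the end-to-end pipeline
#'
#' phantom -> tensor -> CSD -> tracking -> tractometry -> fixels -> stats,
#' writing per-stage outputs (NIfTI, TCK, bvec/bval, TSV, JSON) under
#' `out_dir`. Rerunning with the same config and seed reproduces
#' identical TSV outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return Invisibly, the results list: `records`, `lmm` (per metric,
#'   when >= 2 subjects), `segment_tests`, `truth`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "provenance.json")
  scheme <- default_scheme()
  grid <- centered_grid()
  cohort <- make_cohort(config$n_subjects, scheme, grid, config$lesion,
                        config$noise_sigma, config$seed, config$crossing,
                        config$tissue)
  write_gradients(scheme, file.path(out_dir, "dwi.bvec"),
                  file.path(out_dir, "dwi.bval"))

  profiles <- list()
  peritumoral <- list()
  for (i in seq_len(config$n_subjects)) {
    sd <- file.path(out_dir, sprintf("sub-%02d", i))
    dir.create(sd, showWarnings = FALSE)
    write_nifti(cohort$subjects[[i]]$dwi, grid, file.path(sd, "dwi.nii"))
    res <- run_subject_chain(cohort, i, config)
    for (h in names(res$tractograms)) {
      write_tck(res$tractograms[[h]], file.path(sd, paste0(h, ".tck")))
    }
    write_nifti(res$maps$fa, res$grid, file.path(sd, "fa.nii"))
    write_nifti(res$maps$adc, res$grid, file.path(sd, "adc.nii"))
    profiles[[i]] <- res$profiles
    rng <- cohort$truth$subjects[[i]]$lesion_range
    peritumoral[[i]] <- seq_len(100) >= rng[1] & seq_len(100) <= rng[2]
  }
  records <- assemble_table(profiles, peritumoral)
  write_segment_tsv(records, file.path(out_dir, "segments.tsv"))

  results <- list(records = records, truth = cohort$truth,
                  out_dir = out_dir)
  if (config$n_subjects >= 2) {
    results$lmm <- lapply(setNames(nm = c("fa", "adc", "fd")), function(m) {
      fit_hemisphere_lmm(records, m)
    })
    results$segment_tests <- lapply(setNames(nm = c("fa", "adc", "fd")),
                                    function(m) {
                                      segmentwise_tests(records, m,
                                                        config$stats)
                                    })
  }
  jsonlite::write_json(
    list(seed = config$seed, n_subjects = config$n_subjects,
         n_streamlines = config$n_streamlines, lmax = config$lmax,
         upsample_to = config$upsample_to,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    log_path, auto_unbox = TRUE)
  invisible(results)
}
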