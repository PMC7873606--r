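#' Tissue and geometry parameters of the two-hemisphere phantom
#'
#' The phantom holds two mirror-image curved tubular bundles (one per
#' hemisphere) running caudal to cortical, an optional transverse crossing
#' bundle, and isotropic background. Within a bundle each voxel mixes a
#' cylindrically symmetric fiber compartment with an isotropic compartment;
#' the fiber volume fraction varies smoothly along the tract and tapers at
#' the tube edge.
#'
#' @param lambda_par,lambda_perp axial/radial diffusivity of fiber
#'   compartments (mm^2/s).
#' @param d_iso isotropic (free-water-like) compartment diffusivity
#'   (mm^2/s).
#' @param S0 unattenuated signal (arbitrary units).
#' @param f_tract_base,f_tract_amp tract fiber fraction profile
#'   `f(s) = base + amp * s` of arc fraction `s` (caudal = 0); the
#'   monotone ramp gives the along-tract fiber density a wide dynamic
#'   range against which crossing-induced biases can be judged.
#' @param f_crossing fiber fraction of the crossing bundle (capped so
#'   that at least 5% isotropic fraction remains in shared voxels; at
#'   mid-tract the crossing is then approximately equal-fraction with
#'   the tract, the configuration in which tensor FA is most ambiguous).
#' @param tube_radius bundle tube radius (mm).
#' @param taper_width width of the edge taper band (mm).
#' @param taper_floor fraction retained at the tube surface.
#' @param crossing_radius radius of the transverse crossing tube (mm).
#' @param crossing_center (y, z) world position of the crossing tube axis.
#' @return A list of class `tissue_params`.
#' @export
tissue_params <- function(lambda_par = 1.7e-3, lambda_perp = 0.25e-3,
                          d_iso = 3.0e-3, S0 = 1,
                          f_tract_base = 0.35, f_tract_amp = 0.25,
                          f_crossing = 0.45, tube_radius = 8,
                          taper_width = 2, taper_floor = 0.15,
                          crossing_radius = 7, crossing_center = c(0, 0)) {
  stopifnot(lambda_par >= lambda_perp, lambda_perp > 0, d_iso > 0, S0 > 0)
  structure(as.list(environment()), class = "tissue_params")
}

#' Lesion specification
#'
#' Effect sizes are ground-truth changes of the along-tract metrics inside
#' the lesional segment range of the pathological hemisphere: FA decreases
#' by `effect_fa` (absolute), ADC increases by the fraction `effect_adc`,
#' and the tract fiber fraction (hence FD) decreases by the fraction
#' `effect_fd`. Segment ranges are contiguous and sampled within
#' `[range_lo, range_hi]`.
#'
#' @param effect_fa absolute FA decrease (dimensionless).
#' @param effect_adc fractional ADC increase.
#' @param effect_fd fractional fiber-density decrease.
#' @param range_lo,range_hi bounds of the lesional segment range (1-100).
#' @param len_lo,len_hi bounds of the sampled range length (segments).
#' @return A list of class `lesion_spec`.
#' @export
lesion_spec <- function(effect_fa = 0.10, effect_adc = 0.25,
                        effect_fd = 0.20, range_lo = 25L, range_hi = 95L,
                        len_lo = 10L, len_hi = 25L) {
  stopifnot(range_lo >= 1, range_hi <= 100, range_lo <= range_hi,
            len_lo >= 1, len_lo <= len_hi)
  structure(as.list(environment()), class = "lesion_spec")
}

#' Bundle centerline of one hemisphere
#'
#' A gently curved cubic-spline polyline from the caudal (medulla-like) to
#' the cortical end; the right hemisphere is the mirror image (x -> -x) of
#' the left.
#'
#' @param side `"left"` or `"right"`.
#' @param n number of dense samples.
#' @return List with `points` (n x 3 world mm), unit `tangents`, arc
#'   fraction `s` in `[0, 1]` (0 = caudal) and total `length` (mm).
#' @export
bundle_centerline <- function(side = c("left", "right"), n = 200L) {
  side <- match.arg(side)
  cx <- c(-12, -13, -16, -20, -24)
  cy <- c(2, 0, -3, 0, 4)
  cz <- c(-34, -18, 0, 18, 34)
  if (side == "right") cx <- -cx
  tt <- c(0, cumsum(sqrt(diff(cx)^2 + diff(cy)^2 + diff(cz)^2)))
  tt <- tt / max(tt)
  u <- seq(0, 1, length.out = n)
  p <- cbind(spline(tt, cx, xout = u)$y,
             spline(tt, cy, xout = u)$y,
             spline(tt, cz, xout = u)$y)
  seglen <- sqrt(rowSums(diff(p)^2))
  arc <- c(0, cumsum(seglen))
  tan <- rbind(p[2, ] - p[1, ], p[-1, ] - p[-n, ])
  tan[-c(1, n), ] <- (p[-(1:2), ] - p[1:(n - 2), ])
  tan <- tan / sqrt(rowSums(tan^2))
  list(points = p, tangents = tan, s = arc / max(arc), length = max(arc))
}

#' Sample cohort-level ground truth
#'
#' Each subject has exactly one lesioned hemisphere (left or right, equal
#' probability) and one contiguous lesional segment range.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param lesion a [lesion_spec()].
#' @param seed integer master seed.
#' @return Object of class `cohort_truth`: per-subject list with
#'   `lesion_side`, `lesion_range`, `effects`, `noise_seed`; shared
#'   `centerlines`; the generating `lesion` spec and `seed`.
#' @export
make_cohort_truth <- function(n_subjects, lesion = lesion_spec(),
                              seed = 1L) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  # documented derivation: all subject-level draws come sequentially from
  # the master seed; per-subject noise seeds are drawn here once
  subjects <- lapply(seq_len(n_subjects), function(i) {
    side <- if (runif(1) < 0.5) "left" else "right"
    a <- sample(seq(lesion$range_lo,
                    max(lesion$range_lo, lesion$range_hi - lesion$len_lo)), 1)
    len <- sample(seq(lesion$len_lo, lesion$len_hi), 1)
    b <- min(a + len - 1L, lesion$range_hi)
    list(id = i, lesion_side = side, lesion_range = c(a, b),
         effects = list(fa = lesion$effect_fa, adc = lesion$effect_adc,
                        fd = lesion$effect_fd),
         noise_seed = sample.int(.Machine$integer.max - 1L, 1))
  })
  structure(list(subjects = subjects,
                 centerlines = list(left = bundle_centerline("left"),
                                    right = bundle_centerline("right")),
                 lesion = lesion, seed = seed),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("cohort_truth:", length(x$subjects), "subjects, seed", x$seed, "\n")
  invisible(x)
}

#' Multi-compartment diffusion signal at one voxel
#'
#' `S(g, b) = S0 [ f_iso exp(-b d_iso) + sum_k f_k exp(-b g' D_k g) ]`
#' with `D_k` the cylindrically symmetric tensor with eigenvalues
#' `(lambda_par, lambda_perp, lambda_perp)` about the compartment
#' direction.
#'
#' @param config list with `S0`, `f_iso`, `d_iso` and `compartments`, a
#'   list of lists with `dir` (unit 3-vector), `f`, `lambda_par`,
#'   `lambda_perp`.
#' @param scheme a [gradient_scheme()].
#' @return Numeric vector, one (positive) signal per scheme volume.
#' @export
simulate_signal <- function(config, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  fk <- vapply(config$compartments, `[[`, numeric(1), "f")
  if (config$f_iso < 0 || any(fk < 0)) stop("negative volume fraction")
  if (abs(config$f_iso + sum(fk) - 1) > 1e-9) {
    stop("volume fractions must sum to 1")
  }
  for (cp in config$compartments) {
    if (cp$lambda_par < cp$lambda_perp || cp$lambda_perp <= 0) {
      stop("require lambda_par >= lambda_perp > 0")
    }
    if (cp$f > 0 && abs(sqrt(sum(cp$dir^2)) - 1) > 1e-6) {
      stop("compartment direction must be a unit vector")
    }
  }
  b <- scheme$bvals
  s <- config$f_iso * exp(-b * config$d_iso)
  for (cp in config$compartments) {
    if (cp$f == 0) next
    ct2 <- as.numeric(scheme$bvecs %*% cp$dir)^2
    gDg <- cp$lambda_perp + (cp$lambda_par - cp$lambda_perp) * ct2
    s <- s + cp$f * exp(-b * ifelse(b > 0, gDg, 0))
  }
  config$S0 * s
}

# Per-voxel compartment arrays for a whole grid; internal representation
# used by the vectorized signal synthesis.  Returns vectors of length
# prod(grid$shape) plus per-compartment direction matrices.
.voxel_config <- function(truth, subject = NULL, grid, tissue = tissue_params(),
                          crossing = FALSE, scheme = default_scheme()) {
  co <- grid_coords(grid)
  n <- nrow(co)
  cfg <- list(
    f_iso = rep(1, n), d_iso = rep(tissue$d_iso, n),
    S0 = rep(tissue$S0, n),
    f_t = numeric(n), dir_t = matrix(0, n, 3),
    lam_par = rep(tissue$lambda_par, n),
    lam_perp = rep(tissue$lambda_perp, n),
    f_c = numeric(n), s_arc = rep(NA_real_, n),
    hemisphere = rep(NA_character_, n), lesion = rep(FALSE, n),
    # crossing-bundle compartment always keeps baseline diffusivities
    lam_par_c = tissue$lambda_par, lam_perp_c = tissue$lambda_perp
  )
  for (side in c("left", "right")) {
    cl <- truth$centerlines[[side]]
    nd <- .polyline_nearest_cpp(co, cl$points)
    inside <- nd$distance <= tissue$tube_radius
    if (!any(inside)) next
    idx <- which(inside)
    s <- cl$s[nd$index[idx]]
    taper <- .edge_taper(nd$distance[idx], tissue)
    cfg$f_t[idx] <- .f_tract_profile(s, tissue) * taper
    cfg$dir_t[idx, ] <- cl$tangents[nd$index[idx], ]
    cfg$s_arc[idx] <- s
    cfg$hemisphere[idx] <- side
  }
  if (crossing) {
    dc <- sqrt((co[, 2] - tissue$crossing_center[1])^2 +
                 (co[, 3] - tissue$crossing_center[2])^2)
    inc <- dc <= tissue$crossing_radius & abs(co[, 1]) <= 36
    # cap so at least 5% isotropic signal remains in shared voxels
    cfg$f_c[inc] <- pmin(tissue$f_crossing, 1 - cfg$f_t[inc] - 0.05) *
      .edge_taper(dc[inc], tissue, tissue$crossing_radius)
  }
  cfg$f_iso <- pmax(0, 1 - cfg$f_t - cfg$f_c)
  if (!is.null(subject)) cfg <- .apply_lesion(cfg, subject, scheme)
  cfg
}

# along-tract tract fiber fraction at arc fraction s in [0, 1]
.f_tract_profile <- function(s, tissue) {
  tissue$f_tract_base + tissue$f_tract_amp * s
}

.edge_taper <- function(dist, tissue, radius = tissue$tube_radius) {
  inner <- radius - tissue$taper_width
  w <- rep(1, length(dist))
  band <- dist > inner
  w[band] <- 1 - (1 - tissue$taper_floor) *
    (dist[band] - inner) / tissue$taper_width
  pmax(w, 0)
}

# FA/ADC of a voxel config via noiseless signal synthesis and the IRLS
# tensor fit -- the quantity the DWI chain converges to at zero noise.
.config_metrics <- function(cfg, idx, scheme) {
  S <- .synth_signal(cfg, scheme, idx)
  fit <- .tensor_irls_cpp(S, .tensor_design(scheme), 2L, 1e-10)
  ev <- .tensor_eigs_cpp(fit$beta)$evals
  list(fa = .fa_from_evals(ev), adc = colMeans(ev))
}

.fa_from_evals <- function(ev) {
  mn <- colMeans(ev)
  num <- sqrt(colSums(sweep(ev, 2, mn, "-")^2))
  den <- sqrt(colSums(ev^2))
  fa <- sqrt(1.5) * num / den
  fa[den == 0] <- NA_real_
  fa
}

# Lesion injection with per-voxel calibration: the compartment parameters
# inside the lesional arc window of the pathological hemisphere are
# adjusted so that the zero-noise tensor-fit FA drops by effect$fa, ADC
# rises by the factor (1 + effect$adc), and the tract fiber fraction drops
# by the factor (1 - effect$fd).
.apply_lesion <- function(cfg, subject, scheme) {
  eff <- subject$effects
  rng <- subject$lesion_range
  if (rng[1] < 1 || rng[2] > 100 || rng[1] > rng[2]) {
    stop("lesion segment range must lie within [1, 100]")
  }
  h <- 0.5 / 99
  lo <- (rng[1] - 1) / 99 - h
  hi <- (rng[2] - 1) / 99 + h
  idx <- which(cfg$hemisphere == subject$lesion_side &
                 cfg$s_arc >= lo & cfg$s_arc <= hi & cfg$f_t > 0)
  cfg$lesion[idx] <- TRUE
  if (length(idx) == 0 ||
      (eff$fa == 0 && eff$adc == 0 && eff$fd == 0)) {
    return(cfg)
  }
  base <- .config_metrics(cfg, idx, scheme)
  fa_target <- pmax(0, base$fa - eff$fa)
  adc_target <- base$adc * (1 + eff$adc)
  cfg$f_t[idx] <- cfg$f_t[idx] * (1 - eff$fd)
  cfg$f_iso[idx] <- pmax(0, 1 - cfg$f_t[idx] - cfg$f_c[idx])
  for (k in idx) {
    kk <- match(k, idx)
    # anisotropy shrink kappa, then uniform diffusivity scale alpha;
    # two coordinate passes suffice at the required tolerance
    kap <- 0; alp <- 1
    for (pass in 1:2) {
      fa_of <- function(ka) {
        c2 <- .lesioned_voxel(cfg, k, ka, alp)
        .config_metrics(c2, 1L, scheme)$fa - fa_target[kk]
      }
      f0 <- fa_of(0)
      kap <- if (f0 <= 0) 0 else {
        stats::uniroot(fa_of, c(0, 1), tol = 1e-4)$root
      }
      adc_of <- function(al) {
        c2 <- .lesioned_voxel(cfg, k, kap, al)
        .config_metrics(c2, 1L, scheme)$adc - adc_target[kk]
      }
      alp <- stats::uniroot(adc_of, c(0.5, 4), tol = 1e-6)$root
    }
    lp <- cfg$lam_par[k]; lq <- cfg$lam_perp[k]
    lbar <- (lp + 2 * lq) / 3
    cfg$lam_par[k] <- alp * (lp - kap * (lp - lbar))
    cfg$lam_perp[k] <- alp * (lq - kap * (lq - lbar))
    cfg$d_iso[k] <- alp * cfg$d_iso[k]
  }
  cfg
}

# single-voxel config copy with trial lesion parameters
.lesioned_voxel <- function(cfg, k, kap, alp) {
  lp <- cfg$lam_par[k]; lq <- cfg$lam_perp[k]
  lbar <- (lp + 2 * lq) / 3
  list(f_iso = cfg$f_iso[k], d_iso = alp * cfg$d_iso[k], S0 = cfg$S0[k],
       f_t = cfg$f_t[k], dir_t = cfg$dir_t[k, , drop = FALSE],
       lam_par = alp * (lp - kap * (lp - lbar)),
       lam_perp = alp * (lq - kap * (lq - lbar)),
       f_c = cfg$f_c[k],
       lam_par_c = cfg$lam_par_c, lam_perp_c = cfg$lam_perp_c)
}

# vectorized forward model over selected voxels: returns n_meas x n_vox
.synth_signal <- function(cfg, scheme, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(cfg$f_iso)
  n <- length(idx)
  b <- scheme$bvals
  m <- length(b)
  nv <- length(cfg$f_iso)
  dirs <- cfg$dir_t[idx, , drop = FALSE]
  ct2 <- (scheme$bvecs %*% t(dirs))^2          # m x n
  lp <- rep(cfg$lam_par, length.out = nv)[idx]
  lq <- rep(cfg$lam_perp, length.out = nv)[idx]
  gDg <- sweep(sweep(ct2, 2, lp - lq, "*"), 2, lq, "+")
  # b recycles down columns of the m x n matrices
  S <- sweep(exp(-gDg * b), 2, cfg$f_t[idx], "*")
  fc <- rep(cfg$f_c, length.out = nv)[idx]
  if (any(fc > 0)) {
    ct2c <- as.numeric((scheme$bvecs %*% c(1, 0, 0))^2)
    gDgc <- cfg$lam_perp_c + (cfg$lam_par_c - cfg$lam_perp_c) * ct2c
    S <- S + outer(exp(-b * gDgc), fc)
  }
  S <- S + sweep(exp(-outer(b, rep(cfg$d_iso, length.out = nv)[idx])), 2,
                 cfg$f_iso[idx], "*")
  sweep(S, 2, rep(cfg$S0, length.out = nv)[idx], "*")
}

#' Add Rician (magnitude MR) noise
#'
#' @param S array or matrix of noiseless signals.
#' @param sigma Gaussian channel noise SD (same units as S).
#' @return Noisy signals, same shape; uses the current RNG state.
#' @export
add_rician_noise <- function(S, sigma) {
  if (sigma <= 0) return(S)
  out <- sqrt((S + rnorm(length(S), 0, sigma))^2 +
                rnorm(length(S), 0, sigma)^2)
  dim(out) <- dim(S)
  out
}

#' Seed, inclusion and caudal ROI masks for one subject
#'
#' The seed ROI is a 3 x 3 x 3 acquisition-voxel patch (6 mm cube at the
#' default 2 mm grid) centered near the cortical end of each bundle; the
#' inclusion ROI is a caudal axial slab crossing both bundle ends, and
#' doubles as the caudal reference mask for streamline orientation.
#'
#' @param truth a [make_cohort_truth()] object (geometry source).
#' @param grid target [voxel_grid()].
#' @param seed_edge seed cube edge length (mm).
#' @return List with logical arrays `seed` (per side), `include`, `caudal`.
#' @export
roi_masks <- function(truth, grid, seed_edge = 6) {
  co <- grid_coords(grid)
  msk <- function(v) array(v, dim = grid$shape)
  seed <- list()
  for (side in c("left", "right")) {
    cl <- truth$centerlines[[side]]
    ctr <- cl$points[which.min(abs(cl$s - 0.95)), ]
    inb <- abs(co[, 1] - ctr[1]) <= seed_edge / 2 &
      abs(co[, 2] - ctr[2]) <= seed_edge / 2 &
      abs(co[, 3] - ctr[3]) <= seed_edge / 2
    seed[[side]] <- msk(inb)
  }
  zc <- min(truth$centerlines$left$points[, 3])
  slab <- co[, 3] >= zc - 4 & co[, 3] <= zc + 4
  list(seed = seed, include = msk(slab), caudal = msk(slab))
}

#' Generate a synthetic paired-hemisphere DWI cohort
#'
#' Each subject is a 4D DWI volume on `grid` under `scheme`, with ground
#' truth (lesioned hemisphere, lesional segment range, injected effects)
#' and ROI masks. With `materialize = "none"` only the ground truth is
#' generated (useful for large-n structural checks).
#'
#' @param n_subjects number of subjects.
#' @param scheme a [gradient_scheme()].
#' @param grid acquisition [voxel_grid()].
#' @param lesion a [lesion_spec()]; set all effects to 0 for a null cohort.
#' @param noise_sigma Rician channel SD; `NULL` uses SNR(b0) = 30, i.e.
#'   `S0/30`; 0 disables noise.
#' @param seed master seed; per-subject noise seeds derive from it.
#' @param crossing include the transverse crossing bundle.
#' @param tissue a [tissue_params()].
#' @param materialize `"dwi"` (volumes + masks), or `"none"`.
#' @return List of class `phantom_cohort` with `subjects` (each: `dwi`,
#'   `masks`, `truth`), `truth`, `scheme`, `grid`, `tissue`.
#' @export
make_cohort <- function(n_subjects, scheme = default_scheme(),
                        grid = centered_grid(), lesion = lesion_spec(),
                        noise_sigma = NULL, seed = 1L, crossing = FALSE,
                        tissue = tissue_params(),
                        materialize = c("dwi", "none")) {
  materialize <- match.arg(materialize)
  if (is.null(noise_sigma)) noise_sigma <- tissue$S0 / 30
  truth <- make_cohort_truth(n_subjects, lesion, seed)
  subjects <- lapply(truth$subjects, function(sub) {
    out <- list(truth = sub)
    if (materialize == "dwi") {
      cfg <- .voxel_config(truth, sub, grid, tissue, crossing, scheme)
      S <- .synth_signal(cfg, scheme)
      if (noise_sigma > 0) {
        set.seed(sub$noise_seed)
        S <- add_rician_noise(S, noise_sigma)
      }
      dwi <- array(t(S), dim = c(grid$shape, length(scheme$bvals)))
      out$dwi <- dwi
      out$masks <- roi_masks(truth, grid)
    }
    out
  })
  structure(list(subjects = subjects, truth = truth, scheme = scheme,
                 grid = grid, tissue = tissue, crossing = crossing,
                 noise_sigma = noise_sigma),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("phantom_cohort:", length(x$subjects), "subjects on",
      paste(x$grid$shape, collapse = "x"), "grid\n")
  invisible(x)
}

#' Analytic scalar maps from ground truth (scalar mode)
#'
#' The fast fixture path: FA and ADC are computed per voxel from the
#' noiseless forward signal via the IRLS tensor fit (the value the full
#' DWI chain converges to as noise goes to 0), and the FD map is the
#' ground-truth tract fiber fraction of whichever bundle occupies the
#' voxel. Lesion effects are included exactly as injected.
#'
#' @param truth a [make_cohort_truth()] object.
#' @param subject_index subject whose lesion to apply; `NULL` for the
#'   lesion-free geometry.
#' @param grid target [voxel_grid()].
#' @param scheme a [gradient_scheme()].
#' @param tissue a [tissue_params()].
#' @param crossing include the crossing bundle.
#' @return List of 3D arrays `fa`, `adc`, `fd` plus `hemisphere` (character
#'   array) and the lesion mask.
#' @export
scalar_mode_maps <- function(truth, subject_index = NULL,
                             grid = centered_grid(),
                             scheme = default_scheme(),
                             tissue = tissue_params(), crossing = FALSE) {
  sub <- if (is.null(subject_index)) NULL else truth$subjects[[subject_index]]
  cfg <- .voxel_config(truth, sub, grid, tissue, crossing, scheme)
  met <- .config_metrics(cfg, NULL, scheme)
  shp <- grid$shape
  list(fa = array(met$fa, shp), adc = array(met$adc, shp),
       fd = array(cfg$f_t, shp),
       hemisphere = array(cfg$hemisphere, shp),
       lesion = array(cfg$lesion, shp))
}
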