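# Memoized fixtures shared across test files.  Everything is generated in
# code at test time; the expensive chain runs are computed once per session.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (is.null(.fx[[key]])) assign(key, force(expr), envir = .fx)
  .fx[[key]]
}

# small single-fiber voxel set + response function
fx_response <- function() {
  fx_memo("response", {
    set.seed(42)
    sch <- default_scheme()
    dirs <- matrix(rnorm(90), 30)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    S <- sapply(seq_len(30), function(i) {
      simulate_signal(fx_voxel(dirs[i, ], f = 0.45), sch)
    })
    list(scheme = sch, response = estimate_response(S, sch, rep(TRUE, 30)),
         dirs = dirs)
  })
}

# a phantom-like voxel configuration
fx_voxel <- function(dir, f = 0.45, f2 = 0, dir2 = c(1, 0, 0),
                     d_iso = 3e-3) {
  comps <- list(list(dir = dir, f = f, lambda_par = 1.7e-3,
                     lambda_perp = 0.25e-3))
  if (f2 > 0) {
    comps <- c(comps, list(list(dir = dir2, f = f2, lambda_par = 1.7e-3,
                                lambda_perp = 0.25e-3)))
  }
  list(S0 = 1, f_iso = 1 - f - f2, d_iso = d_iso, compartments = comps)
}

fx_csd_voxel <- function(dir, f = 0.45, f2 = 0, dir2 = c(1, 0, 0)) {
  fr <- fx_response()
  sch <- fr$scheme
  dw <- sch$bvals > 0
  s <- simulate_signal(fx_voxel(dir, f, f2, dir2), sch)
  csd_fit(matrix(s[dw] / mean(s[!dw]), ncol = 1), fr$response, sch)
}

# default noiseless lesioned phantom, one subject, full chain at reduced
# streamline count (shared by phantom/tractometry/fixel/pipeline tests)
fx_chain <- function() {
  fx_memo("chain", {
    cohort <- make_cohort(1, lesion = lesion_spec(), noise_sigma = 0,
                          seed = 101)
    cfg <- pipeline_config(n_subjects = 1, seed = 101,
                           n_streamlines = 800L)
    res <- run_subject_chain(cohort, 1, cfg)
    list(cohort = cohort, res = res, cfg = cfg)
  })
}

# analytic single-direction FOD field in a straight tube along z, for
# tracking geometry tests that must not depend on the CSD stage
fx_straight_field <- function() {
  fx_memo("straight", {
    grid <- centered_grid(c(20L, 20L, 46L), 2)
    mesh <- sphere_mesh(3L)
    # lobe width ~20 deg: representable at lmax 8 and wide enough that
    # cone-sampled candidates hit it reliably
    lobe <- exp(-(acos(pmin(1, abs(mesh$vertices[, 3]))))^2 / (2 * 0.35^2))
    cf <- sh_fit(lobe, mesh$vertices, 8)
    co <- grid_coords(grid)
    intube <- abs(co[, 1]) <= 6 & abs(co[, 2]) <= 6
    coeffs <- matrix(0, length(cf), prod(grid$shape))
    coeffs[, intube] <- cf
    fod <- structure(list(coeffs = coeffs, grid = grid, lmax = 8L,
                          basis = "tractfd-rsh-even-1",
                          mask = array(intube, grid$shape)),
                     class = "fod_field")
    seed <- array(FALSE, grid$shape)
    seed[9:12, 9:12, 22:24] <- TRUE
    include <- array(TRUE, grid$shape)
    list(fod = fod, grid = grid, seed = seed, include = include)
  })
}
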