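test_that("multi-compartment signal matches closed forms", {
  sch <- default_scheme()
  # b = 0 gives S0 regardless of configuration
  cfg <- fx_voxel(c(0, 0, 1), f = 0.6)
  cfg$S0 <- 2.5
  s <- simulate_signal(cfg, sch)
  expect_equal(s[sch$bvals == 0], rep(2.5, 3))
  expect_true(all(s > 0))

  # pure isotropic: S = S0 exp(-b d)
  iso <- list(S0 = 1, f_iso = 1, d_iso = 2e-3, compartments = list())
  expect_equal(simulate_signal(iso, sch),
               exp(-sch$bvals * 2e-3))

  # single stick at 60 degrees to z, b = 1000: g'Dg evaluated by hand
  g <- c(sin(pi / 3), 0, cos(pi / 3))
  sch2 <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), g))
  stick <- list(S0 = 1, f_iso = 0, d_iso = 1e-3, compartments = list(
    list(dir = c(0, 0, 1), f = 1, lambda_par = 1.7e-3,
         lambda_perp = 0.2e-3)))
  # independent scalar evaluation: 0.2e-3 + 1.5e-3 * cos(60deg)^2 =
  # 5.75e-4; exp(-0.575) = 0.56270487
  expect_equal(simulate_signal(stick, sch2)[2], 0.56270487, tolerance = 1e-7)
})

test_that("invalid voxel configurations are rejected", {
  sch <- default_scheme()
  bad_dir <- fx_voxel(c(0, 0, 2))
  expect_error(simulate_signal(bad_dir, sch), "unit vector")
  bad_frac <- fx_voxel(c(0, 0, 1))
  bad_frac$f_iso <- 0.9
  expect_error(simulate_signal(bad_frac, sch), "sum to 1")
  bad_lam <- fx_voxel(c(0, 0, 1))
  bad_lam$compartments[[1]]$lambda_perp <- 2e-3
  expect_error(simulate_signal(bad_lam, sch), "lambda_par")
})

test_that("model ADC strictly increases with the isotropic fraction", {
  sch <- default_scheme()
  adc <- vapply(c(0.2, 0.4, 0.6, 0.8), function(fi) {
    cfg <- fx_voxel(c(0, 0, 1), f = 1 - fi)
    tf <- fit_tensor_irls(matrix(simulate_signal(cfg, sch), ncol = 1), sch)
    compute_adc(tf)
  }, numeric(1))
  expect_true(all(diff(adc) > 0))
})

test_that("null cohort hemispheres are voxel-wise mirror images", {
  truth <- make_cohort_truth(1, lesion_spec(effect_fa = 0, effect_adc = 0,
                                            effect_fd = 0), seed = 3)
  m <- scalar_mode_maps(truth, 1, centered_grid(), default_scheme())
  nx <- dim(m$fa)[1]
  # FA/ADC mirror up to the tensor-fit/multi-exponential interaction;
  # the FD (fiber fraction) map mirrors exactly
  expect_lt(max(abs(m$fa - m$fa[nx:1, , ]), na.rm = TRUE), 1e-3)
  expect_lt(max(abs(m$adc - m$adc[nx:1, , ]) / m$adc, na.rm = TRUE), 1e-3)
  expect_identical(m$fd, m$fd[nx:1, , ])
  # zero effects: lesioned subject's maps equal the lesion-free geometry
  m0 <- scalar_mode_maps(truth, NULL, centered_grid(), default_scheme())
  expect_equal(m$fa, m0$fa, tolerance = 1e-12)
})

test_that("a 65-subject cohort has exactly one lesioned hemisphere each", {
  cohort <- make_cohort(65, materialize = "none", seed = 9)
  expect_length(cohort$subjects, 65L)
  sides <- vapply(cohort$truth$subjects, `[[`, character(1), "lesion_side")
  expect_true(all(sides %in% c("left", "right")))
  expect_length(sides, 65L)
  rng <- t(vapply(cohort$truth$subjects, `[[`, integer(2), "lesion_range"))
  expect_true(all(rng[, 1] >= 25 & rng[, 2] <= 95 & rng[, 1] <= rng[, 2]))
})

test_that("cohort generation is bit-reproducible from the seed", {
  g <- centered_grid(c(16L, 16L, 16L), 2)
  spec0 <- lesion_spec(effect_fa = 0, effect_adc = 0, effect_fd = 0)
  c1 <- make_cohort(2, grid = g, lesion = spec0, seed = 77)
  c2 <- make_cohort(2, grid = g, lesion = spec0, seed = 77)
  expect_identical(c1$subjects[[1]]$dwi, c2$subjects[[1]]$dwi)
  expect_identical(c1$subjects[[2]]$dwi, c2$subjects[[2]]$dwi)
  expect_identical(c1$truth$subjects, c2$truth$subjects)
})

test_that("injected lesion effects appear with the stated sign and size", {
  fxc <- fx_chain()
  truth <- fxc$cohort$truth
  m <- scalar_mode_maps(truth, 1, fxc$cohort$grid, fxc$cohort$scheme)
  les <- which(m$lesion)
  expect_gt(length(les), 50)
  nx <- dim(m$adc)[1]
  ai <- arrayInd(les, dim(m$adc))
  mir <- cbind(nx + 1 - ai[, 1], ai[, 2], ai[, 3])
  expect_true(all(m$adc[les] > m$adc[mir]))
  expect_true(all(m$fa[les] < m$fa[mir]))
  expect_true(all(m$fd[les] < m$fd[mir]))
  eff <- truth$subjects[[1]]$effects
  expect_equal(mean(m$fa[les] - m$fa[mir]), -eff$fa, tolerance = 0.01)
  expect_equal(mean(m$adc[les] / m$adc[mir]), 1 + eff$adc, tolerance = 0.01)
  expect_equal(mean(m$fd[les] / m$fd[mir]), 1 - eff$fd, tolerance = 1e-6)
})

test_that("lesion ranges outside [1,100] are rejected", {
  truth <- make_cohort_truth(1, seed = 1)
  truth$subjects[[1]]$lesion_range <- c(90L, 120L)
  expect_error(
    scalar_mode_maps(truth, 1, centered_grid(c(16L, 16L, 16L), 4)),
    "within"
  )
})

test_that("imaging chain converges to the analytic maps at zero noise", {
  fxc <- fx_chain()
  cohort <- fxc$cohort
  res <- fxc$res
  up <- res$grid
  m_up <- scalar_mode_maps(cohort$truth, 1, up, cohort$scheme)

  # interior bundle voxels: near the centerline, away from tract ends and
  # from the lesion boundary where interpolation mixes configurations
  truth <- cohort$truth
  sub <- truth$subjects[[1]]
  co <- grid_coords(up)
  interior <- rep(FALSE, nrow(co))
  for (side in c("left", "right")) {
    nd <- tractfd:::.polyline_nearest_cpp(co, truth$centerlines[[side]]$points)
    s <- truth$centerlines[[side]]$s[nd$index]
    seg <- s * 99 + 1
    rng <- sub$lesion_range
    far <- if (side == sub$lesion_side) {
      seg < rng[1] - 3 | seg > rng[2] + 3 |
        (seg > rng[1] + 3 & seg < rng[2] - 3)
    } else TRUE
    interior <- interior | (nd$distance <= 4 & s > 0.05 & s < 0.95 & far)
  }
  expect_gt(sum(interior), 1000)
  rel_fa <- abs(res$maps$fa[interior] - m_up$fa[interior]) / m_up$fa[interior]
  rel_adc <- abs(res$maps$adc[interior] - m_up$adc[interior]) /
    m_up$adc[interior]
  expect_lt(max(rel_fa), 0.01)
  expect_lt(max(rel_adc), 0.01)

  # FD is in FOD-integral units: after one least-squares scale, the
  # healthy-hemisphere profile tracks the ground-truth fiber fraction
  tis <- cohort$tissue
  s <- (0:99) / 99
  ft <- tractfd:::.f_tract_profile(s, tis)
  fd <- res$profiles$healthy$fd$median
  int <- 8:93
  k <- sum(fd[int] * ft[int], na.rm = TRUE) / sum(ft[int]^2)
  expect_lt(max(abs(fd[int] - k * ft[int]) / (k * ft[int]), na.rm = TRUE),
            0.10)
})
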