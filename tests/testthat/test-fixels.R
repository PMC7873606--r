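test_that("lobe integrals match a fine-mesh quadrature oracle", {
  mesh <- sphere_mesh(3L)
  fine <- sphere_mesh(4L)   # 4x the triangle count
  set.seed(17)
  for (rep in 1:4) {
    d0 <- rnorm(3)
    d0 <- d0 / sqrt(sum(d0^2))
    fit <- fx_csd_voxel(d0, f = runif(1, 0.35, 0.6))
    fx <- segment_fod_lobes(fit$coeffs, mesh)
    j <- which.max(fx$fixels$fd)
    # oracle: dense quadrature of the positive FOD over the hemisphere
    # around the lobe axis (single-lobe FOD: the lobe pair is everything)
    amp <- pmax(fod_amplitude(fit$coeffs[, 1], fine$vertices), 0)
    oracle <- sum(amp * fine$weights) / 2
    expect_equal(fx$fixels$fd[j], oracle, tolerance = 0.02)
  }
})

test_that("all-zero FODs yield no fixels", {
  mesh <- sphere_mesh(3L)
  fx <- segment_fod_lobes(matrix(0, 45, 2), mesh)
  expect_equal(nrow(fx$fixels), 0L)
  expect_equal(fx$offsets, c(0L, 0L, 0L))
})

test_that("fixel tract density assigns steps by angle, hand-enumerated", {
  # toy: 2 voxels along x, voxel 1 has fixels along z and x, voxel 2 only x
  g <- centered_grid(c(2L, 1L, 1L), 2)
  fixels <- data.frame(
    voxel = c(1L, 1L, 2L),
    dir.x = c(0, 1, 1), dir.y = c(0, 0, 0), dir.z = c(1, 0, 0),
    fd = c(0.5, 0.3, 0.4), peak = c(1, 1, 1)
  )
  fset <- structure(list(fixels = fixels, offsets = c(0L, 2L, 3L),
                         n_vox = 2L, mesh_subdiv = 3L, grid = g),
                    class = "fixel_set")
  # streamline A: 3 steps along z in voxel 1 -> fixel 1 three times
  # streamline B: 1 step along x in voxel 2 -> fixel 3 once
  # streamline C: diagonal 44 deg from z in voxel 1 -> nearer fixel 1
  sl <- list(
    cbind(-1, 0, c(-0.6, -0.2, 0.2, 0.6)),
    rbind(c(0.6, 0, 0), c(1.4, 0, 0)),
    rbind(c(-1.2, 0, -0.3), c(-1.2 + 0.4 * sin(0.77), 0,
                              -0.3 + 0.4 * cos(0.77)))
  )
  tr <- structure(list(streamlines = sl, step = 0.4, grid = g,
                       meta = list()), class = "tractogram")
  counts <- tract_fixel_density(tr, fset, max_angle = pi / 4)
  expect_equal(counts, c(4L, 0L, 1L))
  # orthogonal tangents beyond max_angle stay unassigned
  tr2 <- structure(list(streamlines = list(rbind(c(0.6, 0, -0.2),
                                                 c(0.6, 0, 0.2))),
                        step = 0.4, grid = g, meta = list()),
                   class = "tractogram")
  expect_equal(tract_fixel_density(tr2, fset, max_angle = pi / 4),
               c(0L, 0L, 0L))
})

test_that("thresholding keeps exactly the sufficiently traversed fixels", {
  g <- centered_grid(c(2L, 1L, 1L), 2)
  fixels <- data.frame(voxel = c(1L, 1L, 2L), dir.x = c(0, 1, 1),
                       dir.y = 0, dir.z = c(1, 0, 0),
                       fd = c(0.5, 0.3, 0.4), peak = 1)
  fset <- structure(list(fixels = fixels, offsets = c(0L, 2L, 3L),
                         n_vox = 2L, mesh_subdiv = 3L, grid = g),
                    class = "fixel_set")
  density <- c(10L, 1L, 3L)
  expect_equal(nrow(threshold_fixels(fset, density, 1)$fixels), 3L)
  expect_equal(nrow(threshold_fixels(fset, density, 1e9)$fixels), 0L)
  kept <- threshold_fixels(fset, density, 3)
  expect_equal(kept$fixels$fd, c(0.5, 0.4))
  expect_equal(kept$offsets, c(0L, 1L, 2L))
  # default rule: max(1, 5% of max count)
  expect_equal(threshold_fixels(fset, density)$min_count, 1)
})

test_that("mean FD map averages retained fixels and keeps missing as NA", {
  g <- centered_grid(c(2L, 1L, 1L), 2)
  fixels <- data.frame(voxel = c(1L, 1L), dir.x = c(0, 1), dir.y = 0,
                       dir.z = c(1, 0), fd = c(0.4, 0.6), peak = 1)
  fset <- structure(list(fixels = fixels, offsets = c(0L, 2L, 2L),
                         n_vox = 2L, mesh_subdiv = 3L, grid = g),
                    class = "fixel_set")
  m <- mean_fd_map(fset)
  expect_equal(m[1, 1, 1], 0.5)
  expect_true(is.na(m[2, 1, 1]))
  # single fixel: its own FD
  one <- threshold_fixels(fset, c(5L, 0L), 1)
  expect_equal(mean_fd_map(one)[1, 1, 1], 0.4)
})

test_that("constant FD fields give constant along-tract profiles", {
  g <- centered_grid(c(8L, 8L, 8L), 2)
  fdmap <- array(0.42, g$shape)
  pts <- array(runif(6 * 100 * 3, -5, 5), c(6, 100, 3))
  vals <- fd_along_tract(pts, fdmap, g)
  expect_equal(as.numeric(vals), rep(0.42, 600))
})

test_that("crossing voxels retain the tract-aligned fixel after masking", {
  # phantom crossing configuration: tract along z, crossing along x
  mesh <- sphere_mesh(3L)
  fit <- fx_csd_voxel(c(0, 0, 1), f = 0.45, f2 = 0.45, dir2 = c(1, 0, 0))
  g <- centered_grid(c(1L, 1L, 1L), 2)
  fx <- segment_fod_lobes(fit$coeffs, mesh)
  fx$grid <- g
  # a tract running along z through the voxel
  tr <- structure(list(streamlines = list(cbind(0, 0, seq(-0.8, 0.8, 0.4))),
                       step = 0.4, grid = g, meta = list()),
                  class = "tractogram")
  dens <- tract_fixel_density(tr, fx)
  kept <- threshold_fixels(fx, dens, 1)
  expect_equal(nrow(kept$fixels), 1L)
  expect_gt(abs(kept$fixels$dir.z[1]), 0.95)
  # conservation: lobe segmentation preserves the total FOD integral
  amp <- fod_amplitude(fit$coeffs[, 1], mesh$vertices)
  total <- sum(pmax(amp, 0) * mesh$weights) / 2
  expect_lte(sum(fx$fixels$fd), total * 1.01)
  expect_gte(sum(fx$fixels$fd), total * 0.9)
})
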