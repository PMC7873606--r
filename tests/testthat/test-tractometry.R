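test_that("resampling places points at exact arc-length fractions", {
  # straight line: uniform spacing by symmetry
  line <- cbind(seq(0, 99, by = 9), 0, 0)
  r <- resample_streamline(line, 100L)
  expect_equal(r[, 1], seq(0, 99, length.out = 100))
  expect_equal(dim(r), c(100L, 3L))

  # any valid input yields exactly 100 points, endpoints preserved
  set.seed(14)
  pts <- apply(matrix(rnorm(3 * 17, sd = 2), ncol = 3), 2, cumsum)
  r2 <- resample_streamline(pts, 100L)
  expect_equal(nrow(r2), 100L)
  expect_equal(r2[1, ], pts[1, ])
  expect_equal(r2[100, ], pts[17, ])

  # brute-force cumulative-arc-length bisection oracle
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  total <- max(arc)
  oracle <- t(vapply(seq(0, total, length.out = 100), function(a) {
    lo <- 1
    hi <- nrow(pts)
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (arc[mid] <= a) lo <- mid else hi <- mid
    }
    w <- if (seg[lo] > 0) (a - arc[lo]) / seg[lo] else 0
    pts[lo, ] * (1 - w) + pts[min(lo + 1, nrow(pts)), ] * w
  }, numeric(3)))
  expect_equal(r2, oracle, tolerance = 1e-9, ignore_attr = TRUE)

  # arc length is preserved for smooth curves
  tt <- seq(0, 2 * pi, length.out = 400)
  helix <- cbind(10 * cos(tt), 10 * sin(tt), 3 * tt)
  rh <- resample_streamline(helix, 100L)
  len_in <- sum(sqrt(rowSums(diff(helix)^2)))
  len_out <- sum(sqrt(rowSums(diff(rh)^2)))
  expect_lt(abs(len_out - len_in) / len_in, 0.005)
  # uniform arc spacing: each output point sits at arc fraction
  # (i-1)/99 of the input polyline (projection onto its segment)
  seg <- sqrt(rowSums(diff(helix)^2))
  arc <- c(0, cumsum(seg))
  arcpos <- vapply(seq_len(100), function(i) {
    d2 <- rowSums(sweep(helix, 2, rh[i, ], "-")^2)
    j <- min(which.min(d2), nrow(helix) - 1L)
    if (j > 1 && sum((rh[i, ] - helix[j - 1, ])^2) < sum((rh[i, ] -
                                                            helix[j + 1, ])^2))
      j <- j - 1L
    u <- helix[j + 1, ] - helix[j, ]
    arc[j] + sum((rh[i, ] - helix[j, ]) * u) / sqrt(sum(u^2))
  }, numeric(1))
  expect_equal(arcpos / max(arc), seq(0, 1, length.out = 100),
               tolerance = 1e-6)

  expect_error(resample_streamline(matrix(0, 1, 3)), "at least 2")
  expect_error(resample_streamline(rbind(c(1, 1, 1), c(1, 1, 1))),
               "zero-length")
})

test_that("map sampling is trilinear with missing propagation", {
  g <- centered_grid(c(12L, 12L, 12L), 1.5)
  co <- grid_coords(g)
  ramp <- array(2 * co[, 1] - co[, 2] + 0.25 * co[, 3], g$shape)
  set.seed(15)
  pts <- array(runif(10 * 5 * 3, -6, 6), c(10, 5, 3))
  vals <- sample_map_along(pts, ramp, g)
  flat <- matrix(pts, 50, 3)
  expect_equal(as.numeric(vals),
               2 * flat[, 1] - flat[, 2] + 0.25 * flat[, 3],
               tolerance = 1e-9)
  # constant map
  expect_equal(as.numeric(sample_map_along(pts, array(3, g$shape), g)),
               rep(3, 50))
  # outside points are missing
  pts[1, 1, ] <- c(100, 0, 0)
  expect_true(is.na(sample_map_along(pts, ramp, g)[1, 1]))
})

test_that("streamline orientation is caudal-first and idempotent", {
  g <- centered_grid(c(10L, 10L, 20L), 2)
  caudal <- array(FALSE, g$shape)
  caudal[, , 1:2] <- TRUE    # low-z slab
  sls <- list(
    cbind(0, 0, seq(-15, 15, by = 2)),        # already caudal-first
    cbind(1, 0, seq(15, -15, by = -2)),       # reversed
    cbind(-1, 0.5, seq(-11, 11, by = 2))      # caudal-first
  )
  tr <- structure(list(streamlines = sls, step = 2, grid = g,
                       meta = list()), class = "tractogram")
  o1 <- orient_streamlines(tr, caudal, g)
  for (sl in o1$streamlines) expect_lt(sl[1, 3], sl[nrow(sl), 3])
  o2 <- orient_streamlines(o1, caudal, g)
  expect_identical(o1$streamlines, o2$streamlines)
  # hand labels: only the second needed flipping
  expect_identical(o1$streamlines[[1]], sls[[1]])
  expect_identical(o1$streamlines[[3]], sls[[3]])
  expect_identical(o1$streamlines[[2]],
                   sls[[2]][rev(seq_len(nrow(sls[[2]]))), ])
})

test_that("segment medians use the even-count rule and flag missing", {
  expect_equal(segment_medians(matrix(1:5, 1))$median, 1:5)   # S = 1
  v <- matrix(c(1, 2, 3, 100), 4, 1)
  expect_equal(segment_medians(v)$median, 2.5)
  set.seed(16)
  m <- matrix(rnorm(40 * 7), 40, 7)
  sm <- segment_medians(m)
  oracle <- apply(m, 2, function(x) {
    s <- sort(x)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else mean(s[n / 2 + 0:1])
  })
  expect_equal(sm$median, oracle)
  # missing values are excluded; all-missing segments flagged
  m[, 3] <- NA
  m[1:39, 5] <- NA
  sm2 <- segment_medians(m)
  expect_true(sm2$missing[3])
  expect_equal(sm2$median[5], m[40, 5])
  expect_equal(sm2$n_streamlines, c(40L, 40L, 0L, 40L, 1L, 40L, 40L))
  expect_error(segment_medians(matrix(0, 0, 5)), "at least one")
})

test_that("peritumoral labels mark the range and derive interface bands", {
  lab <- label_peritumoral(c(40, 60), voxel_size = 1.3,
                           mean_segment_length = 0.7)
  expect_equal(sum(lab$peritumoral), 21L)
  expect_true(all(which(lab$peritumoral) == 40:60))
  # width: 3 voxels x 1.3 mm / 0.7 mm per segment ~ 6 segments, by the
  # same arc-length arithmetic performed independently here
  expect_equal(lab$width, round(3 * 1.3 / 0.7))
  expect_equal(lab$interface_external,
               c(seq(40 - lab$width, 39), seq(61, 60 + lab$width)))
  expect_equal(lab$interface_internal,
               c(seq(40, 40 + lab$width - 1), seq(60 - lab$width + 1, 60)))

  empty <- label_peritumoral(NULL)
  expect_false(any(empty$peritumoral))
  expect_error(label_peritumoral(c(60, 40)), "a <= b")
  expect_error(label_peritumoral(c(0, 10)), "within")
  # ranges touching the tract ends clip their bands
  lab2 <- label_peritumoral(c(95, 100), voxel_size = 1.3,
                            mean_segment_length = 0.7)
  expect_true(all(lab2$interface_external < 95))
})
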