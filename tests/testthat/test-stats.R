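test_that("stats config encodes the Bonferroni adjustment", {
  cfg <- stats_config()
  expect_equal(cfg$adjusted_alpha, cfg$alpha / cfg$n_segments)
  expect_equal(stats_config(alpha = 0.01, n_segments = 50)$adjusted_alpha,
               2e-4)
})

test_that("table assembly yields the expected row counts", {
  mk_profiles <- function(n, drop = NULL) {
    lapply(seq_len(n), function(i) {
      v <- lapply(setNames(nm = c("fa", "adc", "fd")),
                  function(m) rep(0.5, 100))
      h <- v
      if (!is.null(drop) && i <= length(drop)) {
        for (m in names(h)) h[[m]][drop[[i]]] <- NA
      }
      list(healthy = h, pathological = v)
    })
  }
  tab1 <- assemble_table(mk_profiles(1))
  expect_equal(sum(tab1$metric == "fa"), 200L)
  # 2 subjects, 3 segments flagged missing in one hemisphere:
  # 2*2*100 - 3 = 397 rows per metric (verified by enumeration)
  tab2 <- assemble_table(mk_profiles(2, drop = list(c(10, 50, 90))))
  expect_equal(sum(tab2$metric == "fa"), 397L)
  expect_equal(nrow(tab2), 3L * 397L)
  # rejection when a hemisphere is absent
  broken <- mk_profiles(1)
  broken[[1]]$pathological <- NULL
  expect_error(assemble_table(broken), "missing a hemisphere")
})

test_that("the LMM recovers degenerate closed forms and the null", {
  # balanced two-subject toy with zero within-cell variance: the fixed
  # effect equals the plain mean difference
  d <- data.frame(
    subject = rep(1:2, each = 4),
    hemisphere = rep(c(0L, 0L, 1L, 1L), 2),
    segment = rep(1:2, 4),
    metric = "fa",
    value = c(0.5, 0.5, 0.4, 0.4, 0.7, 0.7, 0.6, 0.6),
    peritumoral = FALSE
  )
  fit <- suppressMessages(suppressWarnings(fit_hemisphere_lmm(d, "fa")))
  expect_equal(fit$estimate, -0.1, tolerance = 1e-6)

  # null profile cohort: CI contains 0
  pc <- make_profile_cohort(12, lesion_spec(effect_fa = 0, effect_adc = 0,
                                            effect_fd = 0), seed = 21)
  f0 <- fit_hemisphere_lmm(pc$records, "fa")
  expect_true(f0$ci[1] <= 0 && 0 <= f0$ci[2])
  expect_gt(f0$p, 0.05)
  expect_true(f0$converged)
  expect_length(f0$diagnostics$residuals, f0$n_obs)
  expect_error(fit_hemisphere_lmm(d[d$subject == 1, ], "fa"), "2 subjects")
})

test_that("segment-wise tests localize an injected offset", {
  # identical hemispheres: nothing significant
  pc0 <- make_profile_cohort(10, lesion_spec(effect_fa = 0, effect_adc = 0,
                                             effect_fd = 0), seed = 22)
  st0 <- segmentwise_tests(pc0$records, "fa")
  expect_false(any(st0$significant[st0$n_pairs >= 3], na.rm = TRUE))

  # constant offset >> noise in segments 40-60 only
  pc1 <- make_profile_cohort(10, lesion_spec(effect_fa = 0.3,
                                             effect_adc = 0,
                                             effect_fd = 0),
                             seed = 23, common_range = c(40, 60))
  st1 <- segmentwise_tests(pc1$records, "fa")
  sig <- which(st1$significant)
  expect_true(all(sig >= 39 & sig <= 61))
  expect_true(all(41:59 %in% sig))

  # zero-variance differences are untestable, not p = 0
  d <- data.frame(subject = rep(1:5, each = 2),
                  hemisphere = rep(0:1, 5), segment = 1L, metric = "fa",
                  value = rep(c(0.5, 0.4), 5), peritumoral = FALSE)
  st2 <- segmentwise_tests(d, "fa", stats_config(n_segments = 1L))
  expect_true(is.na(st2$significant[1]))
  expect_equal(st2$n_pairs[1], 5L)
})

test_that("Cliff's delta matches brute-force pair counting", {
  expect_equal(cliffs_delta(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  # independent brute force by explicit loops
  brute <- function(x, y) {
    gt <- 0
    lt <- 0
    for (xi in x) for (yj in y) {
      if (xi > yj) gt <- gt + 1
      if (xi < yj) lt <- lt + 1
    }
    (gt - lt) / (length(x) * length(y))
  }
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 3, 4)),
               brute(c(1, 2, 3), c(2, 3, 4)))
  set.seed(24)
  for (rep in 1:10) {
    x <- rnorm(sample(3:12, 1))
    y <- rnorm(sample(3:12, 1))
    expect_equal(cliffs_delta(x, y), brute(x, y))
    expect_equal(cliffs_delta(x, y), -cliffs_delta(y, x))
  }
  expect_error(cliffs_delta(numeric(), 1:3), "non-empty")
})

test_that("segment classification gates on significance and effect size", {
  cfg <- stats_config()
  expect_equal(classify_segments(rep(FALSE, 5), rep(1, 5), cfg), rep(0L, 5))
  expect_equal(classify_segments(rep(TRUE, 5), rep(-1, 5), cfg), rep(1L, 5))
  dec <- c(TRUE, TRUE, FALSE, NA, TRUE)
  del <- c(0.9, 0.2, 0.9, 0.9, -0.5)
  expect_equal(classify_segments(dec, del, cfg),
               c(1L, 0L, 0L, NA_integer_, 1L))
  expect_error(classify_segments(dec, del[1:3], cfg), "aligned")
})

test_that("confusion metrics implement the quoted formulas", {
  perfect <- confusion_metrics(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  # TP=3, FN=1, TN=6, FP=2 -> 0.75 / 0.75
  pred <- c(rep(1, 3), rep(0, 1), rep(0, 6), rep(1, 2))
  truth <- c(rep(TRUE, 4), rep(FALSE, 8))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 0.75)
  expect_equal(unname(cm$counts), c(3L, 2L, 6L, 1L))
  expect_equal(sum(cm$counts), cm$n_evaluated)
  # all-negative prediction: sensitivity 0; no positives: NA flagged
  expect_equal(confusion_metrics(rep(0, 4), c(TRUE, TRUE, FALSE, FALSE))$
                 sensitivity, 0)
  expect_true(is.na(confusion_metrics(rep(1, 3), rep(TRUE, 3))$specificity))
})

test_that("strong-effect cohorts reach high detection power", {
  pc <- make_profile_cohort(20, seed = 17, common_range = c(40, 60))
  truth <- seq_len(100) %in% 40:60
  cfg <- stats_config()
  for (m in c("fa", "adc", "fd")) {
    st <- segmentwise_tests(pc$records, m, cfg)
    dl <- segmentwise_cliffs_delta(pc$records, m)
    cm <- confusion_metrics(classify_segments(st$significant, dl, cfg),
                            truth)
    expect_gte(cm$sensitivity, 0.9)
    expect_gte(cm$specificity, 0.9)
  }
})

test_that("interface classes partition segments and order as injected", {
  pc <- make_profile_cohort(8, seed = 25)
  isum <- interface_summaries(pc$records, pc$labels)
  expect_equal(sum(isum$n), 8L * 100L * 3L)
  for (m in c("fa", "fd")) {
    expect_lt(isum$mean_diff[isum$metric == m & isum$class == "lesional"],
              isum$mean_diff[isum$metric == m & isum$class == "healthy"])
  }
  expect_gt(isum$mean_diff[isum$metric == "adc" & isum$class == "lesional"],
            isum$mean_diff[isum$metric == "adc" & isum$class == "healthy"])
})
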