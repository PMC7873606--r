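test_that("noiseless single-tensor signals are recovered exactly", {
  sch <- default_scheme()
  set.seed(4)
  for (rep in 1:3) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    lam <- sort(runif(3, 2e-4, 2e-3), decreasing = TRUE)
    D <- R %*% diag(lam) %*% t(R)
    S <- exp(-sch$bvals * rowSums((sch$bvecs %*% D) * sch$bvecs))
    tf <- fit_tensor_irls(matrix(S, ncol = 1), sch)
    expect_equal(tf$evals[, 1], lam, tolerance = 1e-8)
  }
  # isotropic signal gives three equal eigenvalues
  S <- exp(-sch$bvals * 1e-3)
  tf <- fit_tensor_irls(matrix(S, ncol = 1), sch)
  expect_equal(max(tf$evals[, 1]) - min(tf$evals[, 1]), 0, tolerance = 1e-9)
})

test_that("ADC and FA match their formulas and hand-computed values", {
  sch <- default_scheme()
  mk_tf <- function(lam) {
    D <- diag(lam)
    S <- exp(-sch$bvals * rowSums((sch$bvecs %*% D) * sch$bvecs))
    fit_tensor_irls(matrix(S, ncol = 1), sch)
  }
  tf <- mk_tf(c(1e-3, 1e-3, 1e-3))
  expect_equal(compute_adc(tf), 1e-3, tolerance = 1e-9)
  expect_equal(compute_fa(tf), 0, tolerance = 1e-6)

  tf2 <- mk_tf(c(1.7e-3, 0.3e-3, 0.3e-3))
  expect_equal(compute_adc(tf2), 0.76667e-3, tolerance = 1e-4)
  # independent formula evaluation
  lam <- c(1.7, 0.3, 0.3) * 1e-3
  fa_oracle <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) /
    sqrt(sum(lam^2))
  expect_equal(compute_fa(tf2), fa_oracle, tolerance = 1e-8)
})

test_that("FA/ADC agree with a brute-force eigendecomposition oracle", {
  sch <- default_scheme()
  set.seed(5)
  n <- 100
  S <- matrix(0, length(sch$bvals), n)
  Ds <- vector("list", n)
  for (i in seq_len(n)) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    lam <- runif(3, 1e-4, 2.5e-3)
    D <- R %*% diag(lam) %*% t(R)
    Ds[[i]] <- D
    S[, i] <- exp(-sch$bvals * rowSums((sch$bvecs %*% D) * sch$bvecs))
  }
  tf <- fit_tensor_irls(S, sch)
  fa <- compute_fa(tf)
  adc <- compute_adc(tf)
  for (i in seq_len(n)) {
    ev <- sort(eigen(Ds[[i]], symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(adc[i], mean(ev), tolerance = 1e-6)
    expect_equal(fa[i], sqrt(1.5) * sqrt(sum((ev - mean(ev))^2)) /
                   sqrt(sum(ev^2)), tolerance = 1e-6)
    expect_true(fa[i] >= 0 && fa[i] <= 1)
  }
})

test_that("FA/ADC are invariant under joint rotation of tensor and scheme", {
  sch <- default_scheme()
  lam <- c(1.6e-3, 0.5e-3, 0.2e-3)
  set.seed(6)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  D1 <- diag(lam)
  D2 <- R %*% D1 %*% t(R)
  S1 <- exp(-sch$bvals * rowSums((sch$bvecs %*% D1) * sch$bvecs))
  # rotate the gradient directions together with the tensor
  sch_rot <- gradient_scheme(sch$bvals, sch$bvecs %*% t(R))
  S2 <- exp(-sch_rot$bvals *
              rowSums((sch_rot$bvecs %*% D2) * sch_rot$bvecs))
  tf1 <- fit_tensor_irls(matrix(S1, ncol = 1), sch)
  tf2 <- fit_tensor_irls(matrix(S2, ncol = 1), sch_rot)
  expect_equal(compute_fa(tf1), compute_fa(tf2), tolerance = 1e-6)
  expect_equal(compute_adc(tf1), compute_adc(tf2), tolerance = 1e-6)
})

test_that("IRLS reduces Rician eigenvalue bias relative to unweighted LLS", {
  sch <- default_scheme()
  lam <- c(1.7e-3, 0.25e-3, 0.25e-3)
  D <- diag(lam)
  S0 <- exp(-sch$bvals * rowSums((sch$bvecs %*% D) * sch$bvecs))
  set.seed(7)
  n <- 500
  S <- matrix(S0, length(S0), n)
  S <- add_rician_noise(S, 1 / 25)
  lls <- fit_tensor_irls(S, sch, n_iter = 0L)
  irls <- fit_tensor_irls(S, sch, n_iter = 2L)
  bias_lls <- abs(median(lls$evals[1, ]) - lam[1])
  bias_irls <- abs(median(irls$evals[1, ]) - lam[1])
  expect_lt(bias_irls, bias_lls)
})

test_that("degenerate inputs are rejected or masked", {
  # too few distinct directions: rank-deficient design
  g <- rbind(c(0, 0, 0), matrix(rep(c(0, 0, 1), 8), ncol = 3, byrow = TRUE))
  sch_bad <- gradient_scheme(c(0, rep(1000, 8)), g)
  expect_error(fit_tensor_irls(matrix(1, 9, 1), sch_bad), "rank-deficient")
  # mask propagates
  sch <- default_scheme()
  S <- matrix(exp(-sch$bvals * 1e-3), length(sch$bvals), 4)
  tf <- fit_tensor_irls(S, sch, mask = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(is.na(compute_adc(tf)), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(is.na(compute_fa(tf)), c(FALSE, TRUE, FALSE, TRUE))
})
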