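test_that("shape statistics match hand examples and basic properties", {
  expect_equal(stat_surface(c(1, -1, 0, 0)), 2)
  expect_equal(stat_surface(rep(0, 6)), 0)
  expect_equal(stat_peak(c(0, 3, -5, 3)), 5)
  expect_equal(stat_delay(c(0, 3, -5, 3)), 3L)
  expect_equal(stat_peak(rep(0, 4)), 0)
  expect_equal(stat_delay(rep(0, 4)), 1L)  # ties break to the smallest lag
  set.seed(1)
  for (r in 1:20) {
    srf <- rnorm(12)
    a <- runif(1, 0.1, 5)
    expect_equal(stat_surface(a * srf), a * stat_surface(srf))
    expect_lte(stat_peak(srf), stat_surface(srf))
    # sign-flip invariance
    expect_equal(stat_peak(-srf), stat_peak(srf))
    expect_equal(stat_surface(-srf), stat_surface(srf))
    expect_equal(stat_delay(-srf), stat_delay(srf))
  }
})

test_that("the null metric is a ridge-regularized inverse covariance", {
  set.seed(2)
  # isotropic nulls: metric is approximately a scaled identity
  A <- matrix(rnorm(4000, sd = 2), 1000, 4)
  Sig <- null_metric(A, ridge_frac = 0.05)
  off <- Sig - diag(diag(Sig))
  expect_lt(max(abs(off)), 0.1 * max(diag(Sig)))
  expect_equal(max(diag(Sig)) / min(diag(Sig)), 1, tolerance = 0.2)
  # with the metric near (1/c) I, the MD statistic is a scaled Euclidean norm
  v <- rnorm(4)
  expect_equal(stat_md(v, Sig), sqrt(sum(v^2) * mean(diag(Sig))),
               tolerance = 0.1)

  # rank-1 null set: ridge still yields a positive definite metric
  expect_warning(S1 <- null_metric(matrix(c(1, 0, 0), 1), ridge_frac = 0.05),
                 "null vectors")
  ev <- eigen(S1, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))

  # random inputs: symmetric positive definite
  B <- matrix(rnorm(60), 20, 3)
  S2 <- null_metric(B)
  expect_equal(S2, t(S2), tolerance = 1e-12)
  expect_true(all(eigen(S2, only.values = TRUE)$values > 0))

  expect_warning(null_metric(matrix(0, 5, 3)), "identity")
})

test_that("the MD statistic matches hand computation and contracts", {
  expect_equal(stat_md(c(1, 1), matrix(c(2, 0, 0, 1), 2)), sqrt(3))
  expect_equal(stat_md(c(0, 0), diag(2)), 0)
  expect_equal(stat_md(c(3, 4), diag(2)), 5)
  expect_error(stat_md(c(1, 1), matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("likelihood ratios match an independent unregularized fit", {
  # oracle: stats::glm logistic deviances on the same design
  basis <- make_gamma_basis(3, 6)
  sim <- simulate_network(tiny_net(w = 2), 3000, seed = 6)
  sm <- sim$spikes
  design <- build_design(sm, basis)
  fit <- fit_glm(sm, 2, basis, eta = 0, design = design)
  lrs <- lr_statistics(fit, sm, basis, design = design)
  y <- spikeconn:::response_vector(sm, design, 2)
  X <- design$X[, -1]
  g_full <- suppressWarnings(glm.fit(cbind(1, X), y, family = binomial()))
  for (src in lrs$source) {
    drop <- spikeconn:::loading_cols(design, src) - 1L
    g_null <- suppressWarnings(glm.fit(cbind(1, X[, -drop]), y,
                                       family = binomial()))
    lr_oracle <- g_null$deviance - g_full$deviance
    expect_equal(lrs$lr[lrs$source == src], lr_oracle, tolerance = 1e-4)
  }
})

test_that("lr_statistic enforces its contract and trivial cases", {
  basis <- make_gamma_basis(2, 4)
  sm <- random_spikes(2, 200, p = 0.1, seed = 7)
  f1 <- fit_glm(sm, 1, basis, eta = 0.1)
  expect_equal(lr_statistic(f1, f1), 0)
  f2 <- fit_glm(sm, 2, basis, eta = 0.1)
  expect_error(lr_statistic(f1, f2), "share")
  f3 <- fit_glm(sm, 1, basis, eta = 0.5)
  expect_error(lr_statistic(f1, f3), "share")
})

test_that("MaxZ thresholding is equivalent to Wald CI detection", {
  # with the raw-lag basis, max_s Z(s) = max_k Z_k exactly, so MaxZ > z*
  # iff some per-weight CI at the matching level excludes zero
  basis <- make_identity_basis(5)
  set.seed(8)
  sim <- simulate_network(tiny_net(w = 2.5), 4000, seed = 8)
  fit <- fit_glm(sim$spikes, 2, basis, eta = 0.05)
  zq <- qnorm(0.975)
  for (src in 1:3) {
    mz <- stat_maxz(fit, basis, src)
    ci <- wald_ci(fit, src)
    ci_detect <- any(ci$lower > 0 | ci$upper < 0)
    expect_identical(mz > zq, ci_detect)
  }
})

test_that("MaxZ matches direct substitution for a single basis", {
  basis <- make_gamma_basis(1, 6)
  f <- structure(list(loadings = matrix(2, 1, 1),
                      se_loadings = matrix(1, 1, 1)),
                 class = "neuron_glm")
  expect_equal(stat_maxz(f, basis, 1), 2 * max(basis$values[1, ]))
  fz <- structure(list(loadings = matrix(0, 1, 1),
                       se_loadings = matrix(1, 1, 1)),
                  class = "neuron_glm")
  expect_equal(stat_maxz(fz, basis, 1), 0)
  ci <- wald_ci(fz, 1)
  expect_true(ci$lower <= 0 & ci$upper >= 0)
})
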