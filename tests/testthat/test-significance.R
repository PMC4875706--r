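test_that("chi-square p-values match closed forms and monotonicity", {
  expect_equal(chi2_pvalues(0, 5), 1)
  expect_equal(chi2_pvalues(3.841459, 1), 0.05, tolerance = 1e-6)
  lr <- seq(0.1, 20, by = 0.4)
  expect_true(all(diff(chi2_pvalues(lr, 4)) < 0))
  expect_error(chi2_pvalues(1, 0), "dof")
  expect_error(chi2_pvalues(-1, 2), "nonnegative")
})

test_that("empirical degrees of freedom track the null mean", {
  expect_warning(expect_equal(fit_null_dof(rep(7, 10)), 7), "noisy")
  set.seed(1)
  x <- rchisq(10000, df = 5)
  expect_equal(fit_null_dof(x), 5, tolerance = 0.1)
  expect_equal(fit_null_dof(x, "mle"), 5, tolerance = 0.1)
  expect_identical(fit_null_dof(x), fit_null_dof(sample(x)))
  expect_error(fit_null_dof(numeric(0)), "no null samples")
})

test_that("BH q-values reproduce the hand example and dominate p", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(50)
  expect_true(all(bh_qvalues(p) >= p))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("direct q-values reproduce the add-one hand example", {
  r <- eb_qvalues(c(0.5, 4), c(1, 2, 3), pi0 = 1)
  expect_equal(r$table$q, c(1.0, 0.5))
})

test_that("q-values are monotone in the statistic and rank-invariant", {
  set.seed(3)
  real <- rchisq(120, 3); null <- rchisq(200, 3)
  eb <- eb_qvalues(real, null)
  ord <- order(real)
  expect_true(all(diff(eb$table$q[ord]) <= 1e-12))
  # strictly monotone transform leaves q unchanged
  tr <- function(x) log1p(x)^1.5
  eb2 <- eb_qvalues(tr(real), tr(null), pi0 = eb$pi0)
  expect_equal(eb2$table$q, eb$table$q, tolerance = 1e-12)
})

test_that("statistics drawn from the null give q near one in the bulk", {
  set.seed(4)
  real <- rchisq(300, 4); null <- rchisq(300, 4)
  eb <- eb_qvalues(real, null, pi0 = 1)
  mid <- real > quantile(real, 0.3) & real < quantile(real, 0.7)
  expect_gt(mean(eb$table$q[mid]), 0.75)
})

test_that("q-values are conservative on exchangeable two-group data", {
  set.seed(5)
  taus <- c(0.05, 0.1, 0.2, 0.3)
  fdp <- matrix(NA_real_, 25, length(taus))
  for (r in 1:25) {
    null <- rchisq(280, 4)
    real <- c(rchisq(180, 4), rchisq(30, 4, ncp = 25))
    truth <- rep(c(FALSE, TRUE), c(180, 30))
    eb <- eb_qvalues(real, null)
    fdp[r, ] <- fdp_curve(eb$table$q, truth, taus)$fdp
  }
  mfdp <- colMeans(fdp)
  mcse <- apply(fdp, 2, sd) / sqrt(nrow(fdp))
  expect_true(all(mfdp <= taus + 2 * mcse))
  expect_error(eb_qvalues(1:3, numeric(0)), "null samples")
})

test_that("the pi0 estimator is close on synthetic mixtures and capped at 1", {
  set.seed(6)
  pi0s <- replicate(20, {
    null <- rchisq(500, 4)
    real <- c(rchisq(425, 4), rchisq(75, 4, ncp = 30))
    eb_qvalues(real, null)$pi0
  })
  expect_equal(mean(pi0s), 0.85, tolerance = 0.05)
  eb1 <- eb_qvalues(rchisq(200, 4), rchisq(200, 4))
  expect_lte(eb1$pi0, 1)
})

test_that("a null network yields few discoveries and a bitwise-stable table", {
  net <- tiny_net(w = 0)
  net$C <- 6L
  net$adjacency <- matrix(0, 6, 6)
  net$baselines <- rep(-4.5, 6)
  net$private_rates <- rep(80, 6)
  sim <- simulate_network(net, 4000, seed = 7)
  basis <- make_gamma_basis(3, 8)
  cfg <- fc_config("EB-surface", eta = 1, seed = 7)
  tab <- run_test_suite(sim$spikes, basis = basis, config = cfg)
  expect_lte(sum(tab$q < 0.2), 0.2 * nrow(tab))
  tab2 <- run_test_suite(sim$spikes, basis = basis, config = cfg)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))

  f <- withr::local_tempfile()
  write_connection_table(tab, f)
  back <- read_connection_table(f)
  expect_equal(back$q, tab$q, tolerance = 0)
  expect_identical(fdp_curve(back$q, rep(FALSE, nrow(back))),
                   fdp_curve(tab$q, rep(FALSE, nrow(tab))))
})

test_that("the pipeline reports coherent statistics for a true connection", {
  sim <- simulate_network(tiny_net(w = 3), 6000, seed = 8)
  basis <- make_gamma_basis(3, 8)
  tab <- run_test_suite(sim$spikes, basis = basis,
                        config = fc_config("EB-regularized-LR", eta = 0.5,
                                           seed = 8))
  expect_s3_class(tab, "connection_table")
  expect_equal(nrow(tab), 6L)
  row <- tab[tab$source == 1 & tab$dest == 2, ]
  expect_equal(row$q, min(tab$q))
  expect_true(all(tab$peak <= tab$surface + 1e-12))
  expect_true(all(tab$delay >= 1 & tab$delay <= basis$M))
  # the chi-square track exposes p-values instead of local fdr
  tc <- run_test_suite(sim$spikes, basis = basis,
                       config = fc_config("CHI2", seed = 8))
  expect_true(all(tc$p >= 0 & tc$p <= 1))
  expect_true(all(tc$q >= tc$p - 1e-12))
})
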