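manual_fit <- function(baseline, loadings, target = 1, eta = 0,
                       reg_kind = "L2", link = "logistic") {
  structure(list(baseline = baseline, ext_coef = numeric(0),
                 loadings = loadings, link = link, eta = eta,
                 reg_kind = reg_kind, target = target),
            class = "neuron_glm")
}

test_that("total response reduces to the baseline and to direct substitution", {
  basis <- make_gamma_basis(3, 8)
  sm <- random_spikes(3, 60, p = 0.1, seed = 2)
  z <- manual_fit(1.25, matrix(0, 3, 3))
  expect_equal(total_response(z, sm, basis, t = 9:60), rep(1.25, 52))

  # one spike of neuron 2 at bin 20, single loading a on basis k = 2:
  # lambda(20 + s0) = baseline + a * B_2(s0)
  counts <- matrix(0L, 3, 60); counts[2, 20] <- 1L
  sm1 <- spike_matrix(counts)
  A <- matrix(0, 3, 3); A[2, 2] <- 0.7
  f <- manual_fit(-1, A)
  for (s0 in c(1, 3, 8))
    expect_equal(total_response(f, sm1, basis, t = 20 + s0),
                 -1 + 0.7 * basis$values[2, s0], tolerance = 1e-12)
})

test_that("total response matches a brute-force triple loop with external input", {
  set.seed(4)
  basis <- make_gamma_basis(3, 6)
  sm <- random_spikes(3, 50, p = 0.15, seed = 4)
  ext <- external_inputs(matrix(rnorm(2 * 50), 2, 50), "given")
  A <- matrix(rnorm(9), 3, 3)
  f <- manual_fit(0.3, A)
  f$ext_coef <- c(0.5, -0.2)
  lam <- total_response(f, sm, basis, ext, t = 7:50)
  for (i in seq_along(7:50)) {
    t <- (7:50)[i]
    expect_equal(lam[i],
                 brute_total_response(0.3, c(0.5, -0.2), A, basis, sm$counts,
                                      ext$signals, t),
                 tolerance = 1e-10)
  }
})

test_that("objective matches hand values for zero parameters and penalties", {
  basis <- make_gamma_basis(2, 5)
  sm <- random_spikes(2, 30, p = 0.2, seed = 5)
  z <- manual_fit(0, matrix(0, 2, 2))
  ob <- glm_objective(z, sm, basis)
  expect_equal(ob$loglik, (30 - 5) * log(0.5), tolerance = 1e-12)
  expect_equal(ob$penalty, 0)

  A <- matrix(0, 2, 2); A[1, 1] <- 2
  expect_equal(glm_objective(manual_fit(0, A, eta = 1), sm, basis)$penalty, 2)
  A2 <- matrix(0, 2, 2); A2[1, ] <- c(3, 4)
  expect_equal(glm_objective(manual_fit(0, A2, eta = 1,
                                        reg_kind = "group_lasso"),
                             sm, basis)$penalty, 5)
})

test_that("analytic gradient of the L2 objective matches finite differences", {
  basis <- make_gamma_basis(2, 4)
  sm <- random_spikes(2, 80, p = 0.15, seed = 6)
  design <- build_design(sm, basis)
  y <- spikeconn:::response_vector(sm, design, 1)
  pen <- spikeconn:::penalty_mask(design)
  set.seed(6)
  beta <- rnorm(ncol(design$X), sd = 0.3)
  eta <- 0.7
  obj <- function(b) spikeconn:::cpp_loglik(design$X, y, b, 0L) -
    eta * 0.5 * sum(pen * b^2)
  g_an <- analytic_gradient(design$X, y, beta, eta, pen, "logistic")
  h <- 1e-6
  g_fd <- vapply(seq_along(beta), function(j) {
    e <- numeric(length(beta)); e[j] <- h
    (obj(beta + e) - obj(beta - e)) / (2 * h)
  }, 0)
  expect_equal(g_an, g_fd, tolerance = 1e-5)
})

test_that("penalty-dominated L2 fits collapse loadings onto the empirical rate", {
  basis <- make_gamma_basis(3, 8)
  sm <- random_spikes(4, 400, p = 0.1, seed = 7)
  fit <- fit_glm(sm, 2, basis, eta = 1e6, reg_kind = "L2")
  expect_true(all(abs(fit$loadings) < 1e-4))
  rate <- mean(spikeconn:::response_vector(sm, build_design(sm, basis), 2))
  expect_equal(fit$baseline, log(rate / (1 - rate)), tolerance = 1e-3)
})

test_that("the convex problems reach the same optimum from different starts", {
  basis <- make_gamma_basis(3, 8)
  sm <- random_spikes(3, 500, p = 0.08, seed = 8)
  design <- build_design(sm, basis)
  set.seed(8)
  for (reg in c("L2", "group_lasso")) {
    f1 <- fit_glm(sm, 1, basis, eta = 0.5, reg_kind = reg, design = design)
    f2 <- fit_glm(sm, 1, basis, eta = 0.5, reg_kind = reg, design = design,
                  init = rnorm(ncol(design$X), sd = 0.2))
    expect_equal(f1$objective_value, f2$objective_value, tolerance = 1e-6)
  }
})

test_that("the L2 objective is concave along rays from the optimum", {
  basis <- make_gamma_basis(3, 8)
  sm <- random_spikes(3, 300, p = 0.1, seed = 9)
  design <- build_design(sm, basis)
  y <- spikeconn:::response_vector(sm, design, 1)
  pen <- spikeconn:::penalty_mask(design)
  for (link in c("logistic", "cloglog")) {
    fit <- fit_glm(sm, 1, basis, eta = 0.3, link = link, design = design)
    beta <- fit$beta
    obj <- function(b) spikeconn:::cpp_loglik(design$X, y, b,
                                              spikeconn:::link_code(link)) -
      0.3 * 0.5 * sum(pen * b^2)
    set.seed(10)
    for (r in 1:5) {
      d <- rnorm(length(beta)); d <- d / sqrt(sum(d^2))
      vals <- vapply(c(0, 0.05, 0.1, 0.3), function(a) obj(beta + a * d), 0)
      expect_true(all(diff(vals) < 1e-10))
    }
  }
})

test_that("fitting recovers generating spike response functions", {
  net <- tiny_net(w = 2.5)
  sim <- simulate_network(net, 20000, seed = 11)
  basis <- make_gamma_basis(4, 16)
  fit <- fit_glm(sim$spikes, 2, basis, eta = 0.2)
  srf_hat <- reconstruct_srf(fit, basis, 1)
  srf_true <- 2.5 * net$kernel
  m <- min(length(srf_hat), length(srf_true))
  expect_gt(cor(srf_hat[1:m], srf_true[1:m]), 0.8)
})

test_that("srf reconstruction is the loadings-basis product and is linear", {
  basis <- make_gamma_basis(4, 12)
  A <- matrix(rnorm(8), 2, 4)
  f <- manual_fit(0, A)
  expect_equal(reconstruct_srf(f, basis, 1),
               as.numeric(A[1, ] %*% basis$values), tolerance = 1e-12)
  fz <- manual_fit(0, matrix(0, 2, 4))
  expect_equal(reconstruct_srf(fz, basis, 2), rep(0, 12))
  fu <- manual_fit(0, rbind(c(0, 0, 1, 0), 0))
  expect_equal(reconstruct_srf(fu, basis, 1), basis$values[3, ])
  # linearity
  B <- matrix(rnorm(8), 2, 4)
  fa <- manual_fit(0, 2 * A + 3 * B)
  expect_equal(reconstruct_srf(fa, basis, 1),
               2 * reconstruct_srf(manual_fit(0, A), basis, 1) +
                 3 * reconstruct_srf(manual_fit(0, B), basis, 1),
               tolerance = 1e-12)
  expect_error(reconstruct_srf(f, basis, 5), "valid")
})

test_that("constrained null fits never beat the unconstrained optimum", {
  basis <- make_gamma_basis(3, 8)
  sm <- random_spikes(4, 600, p = 0.08, seed = 12)
  design <- build_design(sm, basis)
  fit <- fit_glm(sm, 1, basis, eta = 0, design = design)
  lrs <- lr_statistics(fit, sm, basis, design = design)
  expect_true(all(lrs$loglik_null <= fit$loglik + 1e-8))
  expect_true(all(lrs$lr >= 0))
})
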