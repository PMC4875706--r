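test_that("the 15-neuron benchmark network has the prescribed wiring", {
  net <- build_experiment1_network(seed = 3, calibrate = FALSE)
  A <- net$adjacency
  expect_equal(sum(A != 0), 30)
  expect_equal(sum(A > 0), 20)
  expect_equal(sum(A < 0), 10)
  g <- net$groups
  for (idx in which(A != 0)) {
    src <- (idx - 1) %% 15 + 1
    dst <- (idx - 1) %/% 15 + 1
    expect_false(g[src] == g[dst])
    if (A[idx] < 0) {
      expect_identical(g[src], "G3"); expect_identical(g[dst], "G1")
    } else {
      expect_true((g[src] == "G1" && g[dst] == "G2") ||
                    (g[src] == "G2" && g[dst] == "G3"))
    }
  }
  expect_true(all(diag(A) == 0))
  expect_true(all(net$private_rates >= 50 & net$private_rates <= 150))
})

test_that("the 3-neuron benchmark sets peaks equal to the weights", {
  n0 <- build_experiment4_network(A = 2, w = 0)
  expect_equal(sum(n0$adjacency != 0), 1)
  n1 <- build_experiment4_network(A = 2, w = 1)
  expect_equal(sum(n1$adjacency != 0), 2)
  expect_equal(max(n1$adjacency[2, 1] * n1$kernel), 1.0, tolerance = 1e-12)
  w <- 0.37
  nw <- build_experiment4_network(A = 2, w = w)
  expect_equal(max(abs(nw$adjacency[2, 3] * nw$kernel)), w, tolerance = 1e-12)
  expect_equal(nw$baselines, rep(2, 3))
  expect_error(build_experiment4_network(2, -1), "w")
})

test_that("simulation is seeded, binary, and matches the link at zero weights", {
  spec <- network_spec(3, matrix(0, 3, 3), baselines = rep(-4, 3),
                       link = "cloglog", sample_rate = 200)
  T <- 40000
  sim <- simulate_network(spec, T, seed = 5)
  expect_true(all(sim$spikes$counts %in% c(0L, 1L)))
  p <- link_prob(-4, "cloglog")
  for (i in 1:3) {
    phat <- mean(sim$spikes$counts[i, ])
    se <- sqrt(p * (1 - p) / T)
    expect_lt(abs(phat - p), 3 * se)
  }
  sim2 <- simulate_network(spec, T, seed = 5)
  expect_identical(sim2$spikes$counts, sim$spikes$counts)
  expect_false(identical(simulate_network(spec, T, seed = 6)$spikes$counts,
                         sim$spikes$counts))
  expect_identical(sim$truth, spec$adjacency != 0)
})

test_that("raising baselines raises firing, and saturation warns", {
  lo <- network_spec(2, matrix(0, 2, 2), baselines = rep(-5, 2))
  hi <- network_spec(2, matrix(0, 2, 2), baselines = rep(-4, 2))
  r_lo <- sum(simulate_network(lo, 20000, seed = 1)$spikes$counts)
  r_hi <- sum(simulate_network(hi, 20000, seed = 1)$spikes$counts)
  expect_gt(r_hi, r_lo)
  sat <- network_spec(2, matrix(0, 2, 2), baselines = rep(1, 2))
  expect_warning(simulate_network(sat, 500, seed = 1), "assumption")
})

test_that("path categories match a brute-force path enumeration", {
  # oracle: exhaustive depth-first enumeration of simple paths whose
  # intermediate nodes are all unobserved; returns the minimal edge count
  oracle <- function(edges, observed, src, dst) {
    if (edges[src, dst]) return("1")
    C <- nrow(edges)
    unobs <- setdiff(seq_len(C), observed)
    best <- Inf
    dfs <- function(node, used, depth) {
      for (nx in which(edges[node, ])) {
        if (nx == dst) { best <<- min(best, depth + 1); next }
        if (nx %in% used || !(nx %in% unobs)) next
        if (depth + 1 < best) dfs(nx, c(used, nx), depth + 1)
      }
    }
    dfs(src, src, 0)
    if (!is.finite(best)) "0" else if (best == 2) "2" else "3+"
  }
  set.seed(9)
  for (rep in 1:5) {
    C <- 8
    edges <- matrix(runif(C * C) < 0.2, C, C)
    diag(edges) <- FALSE
    observed <- sort(sample.int(C, 4))
    cats <- path_categories(edges, observed)
    for (r in seq_len(nrow(cats)))
      expect_identical(cats$category[r],
                       oracle(edges, observed, cats$source[r], cats$dest[r]),
                       info = sprintf("rep %d pair %d->%d", rep,
                                      cats$source[r], cats$dest[r]))
  }
  # with all neurons observed, no connected pair can be indirect
  full <- path_categories(matrix(c(FALSE, TRUE, FALSE, FALSE), 2), 1:2)
  expect_true(all(full$category %in% c("0", "1")))
})

test_that("the partial-observation scenario labels direct pairs correctly", {
  sc <- build_experiment3_scenario(seed = 2)
  expect_length(sc$observed, 8)
  A <- sc$spec$adjacency != 0
  for (r in seq_len(nrow(sc$categories))) {
    src <- sc$categories$source[r]; dst <- sc$categories$dest[r]
    if (A[src, dst]) expect_identical(sc$categories$category[r], "1")
  }
  expect_false(is.null(sc$spec$shared))
  expect_true(all(sc$spec$shared_coef > 0))
})
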