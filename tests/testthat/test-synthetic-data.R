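test_that("lattice graphs have the expected rook structure", {
  g <- make_lattice_graph(2, 2)
  expect_identical(lengths(g$neighbors), rep(2L, 4))
  g1 <- make_lattice_graph(1, 1)
  expect_identical(g1$islands, 1L)
  g3 <- make_lattice_graph(3, 3)
  expect_identical(length(g3$neighbors[[5]]), 4L)         # centre
  expect_identical(lengths(g3$neighbors)[c(1, 3, 7, 9)], rep(2L, 4))  # corners
  expect_error(make_lattice_graph(0, 3), "positive")
})

test_that("the 19-state contiguity graph is symmetric, connected, and anchored", {
  g <- make_srs_graph()
  expect_identical(g$n, 19L)
  expect_identical(g$n_components, 1L)
  expect_length(g$islands, 0L)
  nm <- attr(g, "area_names")
  expect_setequal(nm[g$neighbors[[which(nm == "Kerala")]]],
                  c("Tamil Nadu", "Karnataka"))
})

test_that("simulation is deterministic under a fixed seed", {
  g <- make_lattice_graph(3, 3)
  s1 <- simulate_panel(g, T = 4, seed = 99,
                       covariate_spec = list(list(name = "x1", cor_s = 0.5)))
  s2 <- simulate_panel(g, T = 4, seed = 99,
                       covariate_spec = list(list(name = "x1", cor_s = 0.5)))
  expect_identical(s1$panel$O, s2$panel$O)
  expect_identical(s1$truth$s, s2$truth$s)
  expect_identical(s1$panel$X, s2$panel$X)
})

test_that("generated ICAR effects are centred and spatially correlated", {
  g <- make_lattice_graph(6, 6)
  set.seed(4)
  # pairs at graph distance 1 vs 3 (BFS on the lattice)
  dist_from <- function(start) {
    d <- rep(NA_integer_, g$n); d[start] <- 0L; q <- start
    while (length(q)) {
      i <- q[[1L]]; q <- q[-1L]
      for (j in g$neighbors[[i]]) if (is.na(d[j])) { d[j] <- d[i] + 1L; q <- c(q, j) }
    }
    d
  }
  D <- vapply(seq_len(g$n), dist_from, integer(g$n))
  p1 <- which(D == 1L, arr.ind = TRUE); p1 <- p1[p1[, 1L] < p1[, 2L], ]
  p3 <- which(D == 3L, arr.ind = TRUE); p3 <- p3[p3[, 1L] < p3[, 2L], ]
  c1 <- c3 <- 0
  for (r in 1:100) {
    s <- ricar(g, tau = 1)
    expect_lt(abs(sum(s)), 1e-10)
    c1 <- c1 + mean(s[p1[, 1L]] * s[p1[, 2L]])
    c3 <- c3 + mean(s[p3[, 1L]] * s[p3[, 2L]])
  }
  expect_gt(c1, c3)   # correlation decays with graph distance
})

test_that("null-effect panels reproduce the expected-count scale", {
  # all effects zero, E = 100, 1000 areas x 5 periods: grand mean near 100
  g <- make_lattice_graph(50, 20)
  zero <- list(alpha = 0, gamma = 0, s = numeric(1000), u = numeric(1000),
               delta = numeric(1000))
  sim <- simulate_panel(g, truth = zero, T = 5,
                        expected = matrix(100, 1000, 5), seed = 3)
  expect_true(mean(sim$panel$O) >= 97 && mean(sim$panel$O) <= 103)
})

test_that("a pure common trend reproduces the implied count ratio", {
  g <- make_lattice_graph(20, 20)
  zero <- list(alpha = 0, gamma = -0.121, s = numeric(400), u = numeric(400),
               delta = numeric(400))
  sim <- simulate_panel(g, truth = zero, T = 5,
                        expected = matrix(100, 400, 5), seed = 5)
  ratio <- mean(sim$panel$O[, 5]) / mean(sim$panel$O[, 1])
  expect_lt(abs(ratio - exp(-0.121 * 4)), 0.02)   # centered coding: t5 - t1 = 4
})

test_that("replicate-averaged counts converge to E * rho", {
  g <- make_lattice_graph(3, 3)
  tr <- sim_truth(g, alpha = 2, gamma = -0.1, tau_s = 10, tau_u = 100,
                  tau_delta = 10, s = rep(0, 9), u = rep(0, 9),
                  delta = rep(c(-0.05, 0, 0.05), 3))
  tvec <- encode_time(4, "centered")
  mu <- exp(linear_predictor(tr$alpha, tr$s, tr$u, numeric(0), NULL,
                             tr$gamma, tr$delta, tvec)) * 50
  acc <- matrix(0, 9, 4)
  for (r in 1:400) {
    sim <- simulate_panel(g, truth = tr, T = 4,
                          expected = matrix(50, 9, 4), seed = 1000 + r)
    acc <- acc + sim$panel$O
  }
  expect_lt(max(abs(acc / 400 - mu) / mu), 0.05)
})

test_that("degenerate simulation inputs are rejected", {
  g <- make_lattice_graph(2, 2)
  expect_error(simulate_panel(g, T = 2, expected = matrix(0, 4, 2), seed = 1),
               "positive")
  expect_error(simulate_panel(g, T = 2, seed = "a"), "seed")
})
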