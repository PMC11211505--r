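test_that("identical seeds give bitwise-identical draws", {
  g <- make_lattice_graph(3, 3)
  sim <- simulate_panel(g, truth = list(alpha = 3), T = 4, seed = 1)
  f1 <- stmmr(sim$panel, g, model = 1, iters = 400, burnin = 200, thin = 2,
              chains = 2, seed = 123)
  f2 <- stmmr(sim$panel, g, model = 1, iters = 400, burnin = 200, thin = 2,
              chains = 2, seed = 123)
  expect_identical(f1$draws$alpha, f2$draws$alpha)
  expect_identical(f1$draws$s, f2$draws$s)
  expect_identical(f1$draws$tau_delta, f2$draws$tau_delta)
})

test_that("intercept-only posterior mean tracks the log mean count", {
  g <- make_lattice_graph(10, 10)
  zero <- list(alpha = 3, gamma = 0, s = numeric(100), u = numeric(100),
               delta = numeric(100))
  sim <- simulate_panel(g, truth = zero, T = 5, seed = 2)
  spec <- model_spec(1, include_spatial = FALSE, include_iid = FALSE,
                     include_trend = FALSE, include_interaction = FALSE)
  fit <- stmmr(sim$panel, g, model = spec, iters = 1500, burnin = 500,
               thin = 1, chains = 1, seed = 3)
  expect_lt(abs(mean(fit$draws$alpha) - log(mean(sim$panel$O))), 0.03)
})

test_that("stored spatial and interaction effects are centred each draw", {
  g <- make_srs_graph()
  sim <- simulate_panel(g, truth = list(alpha = 2.5), T = 5, seed = 4)
  fit <- stmmr(sim$panel, g, model = 1, iters = 600, burnin = 300, thin = 1,
               chains = 1, seed = 5)
  expect_lt(max(abs(rowSums(fit$draws$s))), 1e-8)
  expect_lt(max(abs(rowSums(fit$draws$delta))), 1e-8)
})

test_that("posterior summaries have correct moments, quantiles and rr column", {
  d <- make_draws(s = matrix(2.5, 200, 2), alpha = rep(1.3, 200))
  sm <- summarize_draws(d)
  a <- sm[sm$parameter == "alpha", ]
  expect_equal(a$mean, 1.3)
  expect_equal(a$q2.5, 1.3)
  expect_equal(a$q97.5, 1.3)
  expect_equal(a$rr, exp(1.3))
  expect_true(all(sm$q2.5 <= sm$q97.5))
  # standard-normal draws: empirical 2.5% quantile near -1.96
  set.seed(9)
  d2 <- make_draws(s = matrix(0, 1e5, 1), alpha = rnorm(1e5))
  sm2 <- summarize_draws(d2)
  expect_lt(abs(sm2$mean[sm2$parameter == "alpha"]), 0.02)
  expect_lt(abs(sm2$q2.5[sm2$parameter == "alpha"] + 1.959964), 0.02)
  # rr is exp(mean), never mean(exp(draws))
  expect_equal(sm2$rr[sm2$parameter == "alpha"],
               exp(sm2$mean[sm2$parameter == "alpha"]))
  # chain order does not matter
  perm <- sample(1e5)
  d3 <- make_draws(s = d2$s[perm, , drop = FALSE], alpha = d2$alpha[perm])
  expect_equal(summarize_draws(d3)$mean, sm2$mean)
  expect_error(summarize_draws(make_draws(s = matrix(0, 50, 1))), "at least 100")
})

test_that("relative-risk transform is the exponential on the printed scale", {
  expect_equal(rr_transform(0), 1)
  expect_equal(signif(rr_transform(-0.720), 6), 0.486752)
  expect_equal(rr_transform(0.4939), 1.638695, tolerance = 1e-6)
  expect_error(rr_transform(NaN), "finite")
})

test_that("DIC satisfies its algebraic identities", {
  g <- make_lattice_graph(2, 2)
  p <- areal_panel(matrix(c(3L, 5L, 4L, 6L, 2L, 7L, 5L, 5L), 4, 2),
                   paste0("a", 1:4), 1:2)
  # point-mass draws: pD = 0 and DIC = D(theta_bar)
  d <- make_draws(s = matrix(0.1 * rep(c(1, -1, 1, -1), each = 150), 150, 4),
                  alpha = rep(1.4, 150))
  st <- compute_dic(d, panel = p)
  expect_equal(st$p_d, 0, tolerance = 1e-9)
  expect_equal(st$dic, st$d_at_mean, tolerance = 1e-9)
  expect_equal(st$dic, st$dbar + st$p_d, tolerance = 1e-9)
  # spread draws: dic = 2*dbar - d_at_mean, p_d > 0 for jittered parameters
  set.seed(10)
  d2 <- make_draws(s = matrix(rnorm(600, 0, 0.1), 150, 4),
                   alpha = rnorm(150, 1.4, 0.1))
  st2 <- compute_dic(d2, panel = p)
  expect_equal(st2$dic, 2 * st2$dbar - st2$d_at_mean, tolerance = 1e-9)
  expect_gt(st2$p_d, 0)
})

test_that("prior-only sampling recovers the precision hyperprior moments", {
  g <- make_lattice_graph(3, 3)
  p <- areal_panel(matrix(1L, 9, 3), paste0("a", 1:9), 1:3)
  spec <- model_spec(1, hyper = hyperparams(a_u = 4, b_u = 2))
  d <- run_mcmc(p, g, spec, iters = 6000, burnin = 500, thin = 1, chains = 1,
                seed = 11, prior_only = TRUE)
  # Gamma(4, 2): mean 2, sd 1
  expect_lt(abs(mean(d$tau_u) - 2), 3 * sd(d$tau_u) / sqrt(200))
  expect_equal(sd(d$tau_u), 1, tolerance = 0.15)
})

test_that("fitted, residuals and simulate are mutually consistent", {
  g <- make_lattice_graph(3, 3)
  sim <- simulate_panel(g, truth = list(alpha = 3), T = 4, seed = 12)
  fit <- stmmr(sim$panel, g, model = 1, iters = 600, burnin = 300, thin = 1,
               chains = 1, seed = 13)
  mu <- fitted(fit)
  expect_identical(dim(mu), dim(sim$panel$O))
  expect_true(all(mu > 0))
  expect_equal(residuals(fit, "response"), sim$panel$O - mu, tolerance = 1e-12)
  reps <- simulate(fit, nsim = 3, seed = 14)
  expect_length(reps, 3)
  expect_identical(dim(reps[[1]]), dim(sim$panel$O))
  expect_true(all(reps[[1]] >= 0))
})
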