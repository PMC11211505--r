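test_that("time scores follow the requested coding", {
  expect_equal(encode_time(5, "centered"), c(-2, -1, 0, 1, 2))
  expect_equal(encode_time(5, "raw"), 1:5)
  for (T in c(1, 2, 7, 12)) expect_equal(sum(encode_time(T, "centered")), 0)
})

test_that("the linear predictor is the additive decomposition of log risk", {
  z5 <- numeric(5)
  eta0 <- linear_predictor(0, z5, z5, numeric(0), NULL, 0, z5, encode_time(3, "centered"))
  expect_true(all(eta0 == 0))
  eta_a <- linear_predictor(2.345, z5, z5, numeric(0), NULL, 0, z5,
                            encode_time(3, "centered"))
  expect_true(all(eta_a == 2.345))
  # additivity over disjoint parameter blocks
  set.seed(2)
  s <- rnorm(5); u <- rnorm(5); d <- rnorm(5); X <- matrix(rnorm(10), 5, 2)
  tv <- encode_time(4, "centered")
  e1 <- linear_predictor(1.1, s, numeric(5), numeric(0), NULL, 0, numeric(5), tv)
  e2 <- linear_predictor(0, numeric(5), u, c(0.3, -0.2), X, -0.1, d, tv)
  eb <- linear_predictor(1.1, s, u, c(0.3, -0.2), X, -0.1, d, tv)
  expect_equal(e1 + e2, eb, tolerance = 1e-12)
  expect_error(linear_predictor(0, s, u[1:3], numeric(0), NULL, 0, d, tv), "length")
})

test_that("the Poisson log-likelihood matches direct evaluation and dpois", {
  one <- matrix(1, 1, 1); zero <- matrix(0, 1, 1)
  expect_equal(as.numeric(poisson_loglik(zero, one, zero)), -1)
  expect_equal(as.numeric(poisson_loglik(one, one, zero)), -1)
  expect_equal(as.numeric(poisson_loglik(matrix(2, 1, 1), one, matrix(log(3), 1, 1))),
               2 * log(3) - 3 - log(2))
  set.seed(14)
  for (r in 1:5) {
    O <- matrix(rpois(12, 9), 3, 4)
    E <- matrix(runif(12, 0.5, 2), 3, 4)
    eta <- matrix(rnorm(12, 0, 0.5), 3, 4)
    expect_equal(as.numeric(poisson_loglik(O, E, eta)),
                 naive_poisson_loglik(O, E, eta), tolerance = 1e-10)
  }
  expect_warning(poisson_loglik(one, one, matrix(800, 1, 1)), "clipped")
})

test_that("design matrices follow the model's covariate sets", {
  g <- make_srs_graph()
  set.seed(6)
  X <- matrix(rnorm(19 * 17), 19, 17,
              dimnames = list(NULL, c(stmmr:::MATERNAL_COVARIATES,
                                      stmmr:::SYSTEM_COVARIATES)))
  p <- areal_panel(matrix(5L, 19, 2), paste0("a", 1:19), 1:2, X = X)
  d1 <- build_design(p, model_spec(1))
  expect_identical(ncol(d1$X), 0L)
  d2 <- build_design(p, model_spec(2))
  expect_identical(d2$names, c("anemia", "low_bmi", "low_birth_interval",
                               "contraception", "c_section", "birth_order_gt3"))
  expect_identical(ncol(d2$X), 6L)
  d3 <- build_design(p, model_spec(3))
  expect_identical(ncol(d3$X), 11L)
  expect_lt(max(abs(colMeans(d2$X))), 1e-12)
  expect_lt(max(abs(apply(d2$X, 2, sd) - 1)), 1e-12)
  expect_error(build_design(p, model_spec("custom", covariate_names = "nope")),
               "nope")
})
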