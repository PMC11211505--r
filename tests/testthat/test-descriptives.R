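test_that("per-area trend fits handle exact, degenerate and noisy series", {
  t <- 1:5
  f <- fit_area_trend(2 * t + 1, t)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$slope_se, 0)
  expect_equal(c(f$slope_lo, f$slope_hi), c(2, 2))
  expect_equal(f$r2, 1)
  fc <- fit_area_trend(rep(4, 5), t)
  expect_equal(fc$slope, 0)
  expect_equal(fc$r2, 0)
  expect_error(fit_area_trend(3, 1), "at least 2")
  expect_error(fit_area_trend(c(1, 2), c(2, 2)), "zero variance")
  # against the normal-equations oracle
  set.seed(19)
  for (r in 1:10) {
    y <- rnorm(7, 10 - 0.5 * (1:7), 2)
    f <- fit_area_trend(y, 1:7)
    o <- naive_ols(y, 1:7)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$slope_se, o$se, tolerance = 1e-10)
    expect_equal(f$slope_lo, o$lo, tolerance = 1e-10)
    expect_equal(f$slope_hi, o$hi, tolerance = 1e-10)
  }
})

test_that("trend fits are equivariant under response scaling", {
  set.seed(20)
  y <- rnorm(6, 50, 5)
  f1 <- fit_area_trend(y, 1:6)
  f3 <- fit_area_trend(3 * y, 1:6)
  expect_equal(f3$slope, 3 * f1$slope, tolerance = 1e-10)
  expect_equal(f3$slope_lo, 3 * f1$slope_lo, tolerance = 1e-10)
  expect_equal(f3$slope_hi, 3 * f1$slope_hi, tolerance = 1e-10)
})

test_that("panels with a negative common trend yield mostly negative slopes", {
  g <- make_srs_graph()
  neg <- 0
  for (r in 1:20) {
    sim <- simulate_panel(g, truth = list(alpha = 4.6, gamma = -0.121,
                                          tau_s = 10, tau_u = 100,
                                          delta = numeric(19)),
                          T = 5, seed = 300 + r)
    tr <- area_trends(sim$panel)
    neg <- neg + (mean(tr$slope < 0) > 0.5)
  }
  expect_gte(neg, 18)
})

test_that("heatmap matrices are column-standardised in either orientation", {
  g <- make_srs_graph()
  sim <- simulate_panel(g, T = 5, seed = 23,
                        covariate_spec = list(list(name = "anc", cor_s = -0.4),
                                              list(name = "ghe")))
  hm <- heatmap_matrix(sim$panel, "by_column")
  expect_identical(dim(hm$matrix), c(19L, 5L))
  expect_lt(max(abs(colMeans(hm$matrix))), 1e-12)
  expect_lt(max(abs(apply(hm$matrix, 2, sd) - 1)), 1e-12)
  # by_row equals by_column on the transpose
  hr <- heatmap_matrix(sim$panel, "by_row")
  tp <- areal_panel(t(sim$panel$O), sim$panel$time_ids, sim$panel$area_ids)
  expect_equal(unname(hr$matrix), unname(zscale_columns(t(sim$panel$O))))
  # covariate display: one MMR column plus K covariates
  hc <- heatmap_matrix(sim$panel, include_covariates = TRUE)
  expect_identical(ncol(hc$matrix), 1L + 2L)
  expect_identical(hc$col_labels[1], "mmr")
})
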