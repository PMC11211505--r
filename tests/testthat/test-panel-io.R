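test_that("counts CSV round-trips an areal panel cell-for-cell", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  p <- toy_panel()
  write_panel(p, tmp)
  p2 <- read_panel(tmp)
  expect_identical(p2$O, p$O)
  expect_equal(p2$P, p$P)
  expect_identical(p2$area_ids, c("A", "B"))
  expect_identical(unname(p2$O[, ]), matrix(c(10L, 20L, 12L, 18L), 2, 2))

  # a 19 x 5 generated panel (with covariates) survives the round trip
  g <- make_srs_graph()
  sim <- simulate_panel(g, T = 5, seed = 11,
                        covariate_spec = list(list(name = "anc", cor_s = -0.5),
                                              list(name = "jsy")))
  c1 <- withr::local_tempfile(fileext = ".csv")
  c2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(sim$panel, c1, c2)
  back <- read_panel(c1, c2)
  expect_identical(back$O, sim$panel$O)
  expect_equal(back$X, sim$panel$X, tolerance = 1e-12)
})

test_that("invalid counts files are rejected with informative errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("area_id,time_id,observed", "A,1,10", "A,2,12", "B,1,-5", "B,2,7"), tmp)
  expect_error(read_panel(tmp), "negative")
  writeLines(c("area_id,time_id,observed", "A,1,10", "B,2,7"), tmp)
  expect_error(read_panel(tmp), "missing \\(area, time\\)")
  writeLines(c("area_id,time_id,observed", "A,1,10.5", "A,2,12", "B,1,5", "B,2,7"), tmp)
  expect_error(read_panel(tmp), "integers")
  # covariates keyed by an unknown area
  cv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("area_id,time_id,observed", "A,1,10", "A,2,12", "B,1,5", "B,2,7"), tmp)
  writeLines(c("area_id,anc", "A,55", "Z,40"), cv)
  expect_error(read_panel(tmp, cv), "not in panel")
})

test_that("reports write with the documented schema and re-read losslessly", {
  d <- make_draws(s = matrix(rnorm(300), 100, 3),
                  delta = matrix(rnorm(300, sd = 0.1), 100, 3))
  rep_ <- risk_report(d)
  expect_identical(names(rep_), c("area_id", "spatial_rr", "exceed_prob",
                                  "label", "delta_mean", "delta_lo", "delta_hi"))
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, csv, "csv")
  write_report(rep_, jsn, "json")
  got <- read_report(csv)
  expect_identical(names(got), names(rep_))
  back <- read_report(jsn)
  expect_equal(back$spatial_rr, signif(rep_$spatial_rr, 6))
  expect_identical(back$label, rep_$label)
  # json written at 6 significant digits round-trips bit-stably
  write_report(back, jsn, "json")
  expect_equal(read_report(jsn), back)
  expect_error(write_report(rep_, csv, "xml"), "unknown report format")
})

test_that("graph files parse, round-trip, and reject malformed input", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3", "1 1 2", "2 2 1 3", "3 1 2"), tmp)
  g <- read_graph(tmp)
  expect_identical(g$neighbors, list(2L, c(1L, 3L), 2L))
  write_graph(g, tmp)
  expect_identical(read_graph(tmp)$neighbors, g$neighbors)

  writeLines(c("2", "1 1 2", "2 0"), tmp)
  expect_error(read_graph(tmp), "asymmetric")
  writeLines(c("2", "1 1 3", "2 0"), tmp)
  expect_error(read_graph(tmp), "out of range")
  writeLines(c("2", "1 2 2 2", "2 1 1"), tmp)
  expect_error(read_graph(tmp), "duplicate")
  # islands parse and are flagged
  writeLines(c("3", "1 1 2", "2 1 1", "3 0"), tmp)
  g <- read_graph(tmp)
  expect_identical(g$islands, 3L)
})

test_that("graph validation rejects asymmetric two-node counterexamples", {
  expect_error(adjacency_graph(list(2L, integer(0))), "asymmetric")
  expect_error(adjacency_graph(list(integer(0), 1L)), "asymmetric")
  expect_error(adjacency_graph(list(1L, 1L)), "self-loop")
})
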