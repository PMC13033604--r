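test_that("zero-process configuration yields a constant trajectory", {
  p <- transport_only_params()
  phys0 <- PHYS
  phys0$transport$extravasation_per_day <- 0
  phys0$transport$lymph_exit_per_day <- 0
  y0 <- state_template()
  y0[158] <- y0[160] <- 1e7
  tr <- simulate_protocol(p, "CONTROL", horizon = 5, phys = phys0, y0 = y0)
  expect_true(all(abs(t(tr$state) - y0) <= 1e-6 * (1 + y0)))
})

test_that("tumor-only configuration matches exponential growth to 0.1%", {
  ## no immune cells anywhere (and none born): pure intrinsic growth
  p <- default_parameters(baseline_total = c(DC = 0, M1 = 0, M2 = 0,
                                             TREG = 0, TE1 = 0, APC = 0))
  y0 <- state_template()
  y0[157] <- p$TN0
  y0[158] <- y0[160] <- p$Vi_tumor0 / p$v_cell
  tr <- simulate_protocol(p, "CONTROL", horizon = 24, y0 = y0)
  expected <- p$Vi_tumor0 * exp(p$lg_tumor * tr$times)
  for (tum in 1:2) {
    rel <- abs(output_series(tr, "volume", tum) - expected) / expected
    expect_lt(max(rel), 1e-3)
  }
})

test_that("a single 10 Gy event moves the exact LQ viable fraction", {
  p <- default_parameters()
  tr <- simulate_protocol(p, "T1_RT", horizon = 12)
  ev <- tr$events[[1]]
  ratio <- ev$state_post[[158]] / ev$state_pre[[158]]
  expect_equal(ratio, lq_survival(10, p$a_c, p$b_c), tolerance = 1e-8)
  ## mass balance across the event
  expect_equal(ev$state_post[[158]] + ev$state_post[[159]],
               ev$state_pre[[158]] + ev$state_pre[[159]])
})

test_that("trajectory grid and state invariants hold", {
  tr <- simulate_protocol(default_parameters(), "T1_RT_LN_RT")
  expect_true(all(diff(tr$times) > 0))
  expect_lte(max(diff(tr$times)), 0.25 + 1e-12)
  expect_true(all(tr$state >= 0))
  expect_equal(tr$volume[, 1],
               unname((tr$state[, 158] + tr$state[, 159]) * 1e-6))
  expect_error(simulate_protocol(default_parameters(), "T1_RT",
                                 horizon = 5), "horizon")
})

test_that("two stiff solvers at different tolerances agree within 0.5%", {
  p <- default_parameters()
  a <- simulate_protocol(p, "T1_RT_LN_RT", rtol = 1e-6, method = "bdf")
  b <- simulate_protocol(p, "T1_RT_LN_RT", rtol = 1e-8, method = "lsoda")
  for (tum in 1:2) {
    va <- output_series(a, "volume", tum)
    vb <- output_series(b, "volume", tum)
    expect_lt(max(abs(va - vb) / pmax(vb, 1e-3)), 0.005)
  }
})

test_that("compiled and reference integrations agree", {
  p <- default_parameters()
  a <- simulate_protocol(p, "T1_RT", horizon = 14)
  b <- simulate_protocol(p, "T1_RT", horizon = 14, compiled = FALSE)
  expect_lt(max(abs(a$volume - b$volume) / pmax(b$volume, 1)), 1e-4)
})

test_that("whole-body counts are conserved under pure transport", {
  p <- transport_only_params()
  y0 <- random_state(21, scale = 1e5)
  tr <- simulate_protocol(p, "CONTROL", horizon = 50, y0 = y0)
  for (s in seq_along(SPECIES_TRAFFICKING)) {
    idx <- (s - 1L) * 26L + 1:26
    totals <- rowSums(tr$state[, idx])
    expect_lt(max(abs(totals - totals[1])) / totals[1], 1e-6)
  }
})

test_that("halving the output spacing leaves post-event states unchanged", {
  p <- default_parameters()
  a <- simulate_protocol(p, "T1_RT", horizon = 14, dt = 0.25)
  b <- simulate_protocol(p, "T1_RT", horizon = 14, dt = 0.125)
  ia <- which(a$times %in% c(10.5, 12, 14))
  ib <- which(b$times %in% c(10.5, 12, 14))
  expect_equal(a$volume[ia, ], b$volume[ib, ], tolerance = 1e-4)
})

test_that("ensemble summaries are order statistics on the common grid", {
  p <- default_parameters()
  tr <- simulate_protocol(p, "CONTROL", horizon = 6)
  ## single trajectory: bands collapse onto the median
  s1 <- summarize_ensemble(list(tr))
  expect_equal(s1$median, unname(output_series(tr, "volume", 1)))
  expect_equal(s1$lower, s1$median)
  expect_equal(s1$upper, s1$median)
  ## symmetric matrix ensemble {f - c, f, f + c}: median = f
  f <- sin(seq(0, 3, length.out = 25)) + 2
  mat <- cbind(f - 0.5, f, f + 0.5)
  s2 <- summarize_ensemble(mat, quantiles = c(0.25, 0.75))
  expect_equal(s2$median, f)
  ## IQR quantiles honour the requested probabilities
  expect_equal(s2$lower, apply(mat, 1, quantile, 0.25))
  ## mismatched grids are rejected
  tr2 <- simulate_protocol(p, "CONTROL", horizon = 8)
  expect_error(summarize_ensemble(list(tr, tr2)), "common grid")
})

test_that("trajectories serialize as tidy CSV with a provenance sidecar", {
  tr <- simulate_protocol(default_parameters(), "T1_RT", horizon = 11)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  d <- utils::read.csv(f)
  expect_setequal(names(d), c("time", "species", "compartment",
                              "sub_compartment", "count"))
  expect_equal(nrow(d), length(tr$times) * 161L)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$group, "T1_RT")
  expect_equal(side$rtol, 1e-6)
  expect_length(side$events, 1L)
})
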