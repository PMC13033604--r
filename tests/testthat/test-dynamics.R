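test_that("tumor volume is linear in counts and split-invariant", {
  expect_equal(tumor_volume(0, 0, 1e-6), 0)
  expect_equal(tumor_volume(1e8, 0, 1e-6), 100)
  expect_equal(tumor_volume(5e7, 5e7, 1e-6), 100)
  expect_error(tumor_volume(-1, 0), "negative")
})

test_that("cytolysis follows mass action with saturating suppression", {
  expect_equal(cytolysis_rate(0, 1e6, 1e-6), 0)
  ## suppression off: exact closed form
  expect_equal(cytolysis_rate(2e5, 1e7, 3e-6), 3e-6 * 2e5 * 1e7)
  ## monotone decreasing in each suppressor
  r1 <- cytolysis_rate(2e5, 1e7, 3e-6, Treg_conc = 1e5, s_Treg = 1e-6)
  r2 <- cytolysis_rate(2e5, 1e7, 3e-6, Treg_conc = 2e5, s_Treg = 1e-6)
  expect_true(r2 < r1)
  expect_error(cytolysis_rate(-1, 1, 1), "negative")
})

test_that("phagocytosis converts phagocytes to APCs conservatively", {
  p <- default_parameters()
  none <- phagocytosis_rates(0, 0, 0, 1e7, 1e6, 0.1, p)
  expect_true(all(unlist(none) == 0))
  ## M1 constants off: no M1 conversion, debris removal is DC-only
  p0 <- default_parameters(Ac_M1 = 0, Ac_dead_M1 = 0)
  r <- phagocytosis_rates(1e4, 2e3, 5e4, 1e7, 1e6, 0.1, p0)
  expect_equal(r$M1_to_APC, 0)
  expect_equal(r$Td_removal, p0$Ac_dead_DC * (1e4 + 2e3) / 0.1 * 1e6)
  expect_error(phagocytosis_rates(1, 1, 1, 1, 1, 0, p), "volume")
  ## RHS-level conservation: conversion flux cancels in d(DC+APC)/dt
  y <- random_state(7)
  d <- assemble_rhs(0, y, transport_only_params(), PHYS)
  ## with all kinetics zero the conversion terms vanish identically
  expect_true(all(d[157:161] == 0))
})

test_that("lymph-node priming has the logistic fixed point", {
  p <- default_parameters()
  at_base <- ln_priming_rates(p$TN0, 0, p)
  expect_equal(unlist(at_base), c(TN_regen = 0, TN_activation = 0,
                                  TE1_production = 0))
  half <- ln_priming_rates(p$TN0 / 2, 0, p)
  expect_equal(half$TN_regen, p$k_prol_TN * p$TN0 / 4)
  ## N_exp = 1: effector production equals naive consumption
  p1 <- default_parameters(N_exp = 1)
  r <- ln_priming_rates(5e5, 1e4, p1, k_TN = 1e-6)
  expect_equal(r$TE1_production, r$TN_activation)
  expect_error(ln_priming_rates(1, 1, default_parameters(TN0 = 0)), "TN0")
})

test_that("debris clearance is first order", {
  expect_equal(debris_clearance(0, 0.3), 0)
  expect_equal(debris_clearance(1e6, 0.25), 2.5e5)
  expect_equal(debris_clearance(1e6, 0), 0)
})

test_that("RHS vanishes when every process is switched off", {
  p <- transport_only_params()
  phys0 <- PHYS
  phys0$transport$extravasation_per_day <- 0
  phys0$transport$lymph_exit_per_day <- 0
  ## zero flows are invalid physiology, so keep flows but empty the blood:
  ## an all-zero immune state with no births has zero derivative
  y <- state_template()
  y[157] <- 0; y[158] <- y[160] <- 1e7
  d <- assemble_rhs(0, y, p, phys0)
  expect_true(all(d == 0))
})

test_that("transport conserves each trafficking species at the RHS level", {
  y <- random_state(11)
  d <- assemble_rhs(0, y, transport_only_params(), PHYS)
  for (s in seq_along(SPECIES_TRAFFICKING)) {
    idx <- (s - 1L) * 26L + 1:26
    expect_lt(abs(sum(d[idx])) / max(abs(d[idx])), 1e-12)
  }
})

test_that("transport RHS is homogeneous of degree one in immune counts", {
  ## tumor cell pools set the (fixed) geometry; scaling the trafficking
  ## species must scale their derivatives linearly
  y <- random_state(13)
  p <- transport_only_params()
  y3 <- y
  y3[1:156] <- 3 * y3[1:156]
  d1 <- assemble_rhs(0, y, p, PHYS)
  d3 <- assemble_rhs(0, y3, p, PHYS)
  expect_lt(max(abs(d3[1:156] - 3 * d1[1:156])) / max(abs(d1)), 1e-12)
})

test_that("tumor-only configuration grows exponentially at the RHS level", {
  p <- default_parameters()
  y <- state_template()
  y[158] <- 2e7; y[160] <- 3e7
  d <- assemble_rhs(0, y, p, PHYS)
  expect_equal(d[[158]], p$lg_tumor * 2e7)
  expect_equal(d[[160]], p$lg_tumor * 3e7)
})

test_that("RHS rejects invalid states with the offending index", {
  y <- state_template()
  y[5] <- -1
  expect_error(assemble_rhs(0, y, default_parameters(), PHYS), "index 5")
  y[5] <- NaN
  expect_error(assemble_rhs(0, y, default_parameters(), PHYS), "index 5")
})

test_that("compiled and reference right-hand sides agree", {
  p <- default_parameters()
  for (seed in 1:5) {
    y <- random_state(seed)
    y[158:161] <- abs(y[158:161]) * 100   # sizeable tumors
    for (pair in c("control", "rt")) {
      dr <- assemble_rhs(0, y, p, PHYS, pair = pair)
      dc <- compiled_rhs(y, p, pair)
      expect_equal(unname(dr), dc, tolerance = 1e-12)
    }
  }
})

test_that("state indexing round-trips the documented layout", {
  nm <- abscopalQSP:::state_names()
  expect_length(nm, 161L)
  expect_false(any(duplicated(nm)))
  expect_equal(state_index("TN", "LYMPH_NODES"), 157L)
  expect_equal(state_index("TV", "TUMOR1"), 158L)
  expect_equal(state_index("DC", "LUNGS", "vascular"), 1L)
  expect_equal(nm[state_index("TE1", "TUMOR2", "interstitial")],
               "TE1.TUMOR2.interstitial")
  expect_error(state_index("TN", "LIVER"), "no state slot")
})

test_that("baseline equilibration is a steady state of the full RHS", {
  p <- default_parameters()
  y0 <- initial_state(p, PHYS)
  ## remove the tumors: residual of the trafficking subsystem must vanish.
  ## (venous blood is excluded: implanting the tumors re-routes their small
  ## arterial share, an imbalance of order Q_tumor/Q_total by design)
  y <- y0
  y[158:161] <- 0
  d <- assemble_rhs(0, y, p, PHYS)
  for (s in seq_along(SPECIES_TRAFFICKING)) {
    idx <- (s - 1L) * 26L + c(1:10, 13:22, 25)
    rel <- max(abs(d[idx])) / max(y[idx], 1)
    expect_lt(rel, 1e-8)
  }
  expect_equal(unname(y0[158]), p$Vi_tumor0 / p$v_cell)
})

test_that("the compiled analytic Jacobian matches finite differences", {
  p <- default_parameters()
  ctx <- abscopalQSP:::absq_context(p, PHYS, "rt")
  y <- random_state(17)
  y[158:161] <- abs(y[158:161]) * 100
  f <- function(v) deSolve::DLLfunc(y = v, dllname = "abscopalQSP",
                                    func = "absq_derivs",
                                    initfunc = "absq_init",
                                    parms = ctx$parms, times = 0)$dy
  f0 <- f(unname(y))                     # also sets the parameter block
  out <- .C("absq_jac", as.integer(161), as.double(0),
            as.double(unname(y)), integer(1), integer(1),
            pd = double(161 * 161), as.integer(161), double(1),
            integer(1), PACKAGE = "abscopalQSP")
  J <- matrix(out$pd, 161, 161)
  cols <- c(1, 10, 25, 26, 120, 131, 140, 156, 157, 158, 159, 160, 161)
  scale <- max(abs(J))
  for (j in cols) {
    h <- max(1e-6 * abs(y[j]), 1e-2)
    yp <- unname(y); yp[j] <- yp[j] + h
    fd <- (f(yp) - f0) / h
    expect_lt(max(abs(J[, j] - fd)) / (max(abs(fd)) + 1e-8 * scale), 1e-3)
  }
})
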