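test_that("LQ survival has the closed form and fraction additivity", {
  expect_equal(lq_survival(0, 0.3, 0.03), 1)
  expect_equal(lq_survival(10, 0.1, 0.01), exp(-2))
  ## purely linear kill: three 3 Gy fractions equal one 9 Gy fraction
  expect_equal(lq_survival(3, 0.2, 0)^3, lq_survival(9, 0.2, 0))
  ## with b > 0 fractionation spares: S(3)^3 > S(9)
  expect_gt(lq_survival(3, 0.2, 0.02)^3, lq_survival(9, 0.2, 0.02))
  expect_error(lq_survival(-1, 0.1, 0.01), "negative")
})

test_that("tumor events conserve TV + TD and move the LQ fraction", {
  p <- default_parameters()
  y <- random_state(3)
  ev <- radiation_event(10, 10, "TUMOR1")
  y2 <- apply_radiation_event(y, ev, p)
  expect_equal(y2[[158]] / y[[158]], lq_survival(10, p$a_c, p$b_c))
  expect_equal(y2[[158]] + y2[[159]], y[[158]] + y[[159]])
  ## everything outside TUMOR1's tumor pools untouched
  expect_identical(y2[-c(158, 159)], y[-c(158, 159)])
  ## zero dose is the exact identity
  expect_identical(apply_radiation_event(y, radiation_event(5, 0, "TUMOR1"),
                                         p), y)
  ## only tumor 1 is irradiable
  expect_error(radiation_event(10, 10, "TUMOR2"))
})

test_that("lymph-node events deplete only APC, TN and TE1 in the node", {
  p <- default_parameters()
  y <- random_state(4)
  ev <- radiation_event(10, 3, "LYMPH_NODES")
  y2 <- apply_radiation_event(y, ev, p)
  S <- lq_survival(3, p$a_IM, p$b_IM)
  hit <- c(state_index("TN", "LYMPH_NODES"),
           state_index("APC", "LYMPH_NODES", "interstitial"),
           state_index("APC", "LYMPH_NODES", "vascular"),
           state_index("TE1", "LYMPH_NODES", "interstitial"),
           state_index("TE1", "LYMPH_NODES", "vascular"))
  expect_equal(unname(y2[hit]), unname(S * y[hit]))
  expect_identical(y2[-hit], y[-hit])
  ## DC, M1, M2, Treg in the node are spared
  for (sp in c("DC", "M1", "M2", "TREG")) {
    i <- state_index(sp, "LYMPH_NODES", "interstitial")
    expect_identical(y2[[i]], y[[i]])
  }
})

test_that("same-day tumor and lymph-node events commute", {
  p <- default_parameters()
  y <- random_state(5)
  e1 <- radiation_event(10, 10, "TUMOR1")
  e2 <- radiation_event(10, 3, "LYMPH_NODES")
  a <- apply_radiation_event(apply_radiation_event(y, e1, p), e2, p)
  b <- apply_radiation_event(apply_radiation_event(y, e2, p), e1, p)
  expect_identical(a, b)
})

test_that("the three study protocols are built exactly", {
  expect_length(build_protocol("CONTROL")$events, 0L)
  t1 <- build_protocol("T1_RT")
  expect_length(t1$events, 1L)
  expect_equal(t1$events[[1]]$time, 10)
  expect_equal(t1$events[[1]]$dose_gy, 10)
  expect_equal(t1$events[[1]]$target, "TUMOR1")
  ln <- build_protocol("T1_RT_LN_RT")
  expect_length(ln$events, 4L)
  ln_ev <- Filter(function(e) e$target == "LYMPH_NODES", ln$events)
  expect_length(ln_ev, 3L)
  expect_equal(vapply(ln_ev, `[[`, 0, "time"), c(10, 13, 16))
  expect_true(all(vapply(ln_ev, `[[`, 0, "dose_gy") == 3))
  expect_error(build_protocol("T2_RT"))
})

test_that("protocols round-trip through JSON and YAML", {
  pr <- build_protocol("T1_RT_LN_RT")
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    write_protocol(pr, f)
    back <- read_protocol(f)
    expect_equal(back$group, pr$group)
    expect_equal(length(back$events), length(pr$events))
    expect_equal(vapply(back$events, `[[`, 0, "dose_gy"),
                 vapply(pr$events, `[[`, 0, "dose_gy"))
  }
})
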