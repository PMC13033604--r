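test_that("central differences are exact on linear data", {
  g <- central_difference_growth(c(0, 1, 2), c(1, 2, 4))
  expect_equal(g, c(1, 1.5, 2))
  expect_equal(central_difference_growth(c(0, 2, 5), c(3, 3, 3)),
               c(0, 0, 0))
  t <- c(0, 1, 3, 4, 7)
  expect_equal(central_difference_growth(t, 3 * t), rep(3, 5))
  expect_error(central_difference_growth(c(0, 1, 1), c(1, 2, 3)),
               "duplicate")
  ## invariant to constant offsets
  v <- c(2, 5, 9, 20)
  expect_equal(central_difference_growth(c(0, 2, 4, 6), v + 11),
               central_difference_growth(c(0, 2, 4, 6), v))
})

test_that("SSE is self-consistent at the generating parameters", {
  co <- noise_free_cohort()
  th <- log(params_to_fitted(default_parameters()))
  s0 <- sse_objective(th, co)
  ## zero up to interpolation/integration tolerance, on data of scale
  ## thousands of mm3 squared
  expect_lt(s0, 1)
  ## any perturbed parameter is worse (identifiability smoke test)
  nm <- fitted_parameter_names()
  for (k in seq_along(nm)) {
    for (f in c(log(10), log(0.1))) {
      thk <- th
      thk[k] <- thk[k] + f
      expect_gt(sse_objective(thk, co), s0)
    }
  }
})

test_that("constant volume offsets shift the SSE by m c^2 at the optimum", {
  co <- noise_free_cohort()
  th <- log(params_to_fitted(default_parameters()))
  s0 <- sse_objective(th, co)
  co2 <- co
  subj <- co2$subject == co2$subject[1] & co2$tumor == "T1"
  m <- sum(subj)
  co2$volume_mm3[subj] <- co2$volume_mm3[subj] + 50
  s1 <- sse_objective(th, co2, weight_growth = growth_weight(co))
  expect_equal(s1 - s0, m * 50^2, tolerance = 1e-2)
  ## w = 0 reduces the objective to the pure volume term
  sv <- sse_objective(th, co, weight_growth = 0)
  expect_lte(sv, s0)
})

test_that("adaptive log bounds bracket the population within 10%", {
  set.seed(1)
  pop <- matrix(rnorm(30, -10, 2), ncol = 3)
  b <- adaptive_log_bounds(pop)
  expect_true(all(b$lower <= apply(pop, 2, min)))
  expect_true(all(b$upper >= apply(pop, 2, max)))
  expect_true(all(b$lower >= apply(pop, 2, min) -
                    0.1 * abs(apply(pop, 2, min))))
  expect_true(all(b$upper <= apply(pop, 2, max) +
                    0.1 * abs(apply(pop, 2, max))))
  ## single member: bounds bracket that member
  one <- matrix(c(-5, -20), nrow = 1)
  b1 <- adaptive_log_bounds(one)
  expect_true(all(b1$lower <= one & one <= b1$upper))
  expect_true(all(b1$upper - b1$lower <= 0.2 * abs(one[1, ])))
  ## deterministic under a fixed RNG state
  set.seed(9); ba <- adaptive_log_bounds(pop)
  set.seed(9); bb <- adaptive_log_bounds(pop)
  expect_identical(ba, bb)
  expect_error(adaptive_log_bounds(matrix(numeric(0), 0, 3)), "empty")
})

test_that("the GA engine solves a convex log-space bowl to 1%", {
  truth <- c(0.8, -2.5)
  fn <- function(x) sum((x - truth)^2)
  set.seed(2)
  init <- matrix(rnorm(24, 0, 2), ncol = 2)
  res <- ga_minimize(fn, init, ga_config(pop_size = 30, generations = 80,
                                         stall_generations = 80), seed = 4)
  expect_lt(max(abs(res$par - truth)), 0.01 * max(abs(truth)))
  ## reproducibility
  res2 <- ga_minimize(fn, init, ga_config(pop_size = 30, generations = 80,
                                          stall_generations = 80), seed = 4)
  expect_identical(res$par, res2$par)
  expect_identical(res$value, res2$value)
})

test_that("elitism never loses a supplied optimum", {
  co <- noise_free_cohort()
  th <- log(params_to_fitted(default_parameters()))
  s_truth <- sse_objective(th, co)
  init <- rbind(th, th + 0.3, th - 0.2)
  colnames(init) <- fitted_parameter_names()
  fit <- fit_ga(co, init_population = init,
                config = ga_config(pop_size = 6L, generations = 2L,
                                   hybrid = FALSE),
                seed = 5)
  expect_lte(fit$sse, s_truth + 1e-9)
})

test_that("bootstrap replicates preserve per-(group, tumor) strata", {
  co <- noise_free_cohort(n = 2L)
  th <- log(params_to_fitted(default_parameters()))
  base <- structure(list(log_par = setNames(th, fitted_parameter_names()),
                         par = exp(th), sse = sse_objective(th, co)),
                    class = "absq_fit_ga")
  boot <- bootstrap_refit(co, B = 3L, base_fit = base, seed = 7,
                          config = ga_config(pop_size = 4L,
                                             generations = 1L,
                                             stall_generations = 1L,
                                             hybrid = FALSE))
  expect_equal(boot$B, 3L)
  curves <- split(co, list(co$subject, co$tumor), drop = TRUE)
  stratum <- vapply(curves, function(d) paste(d$group[1], d$tumor[1]), "")
  want <- table(stratum)
  for (idx in boot$resamples) {
    got <- table(stratum[idx])
    expect_equal(as.vector(got[names(want)]), as.vector(want))
  }
  expect_equal(dim(boot$par_matrix), c(3L, 16L))
  expect_length(bootstrap_baselines(boot), 3L)
  expect_error(bootstrap_refit(co, B = 0L, base_fit = base), "B must")
  ## the study default
  expect_equal(formals(bootstrap_refit)$B, 50L)
})
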