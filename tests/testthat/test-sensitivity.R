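test_that("OAT sweeps scale exactly one parameter", {
  p <- default_parameters()
  sw1 <- oat_sweep(p, "Ac_DC", multipliers = 1, protocol = "CONTROL",
                   horizon = 6)
  base <- simulate_protocol(p, "CONTROL", horizon = 6)
  expect_equal(sw1$trajectories[[1]]$volume, base$volume)
  expect_length(oat_sweep(p, "Ac_DC", protocol = "CONTROL",
                          horizon = 4)$trajectories, 6L)
  expect_error(oat_sweep(p, "not_a_param", protocol = "CONTROL"),
               "unknown parameter")
  ## structurally inert parameter under CONTROL: tumor radiosensitivity
  sw <- oat_sweep(p, "a_c", multipliers = c(10, 0.1), protocol = "CONTROL",
                  horizon = 6)
  expect_equal(sw$trajectories[[1]]$state, sw$trajectories[[2]]$state)
})

test_that("total variance matches the analytic value for constants", {
  times <- seq(0, 24, by = 0.25)
  mat <- cbind(rep(0, length(times)), rep(2, length(times)))
  expect_equal(total_variance(mat, times), 2)
  expect_equal(total_variance(cbind(times, times, times), times), 0)
  expect_error(total_variance(mat, times[-1]), "mismatched")
})

test_that("total variance matches an independent fine-grid quadrature", {
  set.seed(31)
  times <- seq(0, 24, by = 0.25)
  mat <- sapply(1:5, function(i) {
    a <- runif(1, 0.5, 2); b <- runif(1, 0, 3)
    a * sin(times / 3 + b) + times / (i + 2)
  })
  got <- total_variance(mat, times, T = 24)
  ## oracle: pracma trapezoid at the same nodes, independent code path
  vbar <- rowMeans(mat)
  oracle <- sum(apply(mat, 2, function(v) {
    pracma::trapz(times, (v - vbar)^2)
  })) / 24
  expect_equal(got, oracle, tolerance = 1e-12)
  ## the ensemble is known only at grid nodes: the 10x-resolution oracle
  ## integrates the interpolated squared-deviation integrand
  ft <- seq(0, 24, by = 0.025)
  fine <- sum(apply(mat, 2, function(v) {
    integrand <- (v - vbar)^2
    pracma::trapz(ft, stats::approx(times, integrand, xout = ft)$y)
  })) / 24
  expect_equal(got, fine, tolerance = 1e-8)
})

test_that("total variance scales quadratically with the output", {
  set.seed(5)
  times <- seq(0, 10, by = 0.5)
  mat <- matrix(rnorm(length(times) * 4, 10), ncol = 4)
  tv <- total_variance(mat, times)
  expect_gt(tv, 0)
  expect_equal(total_variance(3 * mat, times), 9 * tv)
})

test_that("TotVar aggregation applies the strict threshold and NaN rule", {
  rec <- data.frame(parameter = "p", output = "volume", tumor = 1,
                    group = "T1_RT", bootstrap = 1:3,
                    totvar = c(100, 5, 1000))
  agg <- aggregate_totvar(rec, threshold = 10)
  expect_equal(agg$mean_significant, 550)
  expect_equal(agg$log10_totvar, log10(550), tolerance = 1e-6)
  expect_equal(agg$n_significant, 2L)
  ## all below threshold: NaN
  rec$totvar <- c(1, 9, 10)               # 10 itself is excluded (strict)
  agg2 <- aggregate_totvar(rec, threshold = 10)
  expect_true(is.nan(agg2$log10_totvar))
  expect_equal(agg2$n_significant, 0L)
})

test_that("median/IQR bands are permutation-invariant order statistics", {
  times <- seq(0, 5, by = 0.25)
  f <- exp(times / 4)
  mat <- cbind(f, 2 * f, 3 * f)
  b <- median_iqr_bands(mat, times)
  expect_equal(b$median, 2 * f)
  perm <- mat[, c(3, 1, 2)]
  expect_equal(median_iqr_bands(perm, times), b)
  one <- median_iqr_bands(matrix(f, ncol = 1), times)
  expect_equal(one$lower, one$upper)
  expect_equal(one$median, f)
  expect_error(median_iqr_bands(list()), "empty")
})

test_that("the sweep grid feeds consistent TotVar records", {
  p <- default_parameters()
  grid <- run_oat_grid(list(p), param_ids = "k_rc1",
                       multipliers = c(2, 0.5),
                       groups = c("CONTROL", "T1_RT"), horizon = 24)
  rec <- sensitivity_records(grid)
  expect_setequal(names(rec), c("parameter", "output", "tumor", "group",
                                "bootstrap", "totvar"))
  expect_equal(nrow(rec), 1L * 2L * 2L * 2L)  # params x groups x out x tum
  expect_true(all(rec$totvar >= 0))
  ## reproducible from the stored series
  m <- grid$series[[1]][["k_rc1"]][["T1_RT"]][["volume1"]]
  expect_equal(rec$totvar[rec$group == "T1_RT" & rec$output == "volume" &
                          rec$tumor == 1],
               total_variance(m, grid$times))
})
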