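test_that("group differences are trapezoid time-averages", {
  times <- seq(0, 24, by = 0.25)
  f <- exp(times / 6)
  expect_equal(group_difference(f, f, times), 0)
  expect_equal(group_difference(f + 3, f, times), 3)
  expect_equal(group_difference(f, f + 3, times), -3)
  expect_error(group_difference(f, f[-1], times), "mismatched")
})

test_that("group differences match an independent quadrature oracle", {
  times <- seq(0, 24, by = 0.25)
  g1 <- 100 * exp(times / 5) / (1 + exp((times - 12) / 3))
  g2 <- 80 * exp(times / 6)
  got <- group_difference(g1, g2, times, T = 24)
  oracle <- pracma::trapz(times, g1 - g2) / 24
  expect_equal(got, oracle, tolerance = 1e-12)
  ## 10x-resolution oracle on the interpolated difference (the series are
  ## grid samples; trapezoid is exact for their linear interpolant)
  ft <- seq(0, 24, by = 0.025)
  fine <- pracma::trapz(ft, stats::approx(times, g1 - g2, xout = ft)$y) / 24
  expect_equal(got, fine, tolerance = 1e-8)
})

test_that("exact Spearman p equals 2/n! for perfect monotonicity", {
  lev <- c(10, 1.5, 1.1, 0.9, 0.5, 0.1)
  up <- spearman_exact(lev, order(lev))
  expect_equal(up$rho, 1)
  expect_equal(up$p, 2 / factorial(6))
  dn <- spearman_exact(lev, -order(lev))
  expect_equal(dn$rho, -1)
  expect_equal(dn$p, 2 / factorial(6))
  ## constant deltas are flagged undefined
  flat <- spearman_exact(lev, rep(1, 6))
  expect_false(flat$defined)
  expect_error(spearman_exact(1:2, 1:2))
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(8)
  lev <- c(10, 1.5, 1.1, 0.9, 0.5, 0.1)
  for (i in 1:5) {
    d <- rnorm(6)
    a <- spearman_exact(lev, d)
    b <- spearman_exact(log(lev), exp(d))       # log levels, exp deltas
    expect_equal(a$rho, b$rho)
    expect_equal(a$p, b$p)
  }
})

test_that("the enumerated null matches a from-scratch recomputation", {
  ## independent path: insertion-generated permutations + cor() on ranks
  for (n in 4:6) {
    P <- perms_by_insertion(n)
    rho_all <- apply(P, 1, function(ry) cor(rank(1:n), rank(ry)))
    for (seed in 1:3) {
      set.seed(seed)
      d <- rnorm(n)
      got <- spearman_exact(1:n, d)
      rho_obs <- cor(1:n, d, method = "spearman")
      expect_equal(got$rho, rho_obs)
      expect_equal(got$p, mean(abs(rho_all) >= abs(rho_obs) - 1e-12))
    }
  }
})

test_that("the stability filter demands sign consistency and 70% support", {
  expect_equal(stability_filter(rep(0.9, 10), rep(0.01, 10)), 0.9)
  ## one sign flip: rejected
  expect_true(is.nan(stability_filter(c(rep(0.9, 9), -0.1),
                                      rep(0.01, 10))))
  ## 60% significant at 70% threshold: rejected
  expect_true(is.nan(stability_filter(rep(0.8, 10),
                                      c(rep(0.01, 6), rep(0.2, 4)))))
  ## 70% exactly: accepted
  expect_equal(stability_filter(rep(0.8, 10),
                                c(rep(0.01, 7), rep(0.2, 3))), 0.8)
  ## raising the threshold can only turn values into NaN
  rhos <- rep(0.7, 10); ps <- c(rep(0.01, 8), 0.3, 0.3)
  lo <- stability_filter(rhos, ps, frac_threshold = 0.7)
  hi <- stability_filter(rhos, ps, frac_threshold = 0.9)
  expect_false(is.nan(lo))
  expect_true(is.nan(hi))
  expect_error(stability_filter(numeric(0), numeric(0)), "empty")
})

## a synthetic sweep grid with a known monotone structure
fake_grid <- function(B = 3, eps = 0) {
  times <- seq(0, 24, by = 0.25)
  mult <- c(10, 1.5, 1.1, 0.9, 0.5, 0.1)
  series <- lapply(seq_len(B), function(b) {
    list(p1 = lapply(stats::setNames(nm = c("CONTROL", "T1_RT")),
                     function(g) {
      off <- if (g == "CONTROL") 100 else 0
      mats <- lapply(stats::setNames(nm = c("volume1", "volume2", "cd81",
                                            "cd82", "apc1", "apc2")),
                     function(k) {
        sapply(mult, function(m) {
          off + m * 10 + eps * b + 0 * times
        })
      })
      mats
    }))
  })
  structure(list(series = series, times = times, multipliers = mult,
                 param_ids = "p1", groups = c("CONTROL", "T1_RT"), B = B,
                 horizon = 24), class = "absq_oat_grid")
}

test_that("the correlation table reports stable cells with direction", {
  g <- fake_grid()
  ## difference CONTROL - T1_RT is constant (+100) across levels: no-effect
  tab <- correlation_table(g, group_pairs = rbind(c("CONTROL", "T1_RT")))
  expect_true(all(tab$flag == "no-effect"))
  expect_true(all(is.nan(tab$rho)))
  expect_true(all(tab$delta_sign == 1))
})

test_that("swapping the group pair flips both signs", {
  times <- seq(0, 24, by = 0.25)
  g <- fake_grid()
  ## make the difference level-dependent: scale T1_RT by the multiplier
  for (b in 1:g$B) {
    for (k in names(g$series[[b]]$p1$T1_RT)) {
      g$series[[b]]$p1$T1_RT[[k]] <-
        g$series[[b]]$p1$T1_RT[[k]] * rep(2, length(times))
    }
  }
  ab <- correlation_table(g, group_pairs = rbind(c("CONTROL", "T1_RT")))
  ba <- correlation_table(g, group_pairs = rbind(c("T1_RT", "CONTROL")))
  ok <- ab$flag == "ok"
  expect_true(any(ok))
  expect_equal(ba$rho[ok], -ab$rho[ok])
  expect_equal(ba$delta_sign[ok], -ab$delta_sign[ok])
})
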