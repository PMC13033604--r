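## Inter-group difference analysis: time-averaged differences under OAT
## sweeps, exact small-sample Spearman correlation against sweep level, and
## the sign-consistency + significance-fraction stability filter.

#' Time-averaged difference between two output series
#'
#' \code{(1/T) integral_0^T (V_g1(t) - V_g2(t)) dt} by the trapezoid rule
#' on the common grid; antisymmetric in the two groups.
#'
#' @param series_g1,series_g2 Output series on the same grid.
#' @param times Grid times (days).
#' @param T Upper integration limit (default grid end).
#' @return Scalar time-averaged difference (output units).
#' @export
group_difference <- function(series_g1, series_g2, times, T = NULL) {
  if (length(series_g1) != length(series_g2) ||
      length(series_g1) != length(times)) {
    stop("mismatched grids")
  }
  if (is.null(T)) T <- max(times)
  keep <- times <= T + 1e-12
  trapezoid(times[keep], (series_g1 - series_g2)[keep]) / T
}

## all permutations of 1..n (n! rows); small n only, memoised (n = 8 is
## 40320 rows and is enumerated once per session)
permutations_of <- function(n) {
  key <- paste0("perm", n)
  if (!is.null(.absq_cache[[key]])) return(.absq_cache[[key]])
  out <- if (n == 1L) matrix(1L, 1, 1) else {
    sub <- permutations_of(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      rest <- seq_len(n)[-k]
      cbind(k, matrix(rest[sub], nrow(sub)))
    }))
  }
  .absq_cache[[key]] <- out
  out
}

spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Average ranks on ties; for n <= 8 the two-sided p-value is computed by
#' full enumeration of the n! permutations of one rank vector
#' (\code{P(|rho_perm| >= |rho_obs|)}); for larger n the standard
#' t-approximation of \code{cor.test} is used.  Constant inputs have no
#' defined rank correlation and are flagged.
#'
#' @param levels Sweep levels (e.g. multipliers).
#' @param deltas Corresponding time-averaged differences.
#' @return List with \code{rho}, \code{p} and \code{defined} (FALSE when
#'   either vector is constant, in which case rho and p are NA and the cell
#'   is excluded downstream).
#' @export
spearman_exact <- function(levels, deltas) {
  n <- length(levels)
  stopifnot(length(deltas) == n, n >= 3L)
  rho <- spearman_rho(levels, deltas)
  if (is.na(rho)) {
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE))
  }
  if (n <= 8L) {
    rx <- rank(levels); ry <- rank(deltas)
    perms <- permutations_of(n)
    ## rho for every permutation of the delta ranks against fixed levels
    rxc <- rx - mean(rx)
    ryp <- matrix(ry[perms], nrow(perms))
    rypc <- ryp - mean(ry)
    num <- as.vector(rypc %*% rxc)
    den <- sqrt(sum(rxc^2)) * sqrt(rowSums(rypc^2))
    rho_null <- num / den
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    p <- suppressWarnings(
      stats::cor.test(levels, deltas, method = "spearman",
                      exact = FALSE)$p.value)
  }
  list(rho = rho, p = p, defined = TRUE)
}

#' Stability filter over bootstrap replicates
#'
#' A (parameter, output, group-pair) cell is reported only when every
#' per-bootstrap rank correlation shares one sign and the fraction of
#' replicates significant at \code{alpha} is at least
#' \code{frac_threshold}; the reported value is then the mean rho over all
#' replicates, otherwise NaN.
#'
#' @param rhos,pvals Equal-length per-bootstrap vectors.
#' @param frac_threshold Required significant fraction (default 0.70).
#' @param alpha Significance level (default 0.05).
#' @return Mean rho, or NaN when the filter fails.
#' @export
stability_filter <- function(rhos, pvals, frac_threshold = 0.70,
                             alpha = 0.05) {
  if (length(rhos) == 0L || length(rhos) != length(pvals)) {
    stop("empty or mismatched rho/p vectors")
  }
  stopifnot(frac_threshold > 0, frac_threshold <= 1)
  if (any(is.na(rhos)) || any(is.na(pvals))) return(NaN)
  if (!(all(rhos > 0) || all(rhos < 0))) return(NaN)
  if (mean(pvals < alpha) < frac_threshold) return(NaN)
  mean(rhos)
}

#' Default group pairs of the correlation analysis
#' @return Two-column matrix of (g1, g2) labels.
#' @export
default_group_pairs <- function() {
  rbind(c("CONTROL", "T1_RT"),
        c("CONTROL", "T1_RT_LN_RT"),
        c("T1_RT", "T1_RT_LN_RT"))
}

#' Stable Spearman correlation table of inter-group differences
#'
#' For every (parameter, output, tumor, group pair) cell: per bootstrap
#' baseline, the time-averaged inter-group difference is computed at each
#' sweep level, correlated against the multiplier levels by
#' \code{\link{spearman_exact}}, then filtered by
#' \code{\link{stability_filter}}.  Cells whose differences are numerically
#' constant across levels (< 1e-12 spread) are flagged "no-effect" and
#' reported NaN.  The direction indicator is the sign of the mean
#' difference across levels and bootstraps (+1: higher in the first group).
#'
#' @param grid An \code{absq_oat_grid} covering both groups of every pair.
#' @param group_pairs Two-column matrix of group labels.
#' @param outputs Output labels (default APC, CD8+ and tumor volume).
#' @param T Integration window end.
#' @param frac_threshold,alpha Stability-filter settings.
#' @return Data frame: parameter, output, tumor, g1, g2, \code{delta_sign}
#'   (+1/-1), \code{rho} (stable mean rho or NaN), \code{n_significant},
#'   \code{flag} ("ok", "no-effect", or "filtered").
#' @export
correlation_table <- function(grid, group_pairs = default_group_pairs(),
                              outputs = c("apc", "cd8", "volume"),
                              T = NULL, frac_threshold = 0.70,
                              alpha = 0.05) {
  rows <- list()
  for (pr in seq_len(nrow(group_pairs))) {
    g1 <- group_pairs[pr, 1]; g2 <- group_pairs[pr, 2]
    stopifnot(g1 %in% grid$groups, g2 %in% grid$groups)
    for (pid in grid$param_ids) {
      for (out in outputs) {
        for (tum in 1:2) {
          key <- paste0(out, tum)
          rhos <- pvals <- numeric(grid$B)
          all_deltas <- c()
          defined <- TRUE
          for (b in seq_len(grid$B)) {
            m1 <- grid$series[[b]][[pid]][[g1]][[key]]
            m2 <- grid$series[[b]][[pid]][[g2]][[key]]
            deltas <- vapply(seq_along(grid$multipliers), function(i) {
              group_difference(m1[, i], m2[, i], grid$times, T)
            }, 0)
            all_deltas <- c(all_deltas, deltas)
            if (diff(range(deltas)) < 1e-12) {
              defined <- FALSE
              rhos[b] <- pvals[b] <- NA_real_
            } else {
              sp <- spearman_exact(grid$multipliers, deltas)
              defined <- defined && sp$defined
              rhos[b] <- sp$rho; pvals[b] <- sp$p
            }
          }
          rho <- if (defined) {
            stability_filter(rhos, pvals, frac_threshold, alpha)
          } else NaN
          flag <- if (!defined) "no-effect"
                  else if (is.nan(rho)) "filtered" else "ok"
          rows[[length(rows) + 1L]] <- data.frame(
            parameter = pid, output = out, tumor = tum, g1 = g1, g2 = g2,
            delta_sign = sign(mean(all_deltas)), rho = rho,
            n_significant = sum(pvals < alpha, na.rm = TRUE), flag = flag)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
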