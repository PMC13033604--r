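## One-at-a-time parameter sweeps, median/IQR bands, and the time-integrated
## total-variance statistic aggregated into heatmap tables.

#' Default one-at-a-time sweep multipliers
#' @return The six multipliers spanning two orders of magnitude around the
#'   baseline.
#' @export
default_multipliers <- function() c(10, 1.5, 1.1, 0.9, 0.5, 0.1)

## sweepable parameter labels: the 14 model symbols; the paired symbols
## scale both their control and RT values so one label serves every group
sweep_parameter_names <- function() c(FITTED_SHARED, FITTED_PAIRED)

scale_parameter <- function(params, param_id, m) {
  if (param_id %in% names(params)) {
    params[[param_id]] <- params[[param_id]] * m
  } else if (param_id %in% fitted_parameter_names()) {
    th <- params_to_fitted(params)
    th[param_id] <- th[param_id] * m
    params <- fitted_to_params(th, params)
  } else {
    stop("unknown parameter id: ", param_id)
  }
  validate_parameters(params)
  params
}

#' One-at-a-time parameter sweep
#'
#' Simulates the given protocol once per multiplier with only the selected
#' parameter scaled; every other entry of the baseline is untouched.  The
#' paired symbols (\code{k_TN}, \code{k_rc1}) scale both arm values; the
#' suffixed names (\code{k_TN_rt}, ...) scale one.
#'
#' @param baseline An \code{absq_params} baseline (e.g. a bootstrap
#'   optimum).
#' @param param_id One of the 14 model symbols or 16 suffixed fitted names.
#' @param multipliers Positive multipliers (default
#'   \code{\link{default_multipliers}}).
#' @param protocol Protocol or group label.
#' @param horizon,phys,... Passed to \code{\link{simulate_protocol}}.
#' @return List of class \code{absq_sweep}: \code{trajectories} (one per
#'   multiplier), \code{multipliers}, \code{param_id}, \code{group}.
#' @export
oat_sweep <- function(baseline, param_id,
                      multipliers = default_multipliers(),
                      protocol = "CONTROL", horizon = 24,
                      phys = default_phys(), ...) {
  stopifnot(all(multipliers > 0))
  if (is.character(protocol)) protocol <- build_protocol(protocol)
  trajectories <- lapply(multipliers, function(m) {
    simulate_protocol(scale_parameter(baseline, param_id, m), protocol,
                      horizon = horizon, phys = phys, ...)
  })
  structure(list(trajectories = trajectories, multipliers = multipliers,
                 param_id = param_id, group = protocol$group),
            class = "absq_sweep")
}

## internal trapezoid rule (tests cross-check against an independent
## quadrature oracle)
trapezoid <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Time-integrated total variance of a sweep ensemble
#'
#' \code{TotVar = sum_i (1/T) integral_0^T (V_i(t) - Vbar(t))^2 dt}, where
#' \code{Vbar(t)} is the pointwise mean over the sweep members and the
#' integral is the trapezoid rule on the output grid restricted to
#' \code{[0, T]}.  Units are squared output units.
#'
#' @param series Numeric matrix, time points x sweep members (>= 2
#'   columns), or an \code{absq_sweep} (with \code{output}/\code{tumor}).
#' @param times Grid times (days) matching the rows.
#' @param T Upper integration limit (default: end of grid).
#' @param output,tumor Output extraction when \code{series} is a sweep.
#' @return Scalar TotVar >= 0.
#' @export
total_variance <- function(series, times = NULL, T = NULL,
                           output = "volume", tumor = 1) {
  if (inherits(series, "absq_sweep")) {
    times <- series$trajectories[[1]]$times
    series <- vapply(series$trajectories, output_series,
                     numeric(length(times)), output = output, tumor = tumor)
  }
  stopifnot(is.matrix(series), ncol(series) >= 2L)
  if (is.null(times)) stop("grid times required")
  if (length(times) != nrow(series)) stop("mismatched grids")
  if (is.null(T)) T <- max(times)
  keep <- times <= T + 1e-12
  times <- times[keep]
  series <- series[keep, , drop = FALSE]
  vbar <- rowMeans(series)
  sum(apply(series, 2, function(v) trapezoid(times, (v - vbar)^2))) / T
}

#' Aggregate per-bootstrap total variances into a heatmap table
#'
#' Within each (parameter, output, tumor, group) cell, only per-bootstrap
#' TotVar values strictly exceeding the significance threshold are
#' retained; the cell value is the base-10 logarithm of the mean of the
#' retained values, or NaN when no replicate exceeded the threshold.
#'
#' @param records Data frame with columns \code{parameter}, \code{output},
#'   \code{tumor}, \code{group}, \code{bootstrap}, \code{totvar}.
#' @param threshold Significance threshold (strict inequality; default 10).
#' @return Data frame with one row per cell: \code{mean_significant},
#'   \code{log10_totvar} (NaN when never significant) and
#'   \code{n_significant}.
#' @export
aggregate_totvar <- function(records, threshold = 10) {
  stopifnot(threshold > 0)
  cells <- split(records, list(records$parameter, records$output,
                               records$tumor, records$group), drop = TRUE)
  out <- lapply(cells, function(d) {
    keep <- d$totvar > threshold
    m <- if (any(keep)) mean(d$totvar[keep]) else NaN
    data.frame(parameter = d$parameter[1], output = d$output[1],
               tumor = d$tumor[1], group = d$group[1],
               mean_significant = m, log10_totvar = log10(m),
               n_significant = sum(keep))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pointwise median and interquartile bands of a pooled ensemble
#'
#' @param series Matrix (time x members, pooled over bootstrap optima and
#'   multipliers) or list of \code{absq_trajectory}.
#' @param times Grid (when a matrix is given).
#' @param output,tumor Output extraction for trajectory lists.
#' @return Data frame \code{time}, \code{median}, \code{lower},
#'   \code{upper} (25th/75th percentiles).
#' @export
median_iqr_bands <- function(series, times = NULL, output = "volume",
                             tumor = 1) {
  if (is.list(series) && !is.data.frame(series)) {
    if (length(series) == 0L) stop("empty ensemble")
    res <- summarize_ensemble(series, quantiles = c(0.25, 0.75),
                              output = output, tumor = tumor)
    return(res)
  }
  stopifnot(is.matrix(series))
  if (is.null(times)) times <- seq_len(nrow(series)) - 1
  data.frame(time = times,
             median = apply(series, 1, stats::median),
             lower = apply(series, 1, stats::quantile, probs = 0.25),
             upper = apply(series, 1, stats::quantile, probs = 0.75),
             row.names = NULL)
}

#' Run the full one-at-a-time sweep grid
#'
#' For every bootstrap baseline, swept parameter and treatment group, runs
#' the multiplier sweep and stores the compact per-output series (tumor
#' volume, intratumoral CD8+ effector count, intratumoral APC count; both
#' tumors).  The result feeds both \code{\link{sensitivity_records}} and
#' \code{\link{correlation_table}} without re-simulating.
#'
#' @param baselines List of \code{absq_params} (bootstrap optima), or a
#'   single parameter set.
#' @param param_ids Swept parameter labels (default: all 14 model symbols).
#' @param multipliers Sweep multipliers.
#' @param groups Treatment groups.
#' @param horizon,phys Engine settings.
#' @return Nested list of class \code{absq_oat_grid}:
#'   \code{series[[b]][[param]][[group]]} is a list of time x multiplier
#'   matrices per output label, plus \code{times}, \code{multipliers},
#'   metadata.
#' @export
run_oat_grid <- function(baselines, param_ids = sweep_parameter_names(),
                         multipliers = default_multipliers(),
                         groups = treatment_groups(), horizon = 24,
                         phys = default_phys()) {
  if (inherits(baselines, "absq_params")) baselines <- list(baselines)
  outputs <- expand.grid(output = c("volume", "cd8", "apc"), tumor = 1:2,
                         stringsAsFactors = FALSE)
  times <- NULL
  series <- lapply(seq_along(baselines), function(b) {
    per_param <- lapply(param_ids, function(pid) {
      per_group <- lapply(groups, function(g) {
        sw <- oat_sweep(baselines[[b]], pid, multipliers, g,
                        horizon = horizon, phys = phys)
        if (is.null(times)) times <<- sw$trajectories[[1]]$times
        mats <- lapply(seq_len(nrow(outputs)), function(i) {
          vapply(sw$trajectories, output_series,
                 numeric(length(sw$trajectories[[1]]$times)),
                 output = outputs$output[i], tumor = outputs$tumor[i])
        })
        names(mats) <- paste0(outputs$output, outputs$tumor)
        mats
      })
      names(per_group) <- groups
      per_group
    })
    names(per_param) <- param_ids
    per_param
  })
  structure(list(series = series, times = times, multipliers = multipliers,
                 param_ids = param_ids, groups = groups,
                 B = length(baselines), horizon = horizon),
            class = "absq_oat_grid")
}

#' Per-bootstrap TotVar records from a sweep grid
#'
#' @param grid An \code{absq_oat_grid}.
#' @param outputs Output labels to score (default volume and CD8+).
#' @param T Integration window end (default the grid horizon).
#' @return Long data frame of TotVar records, ready for
#'   \code{\link{aggregate_totvar}}.
#' @export
sensitivity_records <- function(grid, outputs = c("volume", "cd8"),
                                T = NULL) {
  rows <- list()
  for (b in seq_len(grid$B)) {
    for (pid in grid$param_ids) {
      for (g in grid$groups) {
        mats <- grid$series[[b]][[pid]][[g]]
        for (out in outputs) {
          for (tum in 1:2) {
            tv <- total_variance(mats[[paste0(out, tum)]], grid$times, T)
            rows[[length(rows) + 1L]] <- data.frame(
              parameter = pid, output = out, tumor = tum, group = g,
              bootstrap = b, totvar = tv)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a heatmap table as CSV
#'
#' @param table Aggregated table from \code{\link{aggregate_totvar}} or
#'   \code{\link{correlation_table}}.
#' @param path Output CSV path.
#' @export
write_heatmap_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
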