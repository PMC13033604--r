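## Model-fitting front end: classed fit object with the usual accessor
## methods over the GA calibration engine.

#' Calibrate the abscopal model to a tumor-growth cohort
#'
#' High-level fitting interface: builds an initial log-space population
#' around \code{base_params}, minimises the SSE objective with the genetic
#' algorithm, and returns a classed fit with \code{print}, \code{summary},
#' \code{coef}, \code{predict}, \code{residuals}, \code{plot} and
#' \code{simulate} methods.
#'
#' @param data Long-format cohort (columns subject, group, tumor, day,
#'   volume_mm3), e.g. from \code{\link{generate_cohort}} or
#'   \code{\link{read_cohort}}.
#' @param base_params Centre of the initial population and source of the
#'   non-fitted constants.
#' @param config An \code{\link{ga_config}}.
#' @param seed Integer seed.
#' @param spread Initial-population half-width in log10 decades.
#' @param weight_growth Growth-observable weight (NULL for the
#'   variance-normalised default).
#' @param phys Physiology table.
#' @return An object of class \code{absq_fit}.
#' @export
fit_abscopal <- function(data, base_params = default_parameters(),
                         config = ga_config(), seed = 1L, spread = 0.7,
                         weight_growth = NULL,
                         phys = default_phys()) {
  init <- init_population_around(base_params, n = config$pop_size,
                                 spread = spread, seed = seed)
  fit <- fit_ga(data, init_population = init, config = config, seed = seed,
                weight_growth = weight_growth, base_params = base_params,
                phys = phys)
  structure(list(fit = fit, params = fitted_to_params(fit$par, base_params),
                 data = data, base_params = base_params, phys = phys,
                 config = config, seed = seed,
                 call = match.call()),
            class = "absq_fit")
}

#' @export
coef.absq_fit <- function(object, ...) object$fit$par

#' @export
print.absq_fit <- function(x, ...) {
  cat("Abscopal PBPK-QSP model fit\n")
  cat(sprintf("  %d curves, groups: %s\n",
              length(unique(paste(x$data$subject, x$data$tumor))),
              paste(unique(x$data$group), collapse = ", ")))
  cat(sprintf("  SSE = %.6g (%d GA generations, seed %d)\n",
              x$fit$sse, x$fit$generations_run, x$seed))
  cat("  fitted parameters:\n")
  print(signif(coef(x), 3))
  invisible(x)
}

#' @export
summary.absq_fit <- function(object, ...) {
  pred <- predict(object)
  res <- pred$volume_mm3 - object$data$volume_mm3
  out <- list(coef = coef(object), sse = object$fit$sse,
              rmse = sqrt(mean(res^2)), n_obs = nrow(object$data),
              groups = table(object$data$group),
              history = object$fit$history)
  class(out) <- "summary.absq_fit"
  out
}

#' @export
print.summary.absq_fit <- function(x, ...) {
  cat("Abscopal model fit summary\n")
  cat(sprintf("  n = %d observations, SSE = %.6g, volume RMSE = %.4g mm3\n",
              x$n_obs, x$sse, x$rmse))
  cat("  fitted parameters:\n")
  print(signif(x$coef, 3))
  invisible(x)
}

#' Model predictions at the cohort's measurement days
#'
#' @param object An \code{absq_fit}.
#' @param newdata Data frame with columns group, tumor, day (defaults to
#'   the fitting data).
#' @param ... Unused.
#' @return \code{newdata} with a \code{volume_mm3} column of predictions.
#' @export
predict.absq_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- object$data
  }
  newdata <- as.data.frame(newdata)
  newdata$volume_mm3 <- NA_real_
  for (g in unique(newdata$group)) {
    tr <- simulate_protocol(object$params, g,
                            horizon = max(newdata$day[newdata$group == g],
                                          24),
                            phys = object$phys)
    for (tum in 1:2) {
      sel <- newdata$group == g &
        (newdata$tumor %in% c(paste0("T", tum), tum))
      if (!any(sel)) next
      newdata$volume_mm3[sel] <- stats::approx(
        tr$times, output_series(tr, "volume", tum),
        xout = newdata$day[sel])$y
    }
  }
  newdata
}

#' @export
residuals.absq_fit <- function(object, ...) {
  predict(object)$volume_mm3 - object$data$volume_mm3
}

#' @export
plot.absq_fit <- function(x, output = "volume", ...) {
  groups <- unique(x$data$group)
  oldpar <- graphics::par(mfrow = c(1, length(groups)))
  on.exit(graphics::par(oldpar))
  for (g in groups) {
    tr <- simulate_protocol(x$params, g, phys = x$phys)
    d <- x$data[x$data$group == g, ]
    plot(d$day, d$volume_mm3,
         col = ifelse(d$tumor %in% c("T1", 1), "firebrick", "steelblue"),
         pch = 1, xlab = "day", ylab = "tumor volume (mm3)", main = g, ...)
    graphics::lines(tr$times, output_series(tr, "volume", 1),
                    col = "firebrick")
    graphics::lines(tr$times, output_series(tr, "volume", 2),
                    col = "steelblue")
  }
  invisible(x)
}

#' Simulate new cohorts from a fitted model
#'
#' @param object An \code{absq_fit}.
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param config Cohort configuration template; its true parameters are
#'   replaced by the fitted ones.
#' @param ... Unused.
#' @return A list of cohort data frames (length \code{nsim}), or a single
#'   data frame when \code{nsim = 1}.
#' @export
simulate.absq_fit <- function(object, nsim = 1, seed = 1L,
                              config = cohort_config(), ...) {
  config$true_params <- object$params
  out <- lapply(seq_len(nsim), function(i) {
    generate_cohort(config, seed = seed + i - 1L)
  })
  if (nsim == 1) out[[1]] else out
}
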