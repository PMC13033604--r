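## Synthetic bilateral-flank cohort generator: the statistical stand-in for
## the digitized mouse tumor-growth curves used for calibration.

#' Cohort generation settings
#'
#' Defaults emulate the bilateral-flank melanoma experiment the model is
#' calibrated against: three treatment arms, n = 8 mice per arm, two tumors
#' per mouse, measurements every ~3 days out to day 24 plus the treatment
#' day, multiplicative lognormal measurement noise on volumes, and
#' lognormal inter-mouse variability in growth rate and implant size.
#'
#' @param groups Treatment arms to include.
#' @param n_per_group Mice per arm.
#' @param days Measurement days.
#' @param sigma_noise Lognormal sdlog of the multiplicative volume
#'   measurement noise (default 0.20).
#' @param sigma_growth,sigma_v0 Lognormal sdlog of the per-mouse
#'   perturbation of \code{lg_tumor} and \code{Vi_tumor0} (default 0.15).
#' @param true_params Generating parameter set.
#' @param horizon Simulation horizon (days).
#' @return List of class \code{absq_cohort_config}.
#' @export
cohort_config <- function(groups = treatment_groups(), n_per_group = 8L,
                          days = sort(unique(c(seq(0, 24, by = 3), 10))),
                          sigma_noise = 0.20, sigma_growth = 0.15,
                          sigma_v0 = 0.15,
                          true_params = default_parameters(),
                          horizon = 24) {
  stopifnot(n_per_group >= 1L, sigma_noise >= 0, sigma_growth >= 0,
            sigma_v0 >= 0, max(days) <= horizon)
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 days = days, sigma_noise = sigma_noise,
                 sigma_growth = sigma_growth, sigma_v0 = sigma_v0,
                 true_params = true_params, horizon = horizon),
            class = "absq_cohort_config")
}

#' Generate a synthetic tumor-growth cohort
#'
#' Per mouse: draw subject-level lognormal perturbations of the intrinsic
#' growth rate and implant volume, simulate both tumors under the mouse's
#' group protocol, sample the volume curves at the measurement days, and
#' apply multiplicative lognormal measurement noise.  Deterministic for a
#' fixed seed.  The generating truth (parameters and per-subject draws) is
#' attached as the \code{"truth"} attribute and travels with
#' \code{\link{write_cohort}} as a JSON sidecar.
#'
#' @param config An \code{\link{cohort_config}}.
#' @param seed Integer seed.
#' @param phys Physiology table.
#' @return Long-format data frame (subject, group, tumor, day, volume_mm3)
#'   of class \code{absq_cohort} with a \code{truth} attribute.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            phys = default_phys()) {
  set.seed(seed)
  rows <- list()
  draws <- list()
  for (g in config$groups) {
    protocol <- build_protocol(g)
    for (m in seq_len(config$n_per_group)) {
      subject <- sprintf("%s_m%02d", g, m)
      f_lg <- stats::rlnorm(1, 0, config$sigma_growth)
      f_v0 <- stats::rlnorm(1, 0, config$sigma_v0)
      p_m <- config$true_params
      p_m$lg_tumor <- p_m$lg_tumor * f_lg
      p_m$Vi_tumor0 <- p_m$Vi_tumor0 * f_v0
      tr <- tryCatch(
        simulate_protocol(p_m, protocol, horizon = config$horizon,
                          phys = phys),
        error = function(e) {
          stop("simulation failed for subject ", subject,
               " (lg x", signif(f_lg, 4), ", V0 x", signif(f_v0, 4), "): ",
               conditionMessage(e))
        })
      draws[[subject]] <- list(lg_factor = f_lg, v0_factor = f_v0)
      for (tum in 1:2) {
        v <- stats::approx(tr$times, output_series(tr, "volume", tum),
                           xout = config$days)$y
        noise <- stats::rlnorm(length(v), 0, config$sigma_noise)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subject, group = g, tumor = paste0("T", tum),
          day = config$days, volume_mm3 = v * noise)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    seed = seed,
    true_parameters = as.list(params_to_fitted(config$true_params)),
    sigma_noise = config$sigma_noise, sigma_growth = config$sigma_growth,
    sigma_v0 = config$sigma_v0, subject_draws = draws)
  class(out) <- c("absq_cohort", "data.frame")
  out
}

#' Write / read a cohort as long-format CSV with a truth sidecar
#'
#' @param cohort A cohort data frame.
#' @param path CSV path; any truth attribute is written to
#'   \code{<path>.json}.
#' @return \code{read_cohort} returns the cohort (with truth re-attached
#'   when the sidecar exists); \code{write_cohort} returns \code{path}
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, c("subject", "group", "tumor",
                                             "day", "volume_mm3")],
                   path, row.names = FALSE)
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject", "group", "tumor", "day", "volume_mm3")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("cohort file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(d), required)
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
    d <- d[required]
  }
  bad <- which(!is.finite(d$volume_mm3) | d$volume_mm3 <= 0)
  if (length(bad)) {
    stop("non-positive or malformed volume at line ", bad[1] + 1L,
         " of ", path)
  }
  for (key in split(seq_len(nrow(d)), list(d$subject, d$tumor),
                    drop = TRUE)) {
    if (any(diff(d$day[key]) <= 0)) {
      stop("non-increasing days for subject ", d$subject[key[1]],
           " tumor ", d$tumor[key[1]], " near line ",
           key[which(diff(d$day[key]) <= 0)[1] + 1L] + 1L)
    }
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(d, "truth") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  class(d) <- c("absq_cohort", "data.frame")
  d
}
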