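## Orchestration: one configuration object, staged execution, and a
## reproducibility manifest.  Each stage is also available directly through
## its exported function (generate_cohort, fit_abscopal, run_oat_grid, ...).

#' Experiment configuration
#'
#' Collects every knob of the full workflow.  A single global seed fans out
#' to per-stage seeds by fixed offsets (stage index x 101), so any stage
#' can be reproduced in isolation.
#'
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param seed Global integer seed.
#' @param horizon Simulation horizon (days).
#' @param cohort A \code{\link{cohort_config}}.
#' @param ga A \code{\link{ga_config}} for the base fit.
#' @param ga_boot GA configuration for bootstrap refits.
#' @param bootstrap_B Bootstrap replicates.
#' @param multipliers Sweep multipliers.
#' @param totvar_threshold Significance threshold for
#'   \code{\link{aggregate_totvar}}.
#' @param frac_threshold Stability-filter fraction.
#' @param sweep_params Parameter labels to sweep.
#' @param params Baseline parameter set.
#' @param phys Physiology table.
#' @return List of class \code{absq_experiment_config}.
#' @export
experiment_config <- function(out_dir = "absq_out", seed = 1L, horizon = 24,
                              cohort = cohort_config(),
                              ga = ga_config(),
                              ga_boot = ga_config(pop_size = 16L,
                                                  generations = 10L),
                              bootstrap_B = 50L,
                              multipliers = default_multipliers(),
                              totvar_threshold = 10,
                              frac_threshold = 0.70,
                              sweep_params = sweep_parameter_names(),
                              params = default_parameters(),
                              phys = default_phys()) {
  structure(as.list(environment()), class = "absq_experiment_config")
}

stage_seed <- function(config, stage_index) {
  (config$seed %% 1000000L) + 101L * stage_index
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (simulate, generate_data,
#' calibrate, sweep, totvar, correlate), writing each stage's artifact
#' (CSV/JSON) into the configured output directory and recording a
#' manifest with seeds, configuration hash and file checksums.  Stages
#' consume the artifacts of earlier stages from the same run.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param stages Character subset of
#'   \code{c("simulate","generate_data","calibrate","sweep","totvar",
#'   "correlate")}; \code{"all"} for the full workflow (without the plain
#'   simulate stage).
#' @return The manifest (list), invisibly; also written as
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(config = experiment_config(),
                         stages = "all") {
  all_stages <- c("generate_data", "calibrate", "sweep", "totvar",
                  "correlate")
  if (identical(stages, "all")) stages <- all_stages
  known <- c("simulate", all_stages)
  if (length(setdiff(stages, known))) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   config_hash = params_hash(config$params),
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list(), artifacts = list())
  art <- function(name, path, seed = NA) {
    manifest$artifacts[[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)), seed = seed)
  }
  state <- new.env(parent = emptyenv())

  for (st in stages) {
    manifest$stages[[length(manifest$stages) + 1L]] <- st
    switch(st,
      simulate = {
        for (g in treatment_groups()) {
          tr <- simulate_protocol(config$params, g,
                                  horizon = config$horizon,
                                  phys = config$phys)
          f <- file.path(config$out_dir,
                         paste0("trajectory_", tolower(g), ".csv"))
          write_trajectory(tr, f)
          art(paste0("trajectory_", g), f)
        }
      },
      generate_data = {
        s <- stage_seed(config, 1L)
        cohort <- generate_cohort(config$cohort, seed = s,
                                  phys = config$phys)
        f <- file.path(config$out_dir, "cohort.csv")
        write_cohort(cohort, f)
        state$cohort <- cohort
        art("cohort", f, s)
      },
      calibrate = {
        s <- stage_seed(config, 2L)
        if (is.null(state$cohort)) {
          state$cohort <- read_cohort(file.path(config$out_dir,
                                                "cohort.csv"))
        }
        fit <- fit_abscopal(state$cohort, base_params = config$params,
                            config = config$ga, seed = s,
                            phys = config$phys)
        boot <- bootstrap_refit(state$cohort, B = config$bootstrap_B,
                                base_fit = fit, seed = s,
                                config = config$ga_boot,
                                base_params = config$params,
                                phys = config$phys)
        state$fit <- fit; state$boot <- boot
        f <- file.path(config$out_dir, "fit.json")
        jsonlite::write_json(list(par = as.list(coef(fit)),
                                  sse = fit$fit$sse, seed = s),
                             f, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        art("fit", f, s)
        f2 <- file.path(config$out_dir, "bootstrap.csv")
        utils::write.csv(boot$par_matrix, f2, row.names = FALSE)
        art("bootstrap", f2, s)
      },
      sweep = {
        baselines <- if (!is.null(state$boot)) {
          bootstrap_baselines(state$boot)
        } else list(config$params)
        state$grid <- run_oat_grid(baselines,
                                   param_ids = config$sweep_params,
                                   multipliers = config$multipliers,
                                   horizon = config$horizon,
                                   phys = config$phys)
        f <- file.path(config$out_dir, "sweep_meta.json")
        jsonlite::write_json(list(B = state$grid$B,
                                  params = config$sweep_params,
                                  multipliers = config$multipliers),
                             f, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        art("sweep_meta", f)
      },
      totvar = {
        if (is.null(state$grid)) stop("totvar stage requires a sweep stage")
        rec <- sensitivity_records(state$grid)
        agg <- aggregate_totvar(rec, config$totvar_threshold)
        f <- file.path(config$out_dir, "totvar_heatmap.csv")
        write_heatmap_table(agg, f)
        state$totvar <- agg
        art("totvar_heatmap", f)
      },
      correlate = {
        if (is.null(state$grid)) {
          stop("correlate stage requires a sweep stage")
        }
        tab <- correlation_table(state$grid,
                                 frac_threshold = config$frac_threshold)
        f <- file.path(config$out_dir, "correlation_table.csv")
        write_heatmap_table(tab, f)
        state$correlation <- tab
        art("correlation_table", f)
      })
  }
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
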