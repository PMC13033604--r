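## Calibration of the fitted parameter subset to a tumor-growth cohort:
## log-space genetic-algorithm minimisation of the SSE objective, with
## bootstrap resampling of growth curves for uncertainty.

#' Empirical growth rate by central differences
#'
#' Interior points use the centred difference
#' \code{(V[i+1] - V[i-1]) / (t[i+1] - t[i-1])}; the two endpoints use
#' one-sided differences, so the output has the length of the input.
#'
#' @param days Strictly increasing measurement days.
#' @param volumes Tumor volumes (mm3) at those days.
#' @return Growth-rate vector (mm3/day), same length as the input.
#' @export
central_difference_growth <- function(days, volumes) {
  n <- length(days)
  stopifnot(n >= 2L, length(volumes) == n)
  if (any(diff(days) <= 0)) stop("duplicate or non-increasing days")
  g <- numeric(n)
  g[1] <- (volumes[2] - volumes[1]) / (days[2] - days[1])
  g[n] <- (volumes[n] - volumes[n - 1]) / (days[n] - days[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1L)
    g[i] <- (volumes[i + 1L] - volumes[i - 1L]) / (days[i + 1L] - days[i - 1L])
  }
  g
}

## map a cohort's group labels to protocols (one shared simulation each)
protocols_for_groups <- function(groups) {
  stats::setNames(lapply(groups, build_protocol), groups)
}

## default growth-term weight: normalise the two observables by the
## control-group data variances (falls back to the whole cohort when no
## control curves are present)
growth_weight <- function(dataset) {
  d <- dataset[dataset$group == "CONTROL", ]
  if (nrow(d) == 0L) d <- dataset
  g <- unlist(lapply(split(d, list(d$subject, d$tumor), drop = TRUE),
                     function(s) {
                       s <- s[order(s$day), ]
                       central_difference_growth(s$day, s$volume_mm3)
                     }))
  vv <- stats::var(d$volume_mm3)
  vg <- stats::var(g)
  if (!is.finite(vg) || vg <= 0) return(1)
  vv / vg
}

#' Sum-of-squared-errors calibration objective
#'
#' One simulation per treatment group present in the cohort (at the
#' candidate parameters), then over every subject-tumor curve the squared
#' mismatch of (i) tumor volumes at the measurement days (simulated volumes
#' linearly interpolated from the output grid) and (ii) empirical growth
#' rates, both observed and simulated rates taken by
#' \code{\link{central_difference_growth}} at the measurement days.  The
#' growth term is weighted by \code{weight_growth}; the default normalises
#' the two terms by the control-group data variances.  A failed simulation
#' yields \code{+Inf} with a warning.
#'
#' @param log_params Named log-parameter vector (natural log) over
#'   \code{\link{fitted_parameter_names}}.
#' @param dataset Long-format cohort (columns subject, group, tumor, day,
#'   volume_mm3).
#' @param protocols Named list of \code{absq_protocol}s per group label
#'   (default: built from the labels in the data).
#' @param weight_growth Growth-term weight w; \code{NULL} for the
#'   variance-normalised default, 0 for a pure volume objective.
#' @param base_params Parameter set supplying the non-fitted constants.
#' @param phys Physiology table.
#' @param horizon,dt Simulation window and grid passed to the engine.
#' @return Scalar SSE (>= 0).
#' @export
sse_objective <- function(log_params, dataset, protocols = NULL,
                          weight_growth = NULL,
                          base_params = default_parameters(),
                          phys = default_phys(),
                          horizon = NULL, dt = 0.25) {
  groups <- unique(dataset$group)
  if (is.null(protocols)) protocols <- protocols_for_groups(groups)
  if (is.null(weight_growth)) weight_growth <- growth_weight(dataset)
  if (is.null(horizon)) horizon <- max(dataset$day)
  theta <- exp(log_params)
  p <- try(fitted_to_params(theta, base_params), silent = TRUE)
  if (inherits(p, "try-error")) return(Inf)
  sims <- list()
  for (g in groups) {
    tr <- try(simulate_protocol(p, protocols[[g]], horizon = horizon,
                                dt = dt, phys = phys), silent = TRUE)
    if (inherits(tr, "try-error")) {
      warning("simulation failed for group ", g, ": ",
              attr(tr, "condition")$message, call. = FALSE)
      return(Inf)
    }
    sims[[g]] <- tr
  }
  sse <- 0
  for (key in split(dataset, list(dataset$subject, dataset$tumor),
                    drop = TRUE)) {
    key <- key[order(key$day), ]
    tr <- sims[[key$group[1]]]
    tum <- if (key$tumor[1] %in% c("T1", 1)) 1L else 2L
    vsim <- stats::approx(tr$times, output_series(tr, "volume", tum),
                          xout = key$day)$y
    sse <- sse + sum((vsim - key$volume_mm3)^2)
    if (weight_growth > 0 && nrow(key) >= 2L) {
      gsim <- central_difference_growth(key$day, vsim)
      gobs <- central_difference_growth(key$day, key$volume_mm3)
      sse <- sse + weight_growth * sum((gsim - gobs)^2)
    }
  }
  sse
}

#' Adaptive log-space search bounds from an initial population
#'
#' Per parameter, the lower bound is the population column minimum expanded
#' downward by up to 10% of its log-space magnitude (a fresh uniform draw
#' per parameter per call), and the upper bound the column maximum expanded
#' upward likewise, so the bounds always contain the initial population and
#' the search is never trapped at preset limits.
#'
#' @param init_population Matrix of log-parameter vectors (rows =
#'   individuals).
#' @return List with \code{lower} and \code{upper} vectors.
#' @export
adaptive_log_bounds <- function(init_population) {
  if (is.null(dim(init_population))) {
    init_population <- matrix(init_population, nrow = 1)
  }
  if (nrow(init_population) == 0L) stop("empty initial population")
  mn <- apply(init_population, 2, min)
  mx <- apply(init_population, 2, max)
  u_lo <- runif(length(mn))
  u_hi <- runif(length(mx))
  list(lower = mn - u_lo * 0.1 * pmax(abs(mn), 1e-8),
       upper = mx + u_hi * 0.1 * pmax(abs(mx), 1e-8))
}

#' Genetic-algorithm configuration
#'
#' @param pop_size Individuals per generation.
#' @param generations Maximum generations.
#' @param elite Elites copied unchanged each generation.
#' @param p_crossover Probability a child is produced by blend crossover.
#' @param p_mutation Per-gene mutation probability.
#' @param mut_sd Gaussian mutation standard deviation (log units).
#' @param stall_generations Stop early after this many generations without
#'   improvement of the best objective (the stopping rule).
#' @param hybrid Run a quasi-Newton (finite-difference BFGS) local polish
#'   of the incumbent — periodically during the run and once at the end —
#'   the customary companion of population GA searches. Disable for
#'   desk-scale bootstrap refits, where a deep polish only overfits
#'   resampled noise.
#' @param hybrid_maxit Iteration cap of the final polish.
#' @return List of class \code{absq_ga_config}.
#' @export
ga_config <- function(pop_size = 40L, generations = 60L, elite = 2L,
                      p_crossover = 0.8, p_mutation = 0.15, mut_sd = 0.2,
                      stall_generations = 15L, hybrid = TRUE,
                      hybrid_maxit = 50L) {
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 elite = as.integer(elite), p_crossover = p_crossover,
                 p_mutation = p_mutation, mut_sd = mut_sd,
                 stall_generations = as.integer(stall_generations),
                 hybrid = isTRUE(hybrid),
                 hybrid_maxit = as.integer(hybrid_maxit),
                 polish_every = 20L, polish_maxit = 8L),
            class = "absq_ga_config")
}

#' Real-coded genetic minimiser in log space
#'
#' Tournament selection, blend (BLX-type) crossover, annealed Gaussian
#' mutation, elitism, exploitation clones of the incumbent, an optional
#' hybrid BFGS polish, and a stall-based stopping rule; every candidate is
#' clipped to the supplied bounds and evaluated through a memoising cache.
#' The returned best individual is reproducible for a fixed seed and
#' configuration.
#'
#' @param fn Objective over a log-parameter vector (minimised).
#' @param init_population Matrix of starting log-parameter vectors; recycled
#'   or subsampled to the configured population size.
#' @param config An \code{\link{ga_config}}.
#' @param seed Integer RNG seed.
#' @param bounds \code{NULL} for \code{\link{adaptive_log_bounds}} of the
#'   initial population, or a list(lower, upper).
#' @return List: \code{par} (best log vector), \code{value},
#'   \code{generations_run}, \code{evaluations}, \code{history} (best value
#'   per generation), \code{bounds}.
#' @export
ga_minimize <- function(fn, init_population, config = ga_config(),
                        seed = 1L, bounds = NULL) {
  if (is.null(dim(init_population))) {
    init_population <- matrix(init_population, nrow = 1)
  }
  if (nrow(init_population) == 0L) stop("empty initial population")
  set.seed(seed)
  npar <- ncol(init_population)
  if (is.null(bounds)) bounds <- adaptive_log_bounds(init_population)
  lower <- bounds$lower; upper <- bounds$upper
  clip <- function(x) pmin(pmax(x, lower), upper)

  cache <- new.env(parent = emptyenv())
  nevals <- 0L
  evaluate <- function(x) {
    key <- paste(signif(x, 12), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- fn(x)
    if (!is.finite(v)) v <- Inf
    nevals <<- nevals + 1L
    cache[[key]] <- v
    v
  }

  ## seed population: supplied rows first, then perturbed copies
  pop <- init_population[rep_len(seq_len(nrow(init_population)),
                                 config$pop_size), , drop = FALSE]
  if (config$pop_size > nrow(init_population)) {
    extra <- (nrow(init_population) + 1L):config$pop_size
    for (i in extra) {
      pop[i, ] <- clip(pop[i, ] + rnorm(npar, 0, config$mut_sd))
    }
  }
  fitness <- apply(pop, 1, evaluate)
  history <- numeric(0)
  best_val <- Inf; best_par <- pop[1, ]; stall <- 0L; gens <- 0L
  n_exploit <- max(2L, config$pop_size %/% 8L)
  for (gen in seq_len(config$generations)) {
    gens <- gen
    ord <- order(fitness)
    if (fitness[ord[1]] < best_val - 1e-12) {
      best_val <- fitness[ord[1]]; best_par <- pop[ord[1], ]; stall <- 0L
    } else stall <- stall + 1L
    history <- c(history, best_val)
    if (stall >= config$stall_generations) break
    ## annealed mutation scale: broad early, refining late
    anneal <- max(0.1, 1 - (gen - 1) / config$generations)
    sd_gen <- config$mut_sd * anneal
    newpop <- pop[ord[seq_len(config$elite)], , drop = FALSE]
    ## exploitation clones around the incumbent optimum
    for (i in seq_len(n_exploit)) {
      newpop <- rbind(newpop,
                      clip(best_par + rnorm(npar, 0, 0.3 * sd_gen)))
    }
    while (nrow(newpop) < config$pop_size) {
      pick <- function() {
        c3 <- sample.int(nrow(pop), 3L)
        pop[c3[which.min(fitness[c3])], ]
      }
      child <- if (runif(1) < config$p_crossover) {
        a <- runif(npar, -0.1, 1.1)
        a * pick() + (1 - a) * pick()
      } else pick()
      mut <- runif(npar) < config$p_mutation
      child[mut] <- child[mut] + rnorm(sum(mut), 0, sd_gen)
      newpop <- rbind(newpop, clip(child))
    }
    ## periodic memetic polish of the incumbent, re-injected into the
    ## population (replaces the last row)
    if (config$hybrid && !is.null(config$polish_every) &&
        gen %% config$polish_every == 0L && is.finite(best_val)) {
      pol <- stats::optim(best_par, function(x) evaluate(clip(x)),
                          method = "BFGS",
                          control = list(maxit = config$polish_maxit))
      if (pol$value < best_val) {
        best_val <- pol$value
        best_par <- clip(pol$par)
        newpop[nrow(newpop), ] <- best_par
      }
    }
    pop <- newpop[seq_len(config$pop_size), , drop = FALSE]
    fitness <- apply(pop, 1, evaluate)
  }
  ord <- order(fitness)
  if (fitness[ord[1]] < best_val) {
    best_val <- fitness[ord[1]]; best_par <- pop[ord[1], ]
  }
  ## hybrid finishing step: derivative-free local polish of the incumbent
  ## (the usual companion of population GA runs), clipped to the bounds
  if (config$hybrid && is.finite(best_val) && config$hybrid_maxit > 0L) {
    pol <- stats::optim(best_par, function(x) evaluate(clip(x)),
                        method = "BFGS",
                        control = list(maxit = config$hybrid_maxit,
                                       reltol = 1e-12))
    if (pol$value < best_val) {
      best_val <- pol$value
      best_par <- clip(pol$par)
    }
  }
  list(par = stats::setNames(as.numeric(best_par),
                             colnames(init_population)),
       value = best_val, generations_run = gens, evaluations = nevals,
       history = history, bounds = bounds)
}

#' Fit the model to a cohort with the genetic algorithm
#'
#' Runs \code{\link{ga_minimize}} on \code{\link{sse_objective}} in log
#' space.  All treatment groups are fitted jointly with shared parameters;
#' only the (k_TN, k_rc1) pair differs between the control and the
#' radiotherapy-treated arms.
#'
#' @param dataset Long-format cohort data frame.
#' @param protocols Named protocol list (default from the group labels).
#' @param init_population Matrix of log-parameter starting vectors (rows).
#' @param config An \code{\link{ga_config}}.
#' @param seed Integer seed (GA and adaptive bounds).
#' @param weight_growth,base_params,phys,horizon Passed to the objective.
#' @return A \code{FitResult}: list of class \code{absq_fit_ga} with
#'   \code{log_par}, \code{par} (natural scale), \code{sse},
#'   \code{generations_run}, \code{evaluations}, \code{config},
#'   \code{seed}, \code{bounds}.
#' @export
fit_ga <- function(dataset, protocols = NULL, init_population,
                   config = ga_config(), seed = 1L, weight_growth = NULL,
                   base_params = default_parameters(),
                   phys = default_phys(), horizon = NULL) {
  groups <- unique(dataset$group)
  if (is.null(protocols)) protocols <- protocols_for_groups(groups)
  if (is.null(weight_growth)) weight_growth <- growth_weight(dataset)
  fn <- function(x) {
    names(x) <- colnames(init_population)
    sse_objective(x, dataset, protocols, weight_growth, base_params, phys,
                  horizon)
  }
  res <- ga_minimize(fn, init_population, config, seed)
  structure(list(log_par = res$par, par = exp(res$par), sse = res$value,
                 generations_run = res$generations_run,
                 evaluations = res$evaluations, history = res$history,
                 bounds = res$bounds, config = config, seed = seed),
            class = "absq_fit_ga")
}

#' Initial GA population around a parameter set
#'
#' First row is the centre itself; the rest are log-uniform perturbations
#' within +/- \code{spread} decades per parameter.
#'
#' @param center An \code{absq_params} object.
#' @param n Population rows.
#' @param spread Half-width in log10 units (default 0.7: x0.2 to x5).
#' @param seed Integer seed.
#' @return Matrix with named columns (natural-log scale).
#' @export
init_population_around <- function(center = default_parameters(), n = 40L,
                                   spread = 0.7, seed = 1L) {
  set.seed(seed)
  th0 <- log(params_to_fitted(center))
  pop <- matrix(rep(th0, each = n), nrow = n,
                dimnames = list(NULL, fitted_parameter_names()))
  if (n > 1L) {
    jit <- matrix(runif((n - 1L) * length(th0), -spread, spread) * log(10),
                  nrow = n - 1L)
    pop[-1L, ] <- pop[-1L, , drop = FALSE] + jit
  }
  pop
}

#' Bootstrap resampling and refitting
#'
#' Resamples whole subject-tumor growth curves with replacement within each
#' (group, tumor) stratum, preserving stratum sizes exactly, and refits the
#' model to each resampled cohort.  Each refit's initial population holds
#' the baseline optimum and all previously found bootstrap optima
#' (accelerating convergence), padded with perturbed copies, and its search
#' bounds are drawn afresh by \code{\link{adaptive_log_bounds}}.
#'
#' @param dataset Long-format cohort data frame.
#' @param B Number of bootstrap replicates (study default 50).
#' @param base_fit An \code{absq_fit_ga} or \code{absq_fit} from the full
#'   dataset.
#' @param seed Integer seed; replicate r uses \code{seed + r}.
#' @param config GA configuration for the refits.
#' @param protocols,weight_growth,base_params,phys Passed through.
#' @return Object of class \code{absq_boot}: \code{fits} (list of
#'   FitResults), \code{resamples} (per-replicate subject-tumor index
#'   lists), \code{par_matrix} (B x npar, natural scale), and \code{stats}
#'   (per-parameter mean, median, sd, and 90% CI).
#' @export
bootstrap_refit <- function(dataset, B = 50L, base_fit, seed = 1L,
                            config = ga_config(pop_size = 16L,
                                               generations = 10L),
                            protocols = NULL, weight_growth = NULL,
                            base_params = default_parameters(),
                            phys = default_phys()) {
  if (B < 1L) stop("B must be >= 1")
  if (inherits(base_fit, "absq_fit")) base_fit <- base_fit$fit
  groups <- unique(dataset$group)
  if (is.null(protocols)) protocols <- protocols_for_groups(groups)
  if (is.null(weight_growth)) weight_growth <- growth_weight(dataset)
  curves <- split(dataset, list(dataset$subject, dataset$tumor), drop = TRUE)
  stratum <- vapply(curves, function(d) {
    paste(d$group[1], d$tumor[1])
  }, "")
  optima <- matrix(base_fit$log_par, nrow = 1,
                   dimnames = list(NULL, names(base_fit$log_par)))
  fits <- vector("list", B)
  resamples <- vector("list", B)
  for (r in seq_len(B)) {
    set.seed(seed + r)
    idx <- unlist(lapply(unique(stratum), function(st) {
      members <- which(stratum == st)
      sample(members, length(members), replace = TRUE)
    }))
    resamples[[r]] <- idx
    boot_data <- do.call(rbind, lapply(seq_along(idx), function(j) {
      d <- curves[[idx[j]]]
      d$subject <- paste0("b", j)        # resampled curves stay distinct
      d
    }))
    init <- optima[rep_len(seq_len(nrow(optima)), config$pop_size), ,
                   drop = FALSE]
    if (config$pop_size > nrow(optima)) {
      extra <- (nrow(optima) + 1L):config$pop_size
      jit <- matrix(rnorm(length(extra) * ncol(init), 0, 0.1),
                    nrow = length(extra))
      init[extra, ] <- init[extra, , drop = FALSE] + jit
    }
    fits[[r]] <- fit_ga(boot_data, protocols, init, config,
                        seed = seed + 1000L + r,
                        weight_growth = weight_growth,
                        base_params = base_params, phys = phys)
    optima <- rbind(optima, fits[[r]]$log_par)
  }
  par_matrix <- do.call(rbind, lapply(fits, `[[`, "par"))
  stats_df <- data.frame(
    parameter = colnames(par_matrix),
    mean = apply(par_matrix, 2, mean),
    median = apply(par_matrix, 2, stats::median),
    sd = apply(par_matrix, 2, stats::sd),
    ci_lower = apply(par_matrix, 2, stats::quantile, probs = 0.05),
    ci_upper = apply(par_matrix, 2, stats::quantile, probs = 0.95),
    row.names = NULL)
  structure(list(fits = fits, resamples = resamples,
                 par_matrix = par_matrix, stats = stats_df, B = B,
                 base_fit = base_fit, seed = seed,
                 base_params = base_params),
            class = "absq_boot")
}

#' Parameter sets of the bootstrap optima
#'
#' @param boot An \code{absq_boot}.
#' @return List of \code{absq_params}, one per replicate (the baselines for
#'   the sensitivity and correlation analyses).
#' @export
bootstrap_baselines <- function(boot) {
  lapply(seq_len(boot$B), function(r) {
    fitted_to_params(boot$par_matrix[r, ], boot$base_params)
  })
}

#' @export
print.absq_boot <- function(x, ...) {
  cat("<absq_boot> ", x$B, " bootstrap refits\n", sep = "")
  print(x$stats, digits = 3)
  invisible(x)
}

#' @export
print.absq_fit_ga <- function(x, ...) {
  cat(sprintf("<absq_fit_ga> SSE = %.6g after %d generations (%d evaluations)\n",
              x$sse, x$generations_run, x$evaluations))
  invisible(x)
}
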