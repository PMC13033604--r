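## Linear-quadratic radiation dose events and the three study protocols.

#' Linear-quadratic surviving fraction
#'
#' \code{S = exp(-(a D + b D^2))}: the fraction of cells surviving a single
#' instantaneous dose \code{D}.
#'
#' @param D Dose in Gy.
#' @param a Linear radiosensitivity (1/Gy).
#' @param b Quadratic radiosensitivity (1/Gy2).
#' @return Surviving fraction in (0, 1].
#' @export
lq_survival <- function(D, a, b) {
  if (any(c(D, a, b) < 0)) stop("lq_survival: negative input")
  exp(-(a * D + b * D^2))
}

#' Construct a radiation dose event
#'
#' @param time Day of delivery.
#' @param dose_gy Dose in Gy (>= 0).
#' @param target \code{"TUMOR1"} or \code{"LYMPH_NODES"}; only the local
#'   tumor is irradiable.
#' @return A list of class \code{absq_event}.
#' @export
radiation_event <- function(time, dose_gy, target = c("TUMOR1",
                                                      "LYMPH_NODES")) {
  target <- match.arg(target)
  if (dose_gy < 0) stop("radiation_event: negative dose")
  structure(list(time = time, dose_gy = dose_gy, target = target),
            class = "absq_event")
}

#' Apply an instantaneous radiation event to a system state
#'
#' A tumor event rescales the viable pool by the tumor-cell LQ survival and
#' moves the killed cells into the dead pool, conserving TV + TD.  A
#' lymph-node event rescales the APC, naive and effector CD8+ T-cell
#' populations of the lymph-node compartment (vascular and interstitial) by
#' the immune-cell LQ survival; killed lymphocytes leave the system.  All
#' other entries are untouched.
#'
#' @param state Named state vector.
#' @param event An \code{absq_event}.
#' @param params An \code{absq_params} object (radiosensitivities).
#' @return The transformed state vector.
#' @export
apply_radiation_event <- function(state, event, params) {
  if (!inherits(event, "absq_event")) stop("not an absq_event")
  if (event$dose_gy == 0) return(state)
  if (event$target == "TUMOR1") {
    S <- lq_survival(event$dose_gy, params$a_c, params$b_c)
    iv <- state_index("TV", "TUMOR1")
    id <- state_index("TD", "TUMOR1")
    killed <- (1 - S) * state[iv]
    state[iv] <- S * state[iv]
    state[id] <- state[id] + killed
  } else if (event$target == "LYMPH_NODES") {
    S <- lq_survival(event$dose_gy, params$a_IM, params$b_IM)
    idx <- c(state_index("TN", "LYMPH_NODES"),
             state_index("APC", "LYMPH_NODES", "interstitial"),
             state_index("APC", "LYMPH_NODES", "vascular"),
             state_index("TE1", "LYMPH_NODES", "interstitial"),
             state_index("TE1", "LYMPH_NODES", "vascular"))
    state[idx] <- S * state[idx]
  } else {
    stop("unsupported radiation target: ", event$target)
  }
  state
}

#' Treatment groups
#' @return Character vector of the three group labels.
#' @export
treatment_groups <- function() c("CONTROL", "T1_RT", "T1_RT_LN_RT")

#' Build a study treatment protocol
#'
#' The three arms of the bilateral-tumor experiment: no treatment; 10 Gy to
#' tumor 1 on day 10; or 10 Gy to tumor 1 on day 10 plus 3 Gy to the
#' tumor-draining lymph nodes on days 10, 13 and 16.
#'
#' @param group One of \code{"CONTROL"}, \code{"T1_RT"},
#'   \code{"T1_RT_LN_RT"}.
#' @return A list of class \code{absq_protocol} with fields \code{group} and
#'   \code{events} (time-ordered \code{absq_event}s).
#' @export
build_protocol <- function(group = treatment_groups()) {
  group <- match.arg(group)
  events <- switch(group,
    CONTROL = list(),
    T1_RT = list(radiation_event(10, 10, "TUMOR1")),
    T1_RT_LN_RT = list(radiation_event(10, 10, "TUMOR1"),
                       radiation_event(10, 3, "LYMPH_NODES"),
                       radiation_event(13, 3, "LYMPH_NODES"),
                       radiation_event(16, 3, "LYMPH_NODES")))
  structure(list(group = group, events = events), class = "absq_protocol")
}

#' @export
print.absq_protocol <- function(x, ...) {
  cat("<absq_protocol> ", x$group, ": ", length(x$events), " event(s)\n",
      sep = "")
  for (e in x$events) {
    cat(sprintf("  day %g: %g Gy -> %s\n", e$time, e$dose_gy, e$target))
  }
  invisible(x)
}

#' Serialize protocols as JSON or YAML
#'
#' @param protocol An \code{absq_protocol}.
#' @param path File path ending in \code{.json}, \code{.yaml} or
#'   \code{.yml}.
#' @export
write_protocol <- function(protocol, path) {
  obj <- list(group = protocol$group,
              events = lapply(protocol$events, function(e) {
                list(day = e$time, dose_gy = e$dose_gy, target = e$target)
              }))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  events <- lapply(obj$events, function(e) {
    radiation_event(e$day, e$dose_gy, e$target)
  })
  ord <- order(vapply(events, `[[`, numeric(1), "time"))
  structure(list(group = obj$group, events = events[ord]),
            class = "absq_protocol")
}
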