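## Kinetic, radiosensitivity and auxiliary constants of the tumor-immune
## interaction kernel, including the two group-dependent (k_TN, k_rc1) pairs.

## names of the calibrated parameters (log-space optimisation vector).
## k_TN and k_rc1 carry one value per treatment condition (control vs any
## radiotherapy-treated arm); everything else is shared across arms.
FITTED_SHARED <- c("lg_tumor", "Vi_tumor0", "Clear_c_dead", "Ac_DC", "Ac_M1",
                   "Ac_dead_DC", "Ac_dead_M1", "k_prol_TN", "a_c", "b_c",
                   "a_IM", "b_IM")
FITTED_PAIRED <- c("k_TN", "k_rc1")

#' Names of the calibrated parameters
#'
#' Shared parameters carry one value; \code{k_TN} and \code{k_rc1} carry a
#' control and a radiotherapy-treated value each, giving the 16-element
#' log-space optimisation vector used by \code{\link{fit_ga}}.
#'
#' @return Character vector of the 16 fitted parameter labels, the paired
#'   entries suffixed \code{_control}/\code{_rt}.
#' @export
fitted_parameter_names <- function() {
  c(FITTED_SHARED,
    paste0(rep(FITTED_PAIRED, each = 2), c("_control", "_rt")))
}

#' Default model parameter set
#'
#' The shipped defaults are the package's calibrated operating point for the
#' bilateral-flank B16F10GP melanoma setting: a fast-growing tumor implanted
#' at 25 mm3, strong direct tumor-cell radiosensitivity, radiosensitive
#' lymph-node lymphocytes, and an immune loop (phagocytosis, antigen
#' presentation, lymph-node priming, cytolysis) tuned so that irradiating
#' tumor 1 slows the contralateral tumor and additional lymph-node
#' irradiation blunts that abscopal response.
#'
#' Units: rates 1/day; volumes mm3; phagocytosis/activation/cytolysis
#' constants per (cells/mL) per day; radiosensitivities 1/Gy and 1/Gy2;
#' suppression coefficients mL/cell; cell volume mm3/cell.
#'
#' @param ... Named overrides of any default entry.
#' @return An object of class \code{absq_params} (named list).
#' @export
default_parameters <- function(...) {
  p <- list(
    ## tumor growth and radiotherapy
    lg_tumor = 0.20,        # intrinsic growth rate (1/day)
    Vi_tumor0 = 25,         # implanted tumor volume (mm3)
    a_c = 0.25, b_c = 0.025,     # tumor-cell LQ radiosensitivity
    a_IM = 0.40, b_IM = 0.05,    # lymph-node immune-cell LQ radiosensitivity
    ## antigen handling
    Clear_c_dead = 0.25,    # debris clearance (1/day)
    Ac_DC = 4e-11,          # phagocytosis of viable cells by DC+APC
    Ac_M1 = 4e-12,          # ... by M1 (minor relative to DC)
    Ac_dead_DC = 8e-11,     # phagocytosis of debris by DC+APC
    Ac_dead_M1 = 8e-12,     # ... by M1 (minor relative to DC)
    ## lymph-node priming (per-group pairs)
    k_prol_TN = 2.0,        # naive CD8 logistic regeneration (1/day)
    k_TN = c(control = 9e-10, rt = 9e-9),     # naive->effector activation
    k_rc1 = c(control = 2e-7, rt = 6e-6),    # effector cytolytic rate
    ## fixed auxiliary constants (not fitted)
    TN0 = 1e6,              # baseline naive CD8 pool in the lymph nodes
    N_exp = 9000,            # effectors produced per activated naive cell
    s_Treg = 2e-7, s_M2 = 1e-7,  # suppression coefficients (mL/cell)
    v_cell = 1e-6,          # cell volume (mm3/cell) -> 1e6 cells per mm3
    phi_int = 0.5, phi_vas = 0.07,  # tumor sub-volume fractions
    ## immune birth/death rates (1/day) and baseline whole-body pools
    death = c(DC = 0.3, M1 = 0.3, M2 = 0.3, TREG = 0.2, TE1 = 0.25,
              APC = 0.7),
    baseline_total = c(DC = 2e6, M1 = 5e6, M2 = 5e6, TREG = 3e6, TE1 = 2e5,
                       APC = 0)
  )
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown)) stop("unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    for (nm in names(ov)) {
      if (length(p[[nm]]) > 1 && length(ov[[nm]]) == length(p[[nm]])) {
        v <- ov[[nm]]
        if (is.null(names(v))) names(v) <- names(p[[nm]])
        p[[nm]] <- v
      } else if (length(p[[nm]]) > 1 && length(ov[[nm]]) == 1) {
        p[[nm]][] <- ov[[nm]]          # scalar override of a paired entry
      } else {
        p[[nm]] <- ov[[nm]]
      }
    }
  }
  p <- structure(p, class = "absq_params")
  validate_parameters(p)
  p
}

validate_parameters <- function(p) {
  rates <- c("lg_tumor", "Clear_c_dead", "Ac_DC", "Ac_M1", "Ac_dead_DC",
             "Ac_dead_M1", "k_prol_TN", "a_c", "b_c", "a_IM", "b_IM")
  for (nm in rates) {
    if (any(p[[nm]] < 0)) stop("parameter ", nm, " must be >= 0")
  }
  if (p$Vi_tumor0 <= 0) stop("Vi_tumor0 must be > 0")
  for (nm in FITTED_PAIRED) {
    v <- p[[nm]]
    if (length(v) != 2 || !setequal(names(v), c("control", "rt"))) {
      stop("parameter ", nm, " must hold a (control, rt) pair")
    }
    if (any(v < 0)) stop("parameter ", nm, " must be >= 0")
  }
  invisible(TRUE)
}

#' @export
print.absq_params <- function(x, ...) {
  cat("<absq_params> tumor-immune kernel parameters\n")
  cat(sprintf("  lg_tumor=%.4g /day  Vi_tumor0=%.4g mm3  LQ(a_c=%.3g, b_c=%.3g)\n",
              x$lg_tumor, x$Vi_tumor0, x$a_c, x$b_c))
  cat(sprintf("  k_TN: control=%.3g rt=%.3g   k_rc1: control=%.3g rt=%.3g\n",
              x$k_TN["control"], x$k_TN["rt"],
              x$k_rc1["control"], x$k_rc1["rt"]))
  invisible(x)
}

#' Flatten / restore the fitted-parameter vector
#'
#' \code{params_to_fitted} extracts the 16 calibrated values (natural scale)
#' in the order of \code{\link{fitted_parameter_names}};
#' \code{fitted_to_params} writes such a vector back into a parameter set.
#'
#' @param p An \code{absq_params} object.
#' @param theta Named or ordered numeric vector of length 16 (natural scale).
#' @return A named numeric vector, or an updated \code{absq_params}.
#' @export
params_to_fitted <- function(p) {
  v <- c(unlist(p[FITTED_SHARED]),
         k_TN_control = unname(p$k_TN["control"]),
         k_TN_rt = unname(p$k_TN["rt"]),
         k_rc1_control = unname(p$k_rc1["control"]),
         k_rc1_rt = unname(p$k_rc1["rt"]))
  v[fitted_parameter_names()]
}

#' @rdname params_to_fitted
#' @export
fitted_to_params <- function(theta, p = default_parameters()) {
  nm <- fitted_parameter_names()
  if (is.null(names(theta))) names(theta) <- nm
  stopifnot(setequal(names(theta), nm))
  for (s in FITTED_SHARED) p[[s]] <- unname(theta[[s]])
  p$k_TN <- c(control = unname(theta[["k_TN_control"]]),
              rt = unname(theta[["k_TN_rt"]]))
  p$k_rc1 <- c(control = unname(theta[["k_rc1_control"]]),
               rt = unname(theta[["k_rc1_rt"]]))
  validate_parameters(p)
  p
}

#' Read and write parameter sets as JSON
#'
#' Values round-trip losslessly (full double precision) together with a
#' units block.
#'
#' @param p An \code{absq_params} object.
#' @param path JSON file path.
#' @export
write_parameters <- function(p, path) {
  body <- lapply(unclass(p), function(v) {
    if (!is.null(names(v))) as.list(v) else v   # keep names in JSON objects
  })
  meta <- list(units = list(
    rates = "1/day", volumes = "mm3",
    interaction_constants = "per (cells/mL) per day",
    radiosensitivity = "1/Gy and 1/Gy2", suppression = "mL/cell",
    v_cell = "mm3/cell"))
  jsonlite::write_json(list(parameters = body, metadata = meta), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- j$parameters
  for (nm in c("k_TN", "k_rc1", "death", "baseline_total")) {
    p[[nm]] <- unlist(p[[nm]])
  }
  p <- structure(p, class = "absq_params")
  validate_parameters(p)
  p
}
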