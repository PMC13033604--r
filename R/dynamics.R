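## State-vector layout, the tumor-immune interaction kernel, and the coupled
## ODE right-hand side (reference R implementation; the solver normally runs
## the compiled equivalent in src/).

## ---- state layout -------------------------------------------------------
## Per trafficking species (DC, M1, M2, TREG, TE1, APC), 26 slots:
## vascular counts in the 12 tissues, interstitial counts in the 12 tissues,
## arterial blood, venous blood.  Then TN (lymph-node interstitium) and the
## viable/dead tumor-cell pools of the two tumors.  161 states total.
N_TISSUE <- 12L
N_PER_SPECIES <- 26L
N_STATE <- 6L * N_PER_SPECIES + 5L

state_names <- function() {
  if (!is.null(.absq_cache$state_names)) return(.absq_cache$state_names)
  nm <- character(N_STATE)
  for (s in seq_along(SPECIES_TRAFFICKING)) {
    sp <- SPECIES_TRAFFICKING[s]
    base <- (s - 1L) * N_PER_SPECIES
    nm[base + 1:12] <- paste(sp, TISSUES, "vascular", sep = ".")
    nm[base + 13:24] <- paste(sp, TISSUES, "interstitial", sep = ".")
    nm[base + 25L] <- paste(sp, "ARTERIAL_BLOOD", "vascular", sep = ".")
    nm[base + 26L] <- paste(sp, "VENOUS_BLOOD", "vascular", sep = ".")
  }
  nm[157L] <- "TN.LYMPH_NODES.interstitial"
  nm[158L] <- "TV.TUMOR1.interstitial"
  nm[159L] <- "TD.TUMOR1.interstitial"
  nm[160L] <- "TV.TUMOR2.interstitial"
  nm[161L] <- "TD.TUMOR2.interstitial"
  .absq_cache$state_names <- nm
  nm
}

#' Locate a state-vector entry
#'
#' The state vector holds non-negative cell counts indexed by (species,
#' compartment, sub-compartment) in a fixed, documented layout; this helper
#' resolves an index so callers never hard-code positions.
#'
#' @param species One of the nine species labels.
#' @param compartment A compartment label.
#' @param sub \code{"vascular"} or \code{"interstitial"} (ignored for blood
#'   pools, which are purely vascular).
#' @return Integer index into the packed state vector.
#' @export
state_index <- function(species, compartment,
                        sub = c("interstitial", "vascular")) {
  sub <- match.arg(sub)
  if (compartment %in% c("ARTERIAL_BLOOD", "VENOUS_BLOOD")) sub <- "vascular"
  nm <- paste(species, compartment, sub, sep = ".")
  i <- match(nm, state_names())
  if (is.na(i)) stop("no state slot for ", nm)
  i
}

#' Empty (zero) state vector with canonical names
#' @return Named numeric vector of length 161.
#' @export
state_template <- function() {
  stats::setNames(numeric(N_STATE), state_names())
}

## ---- interaction kernel -------------------------------------------------

#' Tumor volume from cell counts
#'
#' Tumor volume is carried by the cell pools themselves:
#' \code{V = (Tv + Td) * v_cell}, so dead cells occupy volume until cleared.
#'
#' @param Tv,Td Viable and dead tumor-cell counts.
#' @param v_cell Cell volume in mm3/cell (default 1e-6: 1e6 cells per mm3).
#' @return Volume in mm3.
#' @export
tumor_volume <- function(Tv, Td, v_cell = 1e-6) {
  if (any(Tv < 0) || any(Td < 0)) stop("negative tumor cell counts")
  (Tv + Td) * v_cell
}

#' Cytolytic killing of viable tumor cells by effector CD8+ T cells
#'
#' Mass-action kill down-modulated by a saturating suppression denominator
#' contributed by regulatory T cells and M2 macrophages:
#' \code{k_rc1 * C_TE1 * Tv / (1 + s_Treg*C_Treg + s_M2*C_M2)}.  The same
#' rate leaves the viable pool and enters the dead pool (conversion, not
#' disappearance).
#'
#' @param TE1_conc,Treg_conc,M2_conc Interstitial concentrations (cells/mL).
#' @param Tv Viable tumor-cell count.
#' @param k_rc1 Cytolytic rate constant (per (cells/mL) per day).
#' @param s_Treg,s_M2 Suppression coefficients (mL/cell).
#' @return Kill rate in cells/day.
#' @export
cytolysis_rate <- function(TE1_conc, Tv, k_rc1, Treg_conc = 0, M2_conc = 0,
                           s_Treg = 0, s_M2 = 0) {
  args <- c(TE1_conc, Tv, k_rc1, Treg_conc, M2_conc, s_Treg, s_M2)
  if (any(args < 0)) stop("cytolysis_rate: negative input")
  k_rc1 * TE1_conc * Tv / (1 + s_Treg * Treg_conc + s_M2 * M2_conc)
}

#' Phagocytosis of viable and dead tumor cells and maturation into APCs
#'
#' DCs (and already-matured APCs, which share the DC rate constants) and M1
#' macrophages engulf viable tumor cells and dead-cell debris.  Engulfed
#' tumor cells leave the system; each phagocytosis event converts the
#' engaged DC or M1 cell into an APC at the matching per-cell rate, so the
#' conversion conserves DC+APC and M1+APC totals at the instant of
#' conversion.
#'
#' @param DC,APC,M1 Interstitial phagocyte counts in the tumor.
#' @param Tv,Td Viable/dead tumor-cell counts.
#' @param V_int Tumor interstitial volume (mL) used for all concentrations.
#' @param params An \code{absq_params} object (uses Ac_DC, Ac_M1,
#'   Ac_dead_DC, Ac_dead_M1).
#' @return List with \code{Tv_removal}, \code{Td_removal}, \code{DC_to_APC},
#'   \code{M1_to_APC} (cells/day).
#' @export
phagocytosis_rates <- function(DC, APC, M1, Tv, Td, V_int, params) {
  if (any(c(DC, APC, M1, Tv, Td) < 0)) stop("phagocytosis_rates: negative input")
  if (V_int <= 0) stop("phagocytosis_rates: zero interstitial volume")
  cDCA <- (DC + APC) / V_int
  cM1 <- M1 / V_int
  cTv <- Tv / V_int
  cTd <- Td / V_int
  list(
    Tv_removal = (params$Ac_DC * cDCA + params$Ac_M1 * cM1) * Tv,
    Td_removal = (params$Ac_dead_DC * cDCA + params$Ac_dead_M1 * cM1) * Td,
    DC_to_APC = DC * (params$Ac_DC * cTv + params$Ac_dead_DC * cTd),
    M1_to_APC = M1 * (params$Ac_M1 * cTv + params$Ac_dead_M1 * cTd)
  )
}

#' Lymph-node priming of naive CD8+ T cells
#'
#' Naive cells regenerate logistically towards their baseline pool
#' \code{TN0}, are consumed by APC-driven activation, and each activated
#' cell yields \code{N_exp} effector cells (clonal expansion).
#'
#' @param TN Naive CD8+ count in the lymph-node interstitium.
#' @param APC_LN_conc APC concentration in the lymph-node interstitium
#'   (cells/mL).
#' @param params An \code{absq_params} object (uses k_prol_TN, TN0, N_exp
#'   and the group-selected k_TN).
#' @param k_TN Activation rate constant; defaults to the control-arm value.
#' @return List with \code{TN_regen}, \code{TN_activation},
#'   \code{TE1_production} (cells/day).
#' @export
ln_priming_rates <- function(TN, APC_LN_conc, params,
                             k_TN = params$k_TN[["control"]]) {
  if (any(c(TN, APC_LN_conc) < 0)) stop("ln_priming_rates: negative input")
  if (params$TN0 <= 0) stop("ln_priming_rates: TN0 must be > 0")
  act <- k_TN * APC_LN_conc * TN
  list(TN_regen = params$k_prol_TN * TN * (1 - TN / params$TN0),
       TN_activation = act,
       TE1_production = params$N_exp * act)
}

#' First-order clearance of dead-cell debris
#'
#' @param Td Dead tumor-cell count.
#' @param Clear_c_dead Clearance rate constant (1/day).
#' @return Removal rate (cells/day); the cleared material leaves the system.
#' @export
debris_clearance <- function(Td, Clear_c_dead) {
  if (any(Td < 0)) stop("debris_clearance: negative Td")
  Clear_c_dead * Td
}

## ---- model context ------------------------------------------------------

## Precomputes everything the RHS needs: flow/volume vectors, 6 x 12
## transport matrices, birth/death vectors, and the flat parameter vector
## consumed by the compiled derivative function.
absq_context <- function(params, phys = default_phys(),
                         pair = c("control", "rt")) {
  pair <- match.arg(pair)
  comp <- phys$compartments
  rownames(comp) <- comp$compartment
  Q <- comp[TISSUES, "plasma_flow_ml_day"]
  Vvas <- comp[TISSUES, "vascular_ml"]
  Vint <- comp[TISSUES, "interstitial_ml"]
  Vart <- comp["ARTERIAL_BLOOD", "volume_ml"]
  Vven <- comp["VENOUS_BLOOD", "volume_ml"]
  tr <- phys$transport
  kext <- matrix(0, 6, N_TISSUE, dimnames = list(SPECIES_TRAFFICKING, TISSUES))
  klym <- kext
  kext[cbind(tr$species, tr$compartment)] <- tr$extravasation_per_day
  klym[cbind(tr$species, tr$compartment)] <- tr$lymph_exit_per_day
  death <- params$death[SPECIES_TRAFFICKING]
  birth <- death * params$baseline_total[SPECIES_TRAFFICKING]
  kin <- c(params$lg_tumor, params$Clear_c_dead, params$Ac_DC, params$Ac_M1,
           params$Ac_dead_DC, params$Ac_dead_M1, params$k_prol_TN,
           params$TN0, params$k_TN[[pair]], params$k_rc1[[pair]],
           params$s_Treg, params$s_M2, params$v_cell * 1e-3,  # mm3 -> mL
           params$N_exp, params$phi_int, params$phi_vas, 1e-9)
  parms <- c(Q[1], Q, Vvas, Vint, Vart, Vven,
             as.vector(t(kext)), as.vector(t(klym)), birth, death, kin)
  list(params = params, phys = phys, pair = pair, Q = Q, Qco = Q[[1]],
       Vvas = Vvas, Vint = Vint, Vart = Vart, Vven = Vven,
       kext = kext, klym = klym, birth = birth, death = death,
       parms = unname(parms))
}

## ---- reference right-hand side -----------------------------------------

#' Coupled ODE right-hand side (reference implementation)
#'
#' Assembles the full derivative vector: per trafficking species and tissue,
#' a vascular balance (perfusion in from arterial blood, out to venous
#' blood, minus extravasation), an interstitial balance (extravasation in,
#' lymph exit out, the lymph-node interstitium collecting all afferent lymph
#' and its efferent feeding venous blood), birth into venous blood and
#' first-order death everywhere; the tumor interstitia add the interaction
#' kernel (growth, cytolysis, phagocytosis/APC maturation, debris
#' clearance), and the lymph node adds naive-T regeneration, activation and
#' effector production.  Units are cells/day throughout.
#'
#' This R implementation is the testable reference; \code{simulate_protocol}
#' integrates the identical compiled version.
#'
#' @param t Time (days; the system is autonomous, kept for solver
#'   signature).
#' @param state Named state vector (see \code{\link{state_template}}).
#' @param params An \code{absq_params} object.
#' @param phys An \code{absq_physiology} object.
#' @param pair Which (k_TN, k_rc1) pair to use: "control" or "rt".
#' @return Derivative vector (cells/day) with the same layout as
#'   \code{state}.
#' @export
assemble_rhs <- function(t, state, params, phys = default_phys(),
                         pair = c("control", "rt")) {
  if (any(!is.finite(state))) {
    stop("non-finite state entry at index ", which(!is.finite(state))[1])
  }
  if (any(state < 0)) {
    stop("negative state entry at index ", which(state < 0)[1])
  }
  ctx <- if (inherits(params, "absq_context_ready")) params
         else absq_context(params, phys, match.arg(pair))
  rhs_reference(state, ctx)
}

rhs_reference <- function(state, ctx) {
  p <- ctx$params
  d <- numeric(N_STATE)
  v_cell_ml <- p$v_cell * 1e-3
  Tv1 <- state[158L]; Td1 <- state[159L]
  Tv2 <- state[160L]; Td2 <- state[161L]
  V1 <- (Tv1 + Td1) * v_cell_ml
  V2 <- (Tv2 + Td2) * v_cell_ml
  guard <- 1e-9
  Vint <- ctx$Vint
  Vvas <- ctx$Vvas
  Vint[11:12] <- pmax(p$phi_int * c(V1, V2), guard)
  Vvas[11:12] <- pmax(p$phi_vas * c(V1, V2), guard)

  for (s in seq_along(SPECIES_TRAFFICKING)) {
    base <- (s - 1L) * N_PER_SPECIES
    vas <- state[base + 1:12]
    int <- state[base + 13:24]
    art <- state[base + 25L]
    ven <- state[base + 26L]
    Cart <- art / ctx$Vart
    Cven <- ven / ctx$Vven
    Cvas <- vas / Vvas
    kext <- ctx$kext[s, ]
    klym <- ctx$klym[s, ]
    dvas <- numeric(12)
    dvas[1] <- ctx$Qco * (Cven - Cvas[1])
    dvas[-1] <- ctx$Q[-1] * (Cart - Cvas[-1])
    dvas <- dvas - kext * vas
    dint <- kext * vas - klym * int
    dint[10] <- dint[10] + sum(klym[-10] * int[-10])   # afferent lymph to LN
    dart <- ctx$Qco * Cvas[1] - sum(ctx$Q[-1]) * Cart
    dven <- sum(ctx$Q[-1] * Cvas[-1]) + klym[10] * int[10] -
      ctx$Qco * Cven + ctx$birth[s]
    ds <- ctx$death[s]
    d[base + 1:12] <- dvas - ds * vas
    d[base + 13:24] <- dint - ds * int
    d[base + 25L] <- dart - ds * art
    d[base + 26L] <- dven - ds * ven
  }

  k_TN <- p$k_TN[[ctx$pair]]
  k_rc1 <- p$k_rc1[[ctx$pair]]
  iDC <- (match("DC", SPECIES_TRAFFICKING) - 1L) * N_PER_SPECIES
  iM1 <- (match("M1", SPECIES_TRAFFICKING) - 1L) * N_PER_SPECIES
  iM2 <- (match("M2", SPECIES_TRAFFICKING) - 1L) * N_PER_SPECIES
  iTR <- (match("TREG", SPECIES_TRAFFICKING) - 1L) * N_PER_SPECIES
  iTE <- (match("TE1", SPECIES_TRAFFICKING) - 1L) * N_PER_SPECIES
  iAP <- (match("APC", SPECIES_TRAFFICKING) - 1L) * N_PER_SPECIES

  for (k in 1:2) {
    tum <- 10L + k                       # tissue index of TUMORk
    iv <- 156L + 2L * k                  # TVk slot (158 / 160)
    id <- iv + 1L
    Tv <- state[iv]; Td <- state[id]
    Vi <- Vint[tum]
    DC <- state[iDC + 12L + tum]; M1 <- state[iM1 + 12L + tum]
    M2 <- state[iM2 + 12L + tum]; TR <- state[iTR + 12L + tum]
    TE <- state[iTE + 12L + tum]; AP <- state[iAP + 12L + tum]
    cyto <- cytolysis_rate(TE / Vi, Tv, k_rc1, TR / Vi, M2 / Vi,
                           p$s_Treg, p$s_M2)
    ph <- phagocytosis_rates(DC, AP, M1, Tv, Td, Vi, p)
    d[iv] <- d[iv] + p$lg_tumor * Tv - cyto - ph$Tv_removal
    d[id] <- d[id] + cyto - debris_clearance(Td, p$Clear_c_dead) -
      ph$Td_removal
    d[iDC + 12L + tum] <- d[iDC + 12L + tum] - ph$DC_to_APC
    d[iM1 + 12L + tum] <- d[iM1 + 12L + tum] - ph$M1_to_APC
    d[iAP + 12L + tum] <- d[iAP + 12L + tum] + ph$DC_to_APC + ph$M1_to_APC
  }

  TN <- state[157L]
  apc_ln_conc <- state[iAP + 12L + 10L] / Vint[10]
  pr <- ln_priming_rates(TN, apc_ln_conc, p, k_TN)
  d[157L] <- pr$TN_regen - pr$TN_activation
  d[iTE + 12L + 10L] <- d[iTE + 12L + 10L] + pr$TE1_production
  names(d) <- state_names()
  d
}

## ---- baseline equilibration ---------------------------------------------

#' Initial state: tumor-free immune steady state plus tumor implants
#'
#' Before day 0 the tumor-free trafficking system is linear (transport,
#' birth into venous blood, first-order death), so its steady state is
#' obtained exactly by a linear solve per species rather than by long
#' pre-integration; naive CD8+ cells sit at their logistic baseline
#' \code{TN0} and APCs at zero.  Both tumors are then implanted at
#' \code{Vi_tumor0} as pure viable cells.
#'
#' @param params An \code{absq_params} object.
#' @param phys An \code{absq_physiology} object.
#' @param equilibrate If \code{FALSE}, immune states start at zero.
#' @return Named state vector.
#' @export
initial_state <- function(params, phys = default_phys(),
                          equilibrate = TRUE) {
  ctx <- absq_context(params, phys)
  y <- state_template()
  if (equilibrate) {
    ## the steady state depends only on transport, birth and death (none of
    ## them fitted), so memoise it on those values
    key <- paste(c("ss", ctx$birth, ctx$death, ctx$parms[1:183]),
                 collapse = ",")
    ss <- .absq_cache[[key]]
    if (is.null(ss)) {
      ss <- matrix(0, 26, 6)
      for (s in seq_along(SPECIES_TRAFFICKING)) {
        if (ctx$birth[s] <= 0) next
        ss[, s] <- steady_state_species(s, ctx)
      }
      .absq_cache[[key]] <- ss
    }
    for (s in seq_along(SPECIES_TRAFFICKING)) {
      y[(s - 1L) * N_PER_SPECIES + 1:26] <- ss[, s]
    }
  }
  y[157L] <- params$TN0
  y[158L] <- y[160L] <- params$Vi_tumor0 / params$v_cell
  y
}

## Exact tumor-free steady state of one trafficking species: 26 linear
## balance equations (tumor slots stay zero; the tumor share of arterial
## outflow is shunted straight back to venous blood, matching a tumor-free
## animal whose cardiac output is unchanged).
steady_state_species <- function(s, ctx) {
  A <- matrix(0, 26, 26)
  b <- numeric(26)
  organ <- 1:10                          # tissues present without tumors
  kext <- ctx$kext[s, ]
  klym <- ctx$klym[s, ]
  ds <- ctx$death[s]
  for (i in organ) {
    vi <- i; ii <- 12L + i
    if (i == 1L) {
      A[vi, 26] <- A[vi, 26] + ctx$Qco / ctx$Vven
      A[vi, vi] <- A[vi, vi] - ctx$Qco / ctx$Vvas[i]
    } else {
      A[vi, 25] <- A[vi, 25] + ctx$Q[i] / ctx$Vart
      A[vi, vi] <- A[vi, vi] - ctx$Q[i] / ctx$Vvas[i]
    }
    A[vi, vi] <- A[vi, vi] - kext[i] - ds
    A[ii, vi] <- A[ii, vi] + kext[i]
    A[ii, ii] <- A[ii, ii] - klym[i] - ds
    if (i != 10L) A[22L, ii] <- A[22L, ii] + klym[i]   # afferent lymph to LN
  }
  A[25, 1] <- A[25, 1] + ctx$Qco / ctx$Vvas[1]
  A[25, 25] <- A[25, 25] - sum(ctx$Q[2:12]) / ctx$Vart - ds
  for (i in 2:10) A[26, i] <- A[26, i] + ctx$Q[i] / ctx$Vvas[i]
  A[26, 25] <- A[26, 25] + sum(ctx$Q[11:12]) / ctx$Vart  # tumor-flow shunt
  A[26, 22] <- A[26, 22] + klym[10]
  A[26, 26] <- A[26, 26] - ctx$Qco / ctx$Vven - ds
  b[26] <- ctx$birth[s]
  act <- c(1:10, 13:22, 25:26)           # tumor slots excluded
  x <- numeric(26)
  x[act] <- solve(A[act, act], -b[act])
  pmax(x, 0)
}
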