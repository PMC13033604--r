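## Compartment network: organs, tumors, blood pools, species roster and the
## fixed transport/volume/flow constants of the mouse PBPK scaffold.

#' Species and compartment rosters
#'
#' The model tracks nine cell populations.  Six of them traffic through the
#' whole-body circulation (dendritic cells \code{DC}, pro- and
#' anti-inflammatory macrophages \code{M1}/\code{M2}, regulatory T cells
#' \code{TREG}, effector CD8+ T cells \code{TE1} and antigen-presenting cells
#' \code{APC}); naive CD8+ T cells \code{TN} reside only in the lymph nodes,
#' and viable/dead tumor cells \code{TV}/\code{TD} only in the two tumor
#' interstitia.
#'
#' @format Character vectors of identifiers.
#' @name rosters
NULL

#' @rdname rosters
#' @export
SPECIES_ALL <- c("DC", "M1", "M2", "TREG", "TN", "TE1", "APC", "TV", "TD")

#' @rdname rosters
#' @export
SPECIES_TRAFFICKING <- c("DC", "M1", "M2", "TREG", "TE1", "APC")

#' @rdname rosters
#' @export
COMPARTMENTS <- c("LUNGS", "LIVER", "GI", "SPLEEN", "HEART", "KIDNEYS",
                  "SKIN", "MUSCLE", "BONE", "LYMPH_NODES", "TUMOR1", "TUMOR2",
                  "ARTERIAL_BLOOD", "VENOUS_BLOOD")

## the twelve compartments carrying vascular + interstitial sub-compartments
TISSUES <- COMPARTMENTS[1:12]
ORGANS  <- COMPARTMENTS[1:10]
TUMORS  <- c("TUMOR1", "TUMOR2")

#' Build the default mouse physiology table
#'
#' Returns the compartment volumes, vascular/interstitial sub-volumes, plasma
#' flows and lymph flows of a ~25 g mouse, together with per-(species, tissue)
#' extravasation and lymph-exit rate constants for the six trafficking
#' populations.  Organ volumes and regional plasma flows follow standard
#' murine PBPK reference compilations; transport rate constants are
#' documented package defaults chosen so that baseline immune residence times
#' are on the order of hours to days and tumor extravasation is restricted
#' (abnormal tumor vasculature).  The arrangement is the standard PBPK series
#' circuit: venous blood feeds the lungs, the lungs feed arterial blood, and
#' arterial blood perfuses all other tissues in parallel; interstitial lymph
#' drains to the lymph-node compartment, whose efferent lymph returns to
#' venous blood.
#'
#' Tumor sub-volumes listed here are placeholders evaluated at the default
#' initial tumor volume; during simulation tumor vascular and interstitial
#' volumes scale with the instantaneous tumor volume (fractions 0.07 and
#' 0.5).
#'
#' @param species_profile Species label; only \code{"mouse"} is supported.
#' @return An object of class \code{absq_physiology}: a list with elements
#'   \code{compartments} (data frame: compartment, total/vascular/interstitial
#'   volume in mL, plasma flow Q and lymph flow L in mL/day) and
#'   \code{transport} (data frame: species, compartment, extravasation and
#'   lymph-exit rate constants in 1/day).
#' @export
build_default_physiology <- function(species_profile = "mouse") {
  if (!identical(species_profile, "mouse")) {
    stop("unsupported species profile: ", species_profile,
         " (only 'mouse' is available)")
  }
  ## total volumes (mL) and vascular/interstitial fractions, ~25 g mouse
  vol <- c(LUNGS = 0.20, LIVER = 1.40, GI = 2.50, SPLEEN = 0.10,
           HEART = 0.15, KIDNEYS = 0.34, SKIN = 2.90, MUSCLE = 9.50,
           BONE = 2.80, LYMPH_NODES = 0.05, TUMOR1 = 0.025, TUMOR2 = 0.025)
  f_vas <- c(LUNGS = 0.50, LIVER = 0.31, GI = 0.04, SPLEEN = 0.30,
             HEART = 0.07, KIDNEYS = 0.24, SKIN = 0.02, MUSCLE = 0.04,
             BONE = 0.03, LYMPH_NODES = 0.10, TUMOR1 = 0.07, TUMOR2 = 0.07)
  f_int <- c(LUNGS = 0.30, LIVER = 0.20, GI = 0.30, SPLEEN = 0.20,
             HEART = 0.25, KIDNEYS = 0.20, SKIN = 0.35, MUSCLE = 0.13,
             BONE = 0.10, LYMPH_NODES = 0.60, TUMOR1 = 0.50, TUMOR2 = 0.50)
  ## regional plasma flows (mL/day); lungs carry total cardiac plasma flow
  Q <- c(LIVER = 1770, GI = 1550, SPLEEN = 120, HEART = 730, KIDNEYS = 1000,
         SKIN = 1000, MUSCLE = 3000, BONE = 1600, LYMPH_NODES = 130,
         TUMOR1 = 50, TUMOR2 = 50)
  Qco <- sum(Q)                          # 11000 mL/day plasma cardiac output
  Q <- c(LUNGS = Qco, Q)
  ## lymph drainage: 0.2% of regional plasma flow; LN afferent = sum of all
  L <- 0.002 * Q
  L["LYMPH_NODES"] <- sum(L[setdiff(TISSUES, "LYMPH_NODES")])

  comp <- data.frame(
    compartment = COMPARTMENTS,
    volume_ml = c(vol[TISSUES], ARTERIAL_BLOOD = 0.5, VENOUS_BLOOD = 1.2),
    vascular_ml = c((vol * f_vas)[TISSUES], 0.5, 1.2),
    interstitial_ml = c((vol * f_int)[TISSUES], 0, 0),
    plasma_flow_ml_day = c(Q[TISSUES], Qco, Qco),
    lymph_flow_ml_day = c(L[TISSUES], 0, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )

  ## extravasation k_ext and lymph-exit k_lym (1/day) per species x tissue.
  ## Tumor extravasation is uniformly low (restricted, abnormal vasculature);
  ## APCs have fast lymphatic exit (active migration to the draining node)
  ## but are retained in the lymph node itself while presenting antigen;
  ## effector T cells egress the node quickly.
  kext_organ <- c(DC = 1.0, M1 = 1.0, M2 = 1.0, TREG = 0.8, TE1 = 0.8,
                  APC = 0.3)
  kext_tumor <- c(DC = 0.15, M1 = 0.15, M2 = 0.15, TREG = 0.15, TE1 = 0.15,
                  APC = 0.05)
  klym_organ <- c(DC = 0.3, M1 = 0.2, M2 = 0.2, TREG = 0.3, TE1 = 0.5,
                  APC = 1.5)
  klym_tumor <- c(DC = 0.3, M1 = 0.2, M2 = 0.2, TREG = 0.3, TE1 = 0.5,
                  APC = 2.0)
  klym_ln    <- c(DC = 0.3, M1 = 0.2, M2 = 0.2, TREG = 0.3, TE1 = 1.0,
                  APC = 0.05)

  tr <- expand.grid(species = SPECIES_TRAFFICKING, compartment = TISSUES,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tr$extravasation_per_day <- ifelse(tr$compartment %in% TUMORS,
                                     kext_tumor[tr$species],
                                     kext_organ[tr$species])
  tr$lymph_exit_per_day <- ifelse(
    tr$compartment %in% TUMORS, klym_tumor[tr$species],
    ifelse(tr$compartment == "LYMPH_NODES", klym_ln[tr$species],
           klym_organ[tr$species]))

  phys <- structure(list(compartments = comp, transport = tr,
                         species_profile = species_profile),
                    class = "absq_physiology")
  rep <- validate_physiology(phys)
  stopifnot(nrow(rep) == 0L)
  phys
}

## memoised copy of the (deterministic) default table, used as the default
## argument throughout to avoid rebuilding it in tight loops
.absq_cache <- new.env(parent = emptyenv())
default_phys <- function() {
  if (is.null(.absq_cache$phys)) .absq_cache$phys <- build_default_physiology()
  .absq_cache$phys
}

#' Validate a physiology table
#'
#' Checks the structural invariants of the compartment network and returns a
#' report of violations (empty data frame when the table is consistent):
#' positive volumes and flows for all tissues, sub-volumes summing to at most
#' the total volume, arterial outflow equal to the summed tissue plasma
#' flows, lymph-node afferent flow equal to the summed tissue lymph flows,
#' non-negative venous return \code{Q - L} per tissue, and a complete
#' transport table for every (trafficking species, tissue) pair.
#'
#' @param phys An \code{absq_physiology} object.
#' @return Data frame with columns \code{compartment}, \code{field},
#'   \code{message}, \code{residual}; zero rows iff the table is valid.
#' @export
validate_physiology <- function(phys) {
  bad <- list()
  flag <- function(compartment, field, message, residual = NA_real_) {
    bad[[length(bad) + 1L]] <<- data.frame(
      compartment = compartment, field = field, message = message,
      residual = residual, stringsAsFactors = FALSE)
  }
  comp <- phys$compartments
  if (!setequal(comp$compartment, COMPARTMENTS)) {
    flag("<table>", "compartment", "compartment roster incomplete")
  }
  for (i in seq_len(nrow(comp))) {
    r <- comp[i, ]
    tissue <- r$compartment %in% TISSUES
    if (r$volume_ml <= 0) {
      flag(r$compartment, "volume_ml", "non-positive volume", r$volume_ml)
    }
    if (tissue && r$plasma_flow_ml_day <= 0) {
      flag(r$compartment, "plasma_flow_ml_day", "non-positive plasma flow",
           r$plasma_flow_ml_day)
    }
    if (tissue && r$lymph_flow_ml_day < 0) {
      flag(r$compartment, "lymph_flow_ml_day", "negative lymph flow",
           r$lymph_flow_ml_day)
    }
    if (tissue && r$vascular_ml <= 0) {
      flag(r$compartment, "vascular_ml", "non-positive vascular sub-volume",
           r$vascular_ml)
    }
    if (tissue && r$interstitial_ml <= 0) {
      flag(r$compartment, "interstitial_ml",
           "non-positive interstitial sub-volume", r$interstitial_ml)
    }
    if (r$vascular_ml + r$interstitial_ml > r$volume_ml * (1 + 1e-12)) {
      flag(r$compartment, "sub_volumes", "sub-volumes exceed total volume",
           r$vascular_ml + r$interstitial_ml - r$volume_ml)
    }
    if (tissue && r$compartment != "LYMPH_NODES" &&
        r$plasma_flow_ml_day - r$lymph_flow_ml_day < 0) {
      flag(r$compartment, "venous_return", "negative venous return Q - L",
           r$plasma_flow_ml_day - r$lymph_flow_ml_day)
    }
  }
  cc <- function(name, col) comp[[col]][comp$compartment == name]
  perf <- setdiff(TISSUES, "LUNGS")
  qsum <- sum(comp$plasma_flow_ml_day[comp$compartment %in% perf])
  qart <- cc("ARTERIAL_BLOOD", "plasma_flow_ml_day")
  if (abs(qsum - qart) > 1e-9 * max(1, qart)) {
    flag("ARTERIAL_BLOOD", "plasma_flow_ml_day",
         "arterial outflow != sum of tissue plasma flows", qsum - qart)
  }
  afferent <- setdiff(TISSUES, "LYMPH_NODES")
  lsum <- sum(comp$lymph_flow_ml_day[comp$compartment %in% afferent])
  lln <- cc("LYMPH_NODES", "lymph_flow_ml_day")
  if (abs(lsum - lln) > 1e-9 * max(1, lln)) {
    flag("LYMPH_NODES", "lymph_flow_ml_day",
         "summed lymph flows != lymph-node inflow", lsum - lln)
  }
  tr <- phys$transport
  need <- expand.grid(species = SPECIES_TRAFFICKING, compartment = TISSUES,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$species, d$compartment)
  missing <- setdiff(key(need), key(tr))
  for (m in missing) flag(m, "transport", "missing transport constants")
  if (any(tr$extravasation_per_day < 0) || any(tr$lymph_exit_per_day < 0)) {
    i <- which(tr$extravasation_per_day < 0 | tr$lymph_exit_per_day < 0)[1]
    flag(tr$compartment[i], "transport", "negative transport rate constant")
  }
  if (length(bad) == 0L) {
    return(data.frame(compartment = character(), field = character(),
                      message = character(), residual = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}

#' @export
print.absq_physiology <- function(x, ...) {
  cat("<absq_physiology> ", x$species_profile, " physiology: ",
      nrow(x$compartments), " compartments, ",
      nrow(x$transport), " transport pairs\n", sep = "")
  invisible(x)
}

#' Read and write physiology tables
#'
#' The on-disk form is a pair of CSV tables (one row per compartment, one row
#' per species-compartment transport pair) identified by a \code{table}
#' column, or a YAML file with \code{compartments}/\code{transport} blocks.
#'
#' @param phys An \code{absq_physiology} object.
#' @param path File path (\code{.csv} or \code{.yaml}/\code{.yml}).
#' @return \code{read_physiology} returns an \code{absq_physiology};
#'   \code{write_physiology} returns \code{path} invisibly.
#' @export
write_physiology <- function(phys, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(list(species_profile = phys$species_profile,
                          compartments = phys$compartments,
                          transport = phys$transport), path)
  } else {
    a <- cbind(table = "compartments", phys$compartments)
    b <- cbind(table = "transport", phys$transport)
    nm <- union(names(a), names(b))
    a[setdiff(nm, names(a))] <- NA
    b[setdiff(nm, names(b))] <- NA
    utils::write.csv(rbind(a[nm], b[nm]), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_physiology
#' @export
read_physiology <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    phys <- structure(list(
      compartments = as.data.frame(y$compartments,
                                   stringsAsFactors = FALSE),
      transport = as.data.frame(y$transport, stringsAsFactors = FALSE),
      species_profile = y$species_profile), class = "absq_physiology")
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    comp <- d[d$table == "compartments",
              c("compartment", "volume_ml", "vascular_ml", "interstitial_ml",
                "plasma_flow_ml_day", "lymph_flow_ml_day")]
    tr <- d[d$table == "transport",
            c("species", "compartment", "extravasation_per_day",
              "lymph_exit_per_day")]
    rownames(comp) <- rownames(tr) <- NULL
    phys <- structure(list(compartments = comp, transport = tr,
                           species_profile = "mouse"),
                      class = "absq_physiology")
  }
  rep <- validate_physiology(phys)
  if (nrow(rep) > 0) {
    stop("invalid physiology table in ", path, ": ", rep$message[1])
  }
  phys
}
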