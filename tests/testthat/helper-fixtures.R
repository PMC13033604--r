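## Shared fixtures: built once per test run, all generated in code.

PHYS <- build_default_physiology()

## parameter set with every kinetic, birth and death term switched off:
## pure transport (used for conservation and linearity checks)
transport_only_params <- function() {
  default_parameters(
    lg_tumor = 0, Clear_c_dead = 0, Ac_DC = 0, Ac_M1 = 0, Ac_dead_DC = 0,
    Ac_dead_M1 = 0, k_prol_TN = 0, k_TN = c(control = 0, rt = 0),
    k_rc1 = c(control = 0, rt = 0),
    death = c(DC = 0, M1 = 0, M2 = 0, TREG = 0, TE1 = 0, APC = 0),
    baseline_total = c(DC = 0, M1 = 0, M2 = 0, TREG = 0, TE1 = 0, APC = 0))
}

## strictly positive random state (valid counts everywhere)
random_state <- function(seed = 1, scale = 1e5) {
  set.seed(seed)
  y <- state_template()
  y[] <- stats::rlnorm(length(y), log(scale), 1)
  y
}

## compiled RHS evaluated directly (independent path from assemble_rhs)
compiled_rhs <- function(y, params, pair = "control") {
  ctx <- abscopalQSP:::absq_context(params, PHYS, pair)
  deSolve::DLLfunc(y = unname(y), dllname = "abscopalQSP",
                   func = "absq_derivs", initfunc = "absq_init",
                   parms = ctx$parms, times = 0)$dy
}

## small noise-free cohort at given params (memoised per label)
.fixture_env <- new.env(parent = emptyenv())
noise_free_cohort <- function(params = default_parameters(),
                              label = "default", n = 1L) {
  key <- paste0("nf_", label, "_", n)
  if (is.null(.fixture_env[[key]])) {
    cfg <- cohort_config(n_per_group = n, sigma_noise = 0,
                         sigma_growth = 0, sigma_v0 = 0,
                         true_params = params)
    .fixture_env[[key]] <- generate_cohort(cfg, seed = 1)
  }
  .fixture_env[[key]]
}

## independent permutation enumeration (different algorithm from the
## package's recursive generator): grow permutations by insertion
perms_by_insertion <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- do.call(rbind, lapply(seq_len(k), function(pos) {
      cbind(out[, seq_len(pos - 1L), drop = FALSE], k,
            out[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    }))
  }
  out
}
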