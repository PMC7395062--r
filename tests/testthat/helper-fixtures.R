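# Shared fixtures for the test suite.

# Noise-free noise model (deterministic expected values).
noise_free <- function(seed = 1L) noise_model(cv = 0, well_scale_sd = 0, seed = seed)

# Minimal synthetic panel covering all four simulated mechanisms. The
# downstream inhibitor is not part of the packaged screening panel, so
# tests that exercise stage-3 inhibition build it here.
mechanism_test_panel <- function(potency = -6) {
  tibble::tibble(
    name = c("ci_like", "cii_like", "ciii_like", "downstream_like"),
    target_complex = factor(c("CI", "CII", "CIII", "CI"), levels = c("CI", "CII", "CIII")),
    cas = NA_character_,
    mol_weight = 300,
    clogp = 3,
    subset_flag = TRUE,
    sim_mechanism = c("inhibitor", "inhibitor", "inhibitor", "downstream_inhibitor"),
    sim_potency_log10M = potency
  )
}

# One-row stage summary scaled from a vehicle reference by per-stage
# flux fractions (optionally perturbed multiplicatively).
stage_summary <- function(flux, vehicle = list(m1_pct = 100, m2_pct = 90, m3_pct = 120),
                          mult = c(1, 1, 1)) {
  list(
    m1_pct = vehicle$m1_pct * flux[1] * mult[1],
    m2_pct = vehicle$m2_pct * flux[2] * mult[2],
    m3_pct = vehicle$m3_pct * flux[3] * mult[3]
  )
}

# Expected per-stage flux fractions at occupancy `a` for each mechanism.
stage_flux_truth <- list(
  CI = function(a) c(1 - a, 1, 1),
  CII = function(a) c(1, 1 - a, 1),
  CIII = function(a) c(1 - a, 1 - a, 1),
  CIV_CV_downstream = function(a) c(1 - a, 1 - a, 1 - a)
)
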