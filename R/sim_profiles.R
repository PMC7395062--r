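# Simulator configuration objects: cell-line respiratory profiles,
# injection schedules and the measurement noise model.

#' Define a cell-line respiratory profile for the trace simulator
#'
#' A phenomenological description of one cell line's bioenergetics on the
#' percent-of-basal-OCR scale. `maximal_ocr_pct` is the FCCP-uncoupled
#' capacity; `nonmito_pct` the rotenone/antimycin-A-resistant floor;
#' `leak_pct` the oligomycin-resistant, non-ATP-coupled portion of basal
#' respiration; the ATP-linked portion is the remainder
#' (`100 - nonmito_pct - leak_pct`).
#'
#' Glycolytic behaviour is captured by `glycolytic_reserve` (maximal
#' fold-increase of ECAR over basal when ATP demand shifts fully to
#' glycolysis), `fccp_ecar_boost` (whether ECAR rises beyond the
#' oligomycin plateau after FCCP), `glucose_rescue` (fraction of ATP
#' demand glycolysis can cover in glucose medium; galactose medium forces
#' this to zero) and `culture_modifier_3d` (scaling of `glucose_rescue`
#' in spheroid culture, where cells become less glycolytic).
#'
#' @param name Profile label.
#' @param maximal_ocr_pct Uncoupled capacity, percent of basal (>= 100).
#' @param nonmito_pct Non-mitochondrial floor, percent of basal.
#' @param leak_pct Proton-leak portion, percent of basal
#'   (`nonmito_pct + leak_pct` must stay below 100).
#' @param glycolytic_reserve Max fold-increase of ECAR over basal (>= 0).
#' @param fccp_ecar_boost Logical; extra ECAR rise after FCCP.
#' @param glucose_rescue Fraction of ATP demand coverable by glycolysis in
#'   glucose medium, in `[0, 1]`.
#' @param culture_modifier_3d Scaling of `glucose_rescue` in 3D spheroid
#'   culture, in `[0, 1]`.
#' @param basal_ocr,basal_ecar Raw-unit basal rates used to place the
#'   simulated traces on instrument-like scales (pmol O2/min, mpH/min).
#' @return A `cell_line_profile` list.
#' @export
cell_line_profile <- function(name,
                              maximal_ocr_pct,
                              nonmito_pct,
                              leak_pct,
                              glycolytic_reserve,
                              fccp_ecar_boost = FALSE,
                              glucose_rescue = 1,
                              culture_modifier_3d = 1,
                              basal_ocr = 100,
                              basal_ecar = 20) {
  if (maximal_ocr_pct < 100) stop_domain("maximal_ocr_pct must be >= 100")
  if (nonmito_pct < 0 || leak_pct < 0 || nonmito_pct + leak_pct >= 100) {
    stop_domain("need nonmito_pct >= 0, leak_pct >= 0 and nonmito_pct + leak_pct < 100")
  }
  if (glycolytic_reserve < 0) stop_domain("glycolytic_reserve must be >= 0")
  if (glucose_rescue < 0 || glucose_rescue > 1) stop_domain("glucose_rescue must be in [0, 1]")
  if (culture_modifier_3d < 0 || culture_modifier_3d > 1) {
    stop_domain("culture_modifier_3d must be in [0, 1]")
  }
  structure(
    list(
      name = name,
      maximal_ocr_pct = maximal_ocr_pct,
      nonmito_pct = nonmito_pct,
      leak_pct = leak_pct,
      glycolytic_reserve = glycolytic_reserve,
      fccp_ecar_boost = isTRUE(fccp_ecar_boost),
      glucose_rescue = glucose_rescue,
      culture_modifier_3d = culture_modifier_3d,
      basal_ocr = basal_ocr,
      basal_ecar = basal_ecar
    ),
    class = "cell_line_profile"
  )
}

#' Built-in cell-line profiles
#'
#' Two reference profiles bracketing the respiratory phenotypes seen in
#' screening practice:
#'
#' * `hepg2_profile()` - a glycolytic hepatoma-like line with low spare
#'   respiratory capacity (maximal OCR 159.4% of basal), full glucose
#'   rescue in 2D glucose culture, no further ECAR rise after FCCP, and a
#'   reduced rescue in 3D spheroids (`culture_modifier_3d = 0.2`,
#'   reflecting the shift toward oxidative metabolism on differentiation).
#' * `rptec_profile()` - an oxidative, differentiated renal
#'   proximal-tubule-like line with high spare capacity (maximal OCR
#'   337.4% of basal), little glycolytic rescue of viability, and a
#'   further ECAR increase after FCCP.
#'
#' @return A `cell_line_profile`.
#' @name builtin_profiles
NULL

#' @rdname builtin_profiles
#' @export
hepg2_profile <- function() {
  cell_line_profile(
    name = "HepG2",
    maximal_ocr_pct = 159.4,
    nonmito_pct = 15,
    leak_pct = 15,
    glycolytic_reserve = 1.5,
    fccp_ecar_boost = FALSE,
    glucose_rescue = 1,
    culture_modifier_3d = 0.2,
    basal_ocr = 80,
    basal_ecar = 25
  )
}

#' @rdname builtin_profiles
#' @export
rptec_profile <- function() {
  cell_line_profile(
    name = "RPTEC/TERT1",
    maximal_ocr_pct = 337.4,
    nonmito_pct = 10,
    leak_pct = 12,
    glycolytic_reserve = 2.5,
    fccp_ecar_boost = TRUE,
    glucose_rescue = 0.1,
    culture_modifier_3d = 1,
    basal_ocr = 120,
    basal_ecar = 15
  )
}

#' Injection schedules for the kinetic assays
#'
#' `mitostress_schedule()` encodes the intact-cell sequence: baseline
#' measurements, test-compound injection (5 measurement cycles), then
#' oligomycin 2 uM, FCCP 2 uM and rotenone/antimycin A 0.5 uM (3 cycles
#' each). `complex_schedule()` encodes the permeabilized-cell sequence:
#' baseline on CI substrates (pyruvate/malate/ADP), test compound,
#' succinate + rotenone, then ascorbate/TMPD + antimycin A (2
#' measurements per stage). Each cycle is a mix-plus-read period; times
#' are cycle midpoints in minutes.
#'
#' @param baseline_cycles Number of pre-injection measurement cycles.
#' @param cycle_minutes Minutes per measurement cycle.
#' @return An `injection_schedule`: a tibble with columns `phase`,
#'   `agent`, `n_cycles`, `cycle_minutes`.
#' @name schedules
NULL

new_schedule <- function(phase, agent, n_cycles, cycle_minutes) {
  if (anyDuplicated(phase)) stop_domain("schedule phase labels must be unique")
  if (any(n_cycles < 1)) stop_domain("each phase needs n_cycles >= 1")
  structure(
    tibble::tibble(
      phase = phase, agent = agent,
      n_cycles = as.integer(n_cycles), cycle_minutes = cycle_minutes
    ),
    class = c("injection_schedule", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname schedules
#' @export
mitostress_schedule <- function(baseline_cycles = 3, cycle_minutes = 6) {
  new_schedule(
    phase = c("baseline", "compound", "oligomycin", "fccp", "rot_aa"),
    agent = c(
      "none", "test compound", "oligomycin 2 uM", "FCCP 2 uM",
      "rotenone/antimycin A 0.5 uM"
    ),
    n_cycles = c(baseline_cycles, 5L, 3L, 3L, 3L),
    cycle_minutes = rep(cycle_minutes, 5)
  )
}

#' @rdname schedules
#' @export
complex_schedule <- function(baseline_cycles = 2, cycle_minutes = 2.5) {
  new_schedule(
    phase = c("baseline", "compound", "succ_rot", "tmpd_aa"),
    agent = c(
      "CI substrates (pyruvate/malate/ADP)", "test compound",
      "succinate 10 mM + rotenone 2 uM",
      "ascorbate 10 mM/TMPD 0.5 mM + antimycin A 2 uM"
    ),
    n_cycles = c(baseline_cycles, 2L, 2L, 2L),
    cycle_minutes = rep(cycle_minutes, 4)
  )
}

# Measurement times (cycle midpoints, minutes) for a whole schedule.
schedule_times <- function(schedule) {
  ends <- cumsum(rep(schedule$cycle_minutes, schedule$n_cycles))
  ends - rep(schedule$cycle_minutes, schedule$n_cycles) / 2
}

#' Measurement noise model
#'
#' Multiplicative lognormal noise applied per measurement (coefficient of
#' variation `cv`) combined with one lognormal scale factor per well
#' (`well_scale_sd`), emulating well-to-well seeding differences. Both
#' default to values producing the visual spread typical of kinetic
#' plate data; `cv = 0, well_scale_sd = 0` gives noise-free traces.
#'
#' @param cv Per-measurement coefficient of variation (>= 0).
#' @param well_scale_sd Per-well lognormal scale spread (>= 0).
#' @param seed Integer seed; all simulator randomness is reproducible
#'   given the seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(cv = 0.03, well_scale_sd = 0.05, seed = 1L) {
  if (cv < 0 || well_scale_sd < 0) stop_domain("cv and well_scale_sd must be >= 0")
  structure(
    list(cv = cv, well_scale_sd = well_scale_sd, seed = as.integer(seed)),
    class = "noise_model"
  )
}
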