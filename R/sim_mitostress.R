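# Intact-cell mitostress trace simulator.
#
# The flux model is phenomenological: per-phase expected OCR on the
# percent-of-basal scale as a function of target occupancy, cell-line
# profile and compound mechanism. It is just rich enough to reproduce the
# qualitative patterns of ETC-inhibitor screening (dose-graded basal and
# maximal inhibition, intact-cell CII masking, protonophore uncoupling,
# compensatory ECAR rise), not a mechanistic proton-motive-force model.

#' Hill occupancy fraction
#'
#' Fraction of target bound (or effect saturation) at a given
#' concentration: `conc^slope / (ic50^slope + conc^slope)`. The simulator
#' uses the same sigmoid as occupancy that the analysis side fits as a
#' four-parameter Hill curve.
#'
#' @param conc Concentration(s), molar (>= 0).
#' @param ic50 Half-maximal concentration, molar (> 0).
#' @param slope Hill slope (> 0).
#' @return Occupancy fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' hill_fraction(1e-6, 1e-6, 1)  # 0.5
hill_fraction <- function(conc, ic50, slope = 1) {
  if (any(conc < 0)) stop_domain("conc must be >= 0")
  if (ic50 <= 0) stop_domain("ic50 must be > 0")
  if (slope <= 0) stop_domain("slope must be > 0")
  # work in log space to avoid overflow at extreme conc/ic50 ratios
  r <- (conc / ic50)^slope
  r / (1 + r)
}

# Resolve a compound record to (mechanism, ic50, slope) for the simulator.
sim_mechanism_of <- function(record, default_slope = 1) {
  mech <- record$sim_mechanism %||% "inactive"
  if (is.na(mech)) mech <- "inactive"
  ok <- c("inhibitor", "uncoupler", "downstream_inhibitor", "inactive")
  if (!mech %in% ok) {
    stop_validation(paste0("unknown sim_mechanism: ", mech))
  }
  pot <- record$sim_potency_log10M %||% NA_real_
  list(
    mechanism = mech,
    target = as.character(record$target_complex %||% NA_character_),
    ic50 = if (is.na(pot)) Inf else 10^pot,
    slope = default_slope
  )
}

# Expected noise-free OCR (percent of basal) for every mitostress phase.
# `a` is occupancy; `cii_masking` in [0,1]: 1 = CII inhibition fully
# masked by CI-fed electron flow in intact cells.
mitostress_expected_ocr <- function(phase, mech, a, profile, cii_masking = 1) {
  maximal <- profile$maximal_ocr_pct
  nonmito <- profile$nonmito_pct
  leak <- profile$leak_pct
  u <- if (mech$mechanism == "uncoupler") a else 0
  etc_capacity <- switch(mech$mechanism,
    inhibitor = if (identical(mech$target, "CII")) 1 - (1 - cii_masking) * a else 1 - a,
    downstream_inhibitor = 1 - a,
    uncoupler = 1,
    inactive = 1
  )
  switch(phase,
    baseline = 100,
    compound = if (mech$mechanism == "uncoupler") {
      min(maximal, 100 + (maximal - 100) * u)
    } else {
      nonmito + (100 - nonmito) * etc_capacity
    },
    oligomycin = nonmito + leak * etc_capacity + (maximal - 100) * u,
    fccp = nonmito + (maximal - nonmito) * etc_capacity,
    rot_aa = nonmito,
    stop_domain(paste0("unknown mitostress phase: ", phase))
  )
}

# Expected ECAR as a fraction of the glycolytic range (0 = basal,
# 1 = oligomycin plateau). Compensation model: ECAR rises with the
# fraction of ATP-linked respiration lost, saturates at the oligomycin
# plateau, and exceeds it after FCCP only for lines with an FCCP ECAR
# boost.
mitostress_expected_ecar_frac <- function(phase, mech, a, profile,
                                          cii_masking = 1, fccp_boost = 0.25) {
  etc_capacity <- switch(mech$mechanism,
    inhibitor = if (identical(mech$target, "CII")) 1 - (1 - cii_masking) * a else 1 - a,
    downstream_inhibitor = 1 - a,
    uncoupler = 1,
    inactive = 1
  )
  atp_loss <- if (mech$mechanism == "uncoupler") a else 1 - etc_capacity
  boost <- if (profile$fccp_ecar_boost) fccp_boost else 0
  switch(phase,
    baseline = 0,
    compound = min(1, atp_loss),
    oligomycin = 1,
    fccp = 1 + boost,
    rot_aa = 1,
    stop_domain(paste0("unknown mitostress phase: ", phase))
  )
}

# 384-well names in row-major order: A1..A24, B1.., up to P24.
well_names <- function(n) {
  if (n > 384) stop_domain("plate layout exceeds 384 wells")
  rows <- rep(LETTERS[1:16], each = 24)
  cols <- rep(1:24, times = 16)
  paste0(rows, cols)[seq_len(n)]
}

# Shared trace assembly: given a per-well design (compound, conc, mech)
# and a function expected(phase_label) -> list(ocr, ecar), emit the long
# trace tibble with noise applied.
assemble_traces <- function(design, schedule, noise, plate_id, expected_fun) {
  times <- schedule_times(schedule)
  phase_per_meas <- rep(schedule$phase, schedule$n_cycles)
  n_meas <- length(times)
  with_seed(noise$seed, {
    out <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      exp_i <- expected_fun(design[i, ])
      scale_i <- rlnorm_cv(1, noise$well_scale_sd)
      ocr <- unname(exp_i$ocr[match(phase_per_meas, schedule$phase)]) *
        scale_i * rlnorm_cv(n_meas, noise$cv)
      ecar <- unname(exp_i$ecar[match(phase_per_meas, schedule$phase)]) *
        scale_i * rlnorm_cv(n_meas, noise$cv)
      out[[i]] <- tibble::tibble(
        plate_id = plate_id,
        well = design$well[i],
        compound = design$compound[i],
        conc_M = design$conc_M[i],
        phase = phase_per_meas,
        time_min = times,
        ocr = ocr,
        ecar = ecar
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate an intact-cell mitostress plate
#'
#' Generates long-format kinetic OCR/ECAR traces for every panel compound
#' at every ladder concentration, plus vehicle wells, under the
#' sequential-injection mitostress protocol (test compound, oligomycin,
#' FCCP, rotenone/antimycin A). Noise-free expected values follow the
#' package's flux model; output is deterministic given the noise seed.
#'
#' Mechanism handling: CI/CIII inhibitors (and downstream inhibitors)
#' reduce ETC capacity by their occupancy; CII inhibitors are masked in
#' intact cells (`cii_masking = 1`, i.e. no OCR effect) because CI-fed
#' electron flow bypasses succinate dehydrogenase; protonophore
#' uncouplers raise basal OCR toward the uncoupled maximum and resist
#' oligomycin suppression; inactive compounds track vehicle.
#'
#' @param panel Tibble of compound records as from [load_panel()].
#' @param series `concentration_series` of test concentrations.
#' @param profile `cell_line_profile`.
#' @param schedule `injection_schedule`; must contain phases `baseline`,
#'   `compound`, `oligomycin`, `fccp`, `rot_aa`.
#' @param noise `noise_model`.
#' @param n_vehicle Number of vehicle (0.1% DMSO) wells.
#' @param cii_masking Degree of intact-cell CII masking in `[0, 1]`
#'   (1 = fully masked; lower values expose partial CII inhibition for
#'   sensitivity analyses).
#' @param sim_hill_slope Hill slope of the simulated occupancy sigmoid.
#' @param plate_id Plate label carried through the output.
#' @return Long tibble with columns `plate_id`, `well`, `compound`,
#'   `conc_M` (0 for vehicle), `phase`, `time_min`, `ocr`, `ecar`.
#' @export
#' @examples
#' panel <- load_panel()[1:2, ]
#' tr <- simulate_mitostress_plate(panel, make_dilution_series(1e-5, 5, 4),
#'                                 hepg2_profile(), noise = noise_model(0, 0))
#' head(tr)
simulate_mitostress_plate <- function(panel,
                                      series,
                                      profile,
                                      schedule = mitostress_schedule(),
                                      noise = noise_model(),
                                      n_vehicle = 6,
                                      cii_masking = 1,
                                      sim_hill_slope = 1,
                                      plate_id = "mitostress_1") {
  required <- c("baseline", "compound", "oligomycin", "fccp", "rot_aa")
  missing <- setdiff(required, schedule$phase)
  if (length(missing) > 0) {
    stop_domain(paste0("schedule lacks phase(s): ", paste(missing, collapse = ", ")))
  }
  design <- tidyr::expand_grid(
    compound = panel$name,
    conc_M = series$values
  )
  design <- dplyr::bind_rows(
    design,
    tibble::tibble(compound = "DMSO", conc_M = rep(0, n_vehicle))
  )
  design$well <- well_names(nrow(design))

  mechs <- lapply(seq_len(nrow(panel)), function(i) {
    sim_mechanism_of(as.list(panel[i, ]), default_slope = sim_hill_slope)
  })
  names(mechs) <- panel$name
  vehicle_mech <- list(mechanism = "inactive", target = NA_character_, ic50 = Inf, slope = 1)

  expected_fun <- function(row) {
    mech <- if (row$compound == "DMSO") vehicle_mech else mechs[[row$compound]]
    a <- if (is.infinite(mech$ic50)) 0 else hill_fraction(row$conc_M, mech$ic50, mech$slope)
    pct <- vapply(schedule$phase, mitostress_expected_ocr, numeric(1),
      mech = mech, a = a, profile = profile, cii_masking = cii_masking
    )
    frac <- vapply(schedule$phase, mitostress_expected_ecar_frac, numeric(1),
      mech = mech, a = a, profile = profile, cii_masking = cii_masking
    )
    list(
      ocr = profile$basal_ocr * pct / 100,
      ecar = profile$basal_ecar * (1 + profile$glycolytic_reserve * frac)
    )
  }
  assemble_traces(design, schedule, noise, plate_id, expected_fun)
}
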