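# Permeabilized-cell complex-assay trace simulator.
#
# Electron flow through the chain is modelled as a product of per-complex
# capacity factors g(X) = 1 - occupancy for a compound targeting X, else 1.
# Stage 1 (CI substrates): flux ~ g(CI) g(CIII) g(CIV).
# Stage 2 (succinate + rotenone): flux ~ g(CII) g(CIII) g(CIV).
# Stage 3 (ascorbate/TMPD + antimycin A): flux ~ g(CIV).
# A downstream inhibitor acts on g(CIV); a protonophore uncoupler has no
# effect in this ADP-stimulated permeabilized preparation.

complex_stage_flux <- function(mech, a) {
  g <- c(CI = 1, CII = 1, CIII = 1, CIV = 1)
  if (mech$mechanism == "inhibitor") {
    if (!mech$target %in% names(g)) {
      stop_validation(paste0("unknown target complex: ", mech$target))
    }
    g[mech$target] <- 1 - a
  } else if (mech$mechanism == "downstream_inhibitor") {
    g["CIV"] <- 1 - a
  } else if (!mech$mechanism %in% c("uncoupler", "inactive")) {
    stop_validation(paste0("unknown mechanism: ", mech$mechanism))
  }
  c(
    stage1 = unname(g["CI"] * g["CIII"] * g["CIV"]),
    stage2 = unname(g["CII"] * g["CIII"] * g["CIV"]),
    stage3 = unname(g["CIV"])
  )
}

#' Simulate a permeabilized-cell complex-assay plate
#'
#' Generates kinetic OCR traces for the three-stage ETC-localization
#' protocol: cells permeabilized on complex-I substrates
#' (pyruvate/malate/ADP), then injected with the test compound (stage 1),
#' succinate + rotenone (stage 2, blocks CI while feeding CII) and
#' ascorbate/TMPD + antimycin A (stage 3, blocks CIII while feeding CIV).
#' The OCR pattern across stages localizes the inhibited complex.
#'
#' @param panel Tibble of compound records as from [load_panel()].
#' @param series `concentration_series` of test concentrations (the
#'   permeabilized assay typically uses the wider
#'   `dilution_preset("permeabilized_extended")` ladder).
#' @param noise `noise_model`.
#' @param stage_capacities Named numeric vector giving vehicle-well OCR of
#'   each stage relative to the CI-substrate baseline
#'   (`c(stage1 =, stage2 =, stage3 =)`); substrate-dependent, order 1.
#' @param schedule `injection_schedule` with phases `baseline`,
#'   `compound`, `succ_rot`, `tmpd_aa`.
#' @param n_vehicle Number of vehicle wells.
#' @param sim_hill_slope Hill slope of the simulated occupancy sigmoid.
#' @param plate_id Plate label.
#' @return Long trace tibble as for [simulate_mitostress_plate()]
#'   (ECAR column present but constant: the mitochondrial assay buffer
#'   has no glycolytic component).
#' @export
simulate_complex_assay_plate <- function(panel,
                                         series = dilution_preset("permeabilized_extended"),
                                         noise = noise_model(),
                                         stage_capacities = c(stage1 = 1, stage2 = 0.9, stage3 = 1.2),
                                         schedule = complex_schedule(),
                                         n_vehicle = 6,
                                         sim_hill_slope = 1,
                                         plate_id = "complex_1") {
  required <- c("baseline", "compound", "succ_rot", "tmpd_aa")
  missing <- setdiff(required, schedule$phase)
  if (length(missing) > 0) {
    stop_domain(paste0("schedule lacks phase(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(c("stage1", "stage2", "stage3") %in% names(stage_capacities))) {
    stop_domain("stage_capacities needs named entries stage1, stage2, stage3")
  }
  design <- tidyr::expand_grid(compound = panel$name, conc_M = series$values)
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
  baseline_ocr <- 150 # pmol O2/min; ADP-stimulated CI-substrate respiration

  expected_fun <- function(row) {
    mech <- if (row$compound == "DMSO") vehicle_mech else mechs[[row$compound]]
    a <- if (is.infinite(mech$ic50)) 0 else hill_fraction(row$conc_M, mech$ic50, mech$slope)
    flux <- complex_stage_flux(mech, a)
    ocr_by_phase <- c(
      baseline = 1,
      compound = stage_capacities[["stage1"]] * flux[["stage1"]],
      succ_rot = stage_capacities[["stage2"]] * flux[["stage2"]],
      tmpd_aa = stage_capacities[["stage3"]] * flux[["stage3"]]
    ) * baseline_ocr
    list(
      ocr = ocr_by_phase[schedule$phase],
      ecar = rep(2, nrow(schedule)) # buffer acidification only
    )
  }
  assemble_traces(design, schedule, noise, plate_id, expected_fun)
}
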