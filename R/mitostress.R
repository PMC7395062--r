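# Mitostress parameter decomposition: the six respiration quantities
# readable from a sequential-injection trace, plus uncoupler detection.

#' Decompose a normalized mitostress trace into respiration parameters
#'
#' From one well's baseline-normalized trace, extracts:
#' * `basal_pct` - 100 by construction;
#' * `compound_basal_pct` - respiration after test-compound injection
#'   (mean of the last 2 of its 5 cycles, capturing equilibrated
#'   inhibition);
#' * `oligo_pct` - oligomycin-phase OCR (minimum of its cycles);
#' * `atp_linked_pct` - `compound_basal_pct - oligo_pct`, the oxygen
#'   used for ATP production;
#' * `maximal_pct` - FCCP-phase maximum, the uncoupled capacity;
#' * `nonmito_pct` - rotenone/antimycin-A floor (mean of its cycles);
#' * `proton_leak_pct` - `oligo_pct - nonmito_pct`.
#'
#' On vehicle wells the identity
#' `basal = atp_linked + proton_leak + nonmito` holds exactly in the
#' noise-free limit.
#'
#' @param trace One well's trace tibble on the percent-of-baseline scale
#'   (see [normalize_to_baseline()]); may carry an `ecar_range_pct`
#'   column from [normalize_ecar_range()].
#' @param vehicle_maximal_pct Optional vehicle maximal OCR (percent of
#'   baseline) used to fill `maximal_vs_control_pct`.
#' @param rise_threshold,oligo_resistance Passed to [detect_uncoupling()].
#' @return One-row tibble of mitostress parameters, including the
#'   `uncoupling` flag and, when available, `ecar_compound_pct_range`.
#' @export
decompose_mitostress <- function(trace, vehicle_maximal_pct = NA_real_,
                                 rise_threshold = 115, oligo_resistance = 100) {
  needed <- c("baseline", "compound", "oligomycin", "fccp", "rot_aa")
  for (ph in needed) {
    if (!ph %in% trace$phase) {
      stop_validation(paste0("trace is missing phase: ", ph))
    }
  }
  if (dplyr::n_distinct(trace$well) != 1) {
    stop_validation("decompose_mitostress expects a single well's trace")
  }
  phase_vals <- function(ph, col = "ocr") trace[[col]][trace$phase == ph]
  comp <- phase_vals("compound")
  compound_basal <- mean(tail(comp, 2))
  oligo <- min(phase_vals("oligomycin"))
  maximal <- max(phase_vals("fccp"))
  nonmito <- mean(phase_vals("rot_aa"))
  ecar_range <- if ("ecar_range_pct" %in% names(trace)) {
    mean(tail(phase_vals("compound", "ecar_range_pct"), 2))
  } else {
    NA_real_
  }
  params <- tibble::tibble(
    plate_id = trace$plate_id[1],
    well = trace$well[1],
    compound = trace$compound[1],
    conc_M = trace$conc_M[1],
    basal_pct = 100,
    compound_basal_pct = compound_basal,
    oligo_pct = oligo,
    atp_linked_pct = compound_basal - oligo,
    maximal_pct = maximal,
    maximal_vs_control_pct = if (is.na(vehicle_maximal_pct)) {
      NA_real_
    } else {
      normalize_maximal_to_control(maximal, vehicle_maximal_pct)
    },
    nonmito_pct = nonmito,
    proton_leak_pct = oligo - nonmito,
    ecar_compound_pct_range = ecar_range
  )
  params$uncoupling <- detect_uncoupling(params, rise_threshold, oligo_resistance)
  params
}

#' Flag protonophore-like uncoupling
#'
#' A well is flagged as uncoupled when the test compound raised basal
#' respiration (`compound_basal_pct >= rise_threshold`) and oligomycin
#' failed to suppress it (`oligo_pct >= oligo_resistance`): respiration
#' that is elevated and no longer coupled to ATP synthesis is the
#' signature of proton-gradient dissipation. Default thresholds are
#' deliberately permissive (115% rise, oligomycin-phase OCR still at or
#' above baseline); a genuine protonophore near saturation shows a far
#' larger signal.
#'
#' @param params Parameter row(s) from [decompose_mitostress()].
#' @param rise_threshold Basal-rise threshold, percent of baseline.
#' @param oligo_resistance Oligomycin-phase floor, percent of baseline.
#' @return Logical vector.
#' @export
detect_uncoupling <- function(params, rise_threshold = 115, oligo_resistance = 100) {
  params$compound_basal_pct >= rise_threshold & params$oligo_pct >= oligo_resistance
}

#' Mitostress parameters for every well of a plate
#'
#' Applies [normalize_ecar_range()], [normalize_to_baseline()] and
#' [decompose_mitostress()] across a raw trace table, filling
#' `maximal_vs_control_pct` from the plate's vehicle wells.
#'
#' @param traces Raw long trace tibble (as simulated or read from file).
#' @return Tibble of per-well parameter rows.
#' @export
decompose_plate <- function(traces) {
  traces <- normalize_ecar_range(traces)
  norm <- normalize_to_baseline(traces)
  wells <- dplyr::group_split(norm, .data$plate_id, .data$well)
  params <- dplyr::bind_rows(lapply(wells, decompose_mitostress))
  veh <- dplyr::filter(params, .data$conc_M == 0)
  if (nrow(veh) == 0) stop_validation("plate has no vehicle wells")
  vehicle_maximal <- mean(veh$maximal_pct)
  params$maximal_vs_control_pct <- normalize_maximal_to_control(
    params$maximal_pct, vehicle_maximal
  )
  params
}

#' Dose-response curves from a mitostress plate
#'
#' Aggregates per-well mitostress parameters into three per-compound
#' concentration-response curves ready for potency fitting:
#' `ocr_basal` (compound-phase OCR, percent of own baseline),
#' `ocr_maximal` (FCCP maximum, percent of vehicle maximal) and
#' `ecar` (compound-phase ECAR, percent of glycolytic range).
#'
#' @param traces Raw long trace tibble containing vehicle wells.
#' @return Long tibble: `compound`, `endpoint`, `conc_M`, `response`,
#'   `sd`, `n`, sorted by concentration within compound/endpoint.
#' @export
potency_curves_from_plate <- function(traces) {
  params <- decompose_plate(traces)
  treated <- dplyr::filter(params, .data$conc_M > 0)
  n_conc <- treated |>
    dplyr::summarise(k = dplyr::n_distinct(.data$conc_M), .by = "compound")
  if (any(n_conc$k < 2)) {
    stop_validation("need >= 2 concentrations per compound for dose-response curves")
  }
  long <- treated |>
    dplyr::select(dplyr::all_of(c(
      "compound", "conc_M",
      ocr_basal = "compound_basal_pct",
      ocr_maximal = "maximal_vs_control_pct",
      ecar = "ecar_compound_pct_range"
    ))) |>
    tidyr::pivot_longer(
      cols = c("ocr_basal", "ocr_maximal", "ecar"),
      names_to = "endpoint", values_to = "value"
    )
  long |>
    dplyr::summarise(
      response = mean(.data$value),
      sd = stats::sd(.data$value),
      n = dplyr::n(),
      .by = c("compound", "endpoint", "conc_M")
    ) |>
    dplyr::arrange(.data$compound, .data$endpoint, .data$conc_M)
}
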