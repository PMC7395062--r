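# Permeabilized-cell complex assay: stage summaries and the case table
# assigning ETC complex specificity from the three-stage OCR pattern.

#' Summarize a three-stage complex-assay trace
#'
#' Stage summaries use the second OCR measurement after each injection
#' (compound; succinate + rotenone; ascorbate/TMPD + antimycin A),
#' normalised to the mean of the pre-compound baseline measurements.
#'
#' @param trace One well's raw trace tibble with phases `baseline`,
#'   `compound`, `succ_rot`, `tmpd_aa`, each post-compound stage holding
#'   at least 2 measurements.
#' @return One-row tibble: `plate_id`, `well`, `compound`, `conc_M`,
#'   `m1_pct`, `m2_pct`, `m3_pct` (percent of baseline).
#' @export
summarize_stages <- function(trace) {
  stages <- c(compound = "m1_pct", succ_rot = "m2_pct", tmpd_aa = "m3_pct")
  if (!"baseline" %in% trace$phase) stop_validation("trace lacks baseline phase")
  trace <- dplyr::arrange(trace, .data$time_min)
  base <- mean(trace$ocr[trace$phase == "baseline"])
  if (base <= 0) stop_validation("degenerate well: baseline OCR <= 0")
  out <- tibble::tibble(
    plate_id = trace$plate_id[1],
    well = trace$well[1],
    compound = trace$compound[1],
    conc_M = trace$conc_M[1]
  )
  for (ph in names(stages)) {
    vals <- trace$ocr[trace$phase == ph]
    if (length(vals) < 2) {
      stop_validation(paste0("stage ", ph, " has fewer than 2 measurements"))
    }
    out[[stages[[ph]]]] <- vals[2] / base * 100
  }
  out
}

#' Assign ETC complex specificity from stage summaries
#'
#' Implements the five-case decision table for the three-stage
#' permeabilized assay. Relative to matched vehicle references, stage k
#' counts as inhibited when `m_k < inhibition_frac * vehicle_m_k` and as
#' rescued when `m_k >= rescue_frac * vehicle_m_k`:
#'
#' * no stage inhibited - `no_inhibition` (case 1);
#' * stage 1 inhibited, rescued by succinate - `CI` (case 2);
#' * stage 1 spared but stage 2 inhibited, rescued by TMPD - `CII`
#'   (case 3; in intact cells this pattern is invisible, hence "masked"
#'   CII inhibitors);
#' * stages 1 and 2 inhibited, rescued by TMPD - `CIII` (case 4);
#' * stages 1 and 2 inhibited, TMPD rescue only partial (stage-3 ratio
#'   inside `partial_band`) - `CIII_partial`;
#' * stage 3 inhibited - `CIV_CV_downstream` (case 5; the assay cannot
#'   separate CIV from CV);
#' * anything else - `ambiguous`.
#'
#' The classification depends only on the ratios `m_k / vehicle_m_k`,
#' so it is invariant to common rescaling of all stage values.
#'
#' @param s One-row stage summary (from [summarize_stages()]).
#' @param vehicle One-row vehicle reference with the same `m*_pct`
#'   columns (plate vehicle means); all entries must be positive.
#' @param inhibition_frac Ratio below which a stage counts as inhibited.
#' @param rescue_frac Ratio at or above which a stage counts as rescued.
#' @param partial_band Two-element ratio band for partial TMPD rescue.
#' @return A list with `call` (character) and `thresholds_used`.
#' @export
classify_complex <- function(s, vehicle,
                             inhibition_frac = 0.7,
                             rescue_frac = 0.7,
                             partial_band = c(0.4, 0.7)) {
  v <- c(vehicle$m1_pct, vehicle$m2_pct, vehicle$m3_pct)
  if (any(v <= 0)) stop_validation("vehicle stage references must be positive")
  m <- c(s$m1_pct, s$m2_pct, s$m3_pct)
  ratio <- m / v
  inhibited <- ratio < inhibition_frac
  rescued <- ratio >= rescue_frac
  partial3 <- ratio[3] >= partial_band[1] & ratio[3] < partial_band[2]
  call <- if (!any(inhibited)) {
    "no_inhibition"
  } else if (inhibited[1] && rescued[2]) {
    "CI"
  } else if (!inhibited[1] && inhibited[2] && rescued[3]) {
    "CII"
  } else if (inhibited[1] && inhibited[2] && rescued[3]) {
    "CIII"
  } else if (inhibited[1] && inhibited[2] && partial3) {
    "CIII_partial"
  } else if (inhibited[3]) {
    "CIV_CV_downstream"
  } else {
    "ambiguous"
  }
  list(
    call = call,
    thresholds_used = list(
      inhibition_frac = inhibition_frac,
      rescue_frac = rescue_frac,
      partial_band = partial_band
    )
  )
}

#' Stage summaries and per-concentration calls for a whole plate
#'
#' Summarizes every well, builds plate vehicle references (mean stage
#' values across vehicle wells) and classifies every treated well.
#'
#' @param traces Raw complex-assay trace tibble with vehicle wells.
#' @inheritParams classify_complex
#' @return Tibble of per-well summaries with `call` and vehicle
#'   reference columns `vehicle_m1_pct` .. `vehicle_m3_pct`.
#' @export
complex_calls_from_plate <- function(traces,
                                     inhibition_frac = 0.7,
                                     rescue_frac = 0.7,
                                     partial_band = c(0.4, 0.7)) {
  wells <- dplyr::group_split(traces, .data$plate_id, .data$well)
  summaries <- dplyr::bind_rows(lapply(wells, summarize_stages))
  veh <- dplyr::filter(summaries, .data$conc_M == 0)
  if (nrow(veh) == 0) stop_validation("plate has no vehicle wells")
  vehicle <- tibble::tibble(
    m1_pct = mean(veh$m1_pct),
    m2_pct = mean(veh$m2_pct),
    m3_pct = mean(veh$m3_pct)
  )
  summaries$vehicle_m1_pct <- vehicle$m1_pct
  summaries$vehicle_m2_pct <- vehicle$m2_pct
  summaries$vehicle_m3_pct <- vehicle$m3_pct
  summaries$call <- vapply(seq_len(nrow(summaries)), function(i) {
    classify_complex(summaries[i, ], vehicle,
      inhibition_frac = inhibition_frac,
      rescue_frac = rescue_frac,
      partial_band = partial_band
    )$call
  }, character(1))
  summaries
}

#' Per-compound complex call across a concentration ladder
#'
#' Collapses per-concentration calls into one call per compound. With
#' `dose_rule = "consensus"` (default) the modal call among
#' concentrations showing any inhibition wins, ties resolved toward the
#' higher dose; `"lowest"` takes the call at the lowest concentration
#' reaching inhibition. Consensus is robust to single borderline doses
#' where measurement noise can flip one stage across the inhibition
#' threshold.
#'
#' @param calls Per-well call tibble from [complex_calls_from_plate()].
#' @param dose_rule `"consensus"` or `"lowest"`.
#' @return Tibble: `compound`, `call`, `call_conc_M` (lowest
#'   concentration showing inhibition, NA when none).
#' @export
complex_call_per_compound <- function(calls, dose_rule = c("consensus", "lowest")) {
  dose_rule <- match.arg(dose_rule)
  treated <- dplyr::filter(calls, .data$conc_M > 0)
  one <- function(df) {
    df <- dplyr::arrange(df, .data$conc_M)
    active <- df[!df$call %in% c("no_inhibition", "ambiguous"), ]
    if (nrow(active) == 0) {
      call <- if (any(df$call == "ambiguous")) "ambiguous" else "no_inhibition"
      return(tibble::tibble(call = call, call_conc_M = NA_real_))
    }
    call <- if (dose_rule == "lowest") {
      active$call[1]
    } else {
      counts <- table(active$call)
      top <- names(counts)[counts == max(counts)]
      if (length(top) == 1) top else {
        # tie: prefer the call observed at the highest dose
        rev(active$call)[which(rev(active$call) %in% top)[1]]
      }
    }
    tibble::tibble(call = call, call_conc_M = min(active$conc_M))
  }
  treated |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Stage-attributed potencies from complex-assay summaries
#'
#' Fits a censored inhibition curve to each stage's response ladder
#' (stage value as percent of vehicle reference vs concentration) and
#' reports stage-attributed potencies: stage 1 probes CI, stage 2
#' CII/CIII, stage 3 CIV (and downstream). Flat stages render `"NR"`;
#' stages already fully suppressed at the lowest tested dose censor to
#' `"< log10(lowest)"`.
#'
#' @param calls Per-well summary tibble from
#'   [complex_calls_from_plate()] for one or more compounds.
#' @param no_response_max_effect Percent effect below which a stage is
#'   reported as no-response.
#' @return Tibble: `compound`, `stage` (`CI`, `CII/CIII`, `CIV`),
#'   `log10_potency`, `censored`, `display`.
#' @export
complex_potency <- function(calls, no_response_max_effect = 20) {
  treated <- dplyr::filter(calls, .data$conc_M > 0)
  stages <- c(CI = "m1_pct", `CII/CIII` = "m2_pct", CIV = "m3_pct")
  refs <- c(CI = "vehicle_m1_pct", `CII/CIII` = "vehicle_m2_pct", CIV = "vehicle_m3_pct")
  out <- list()
  for (cmpd in unique(treated$compound)) {
    df <- dplyr::filter(treated, .data$compound == cmpd)
    if (dplyr::n_distinct(df$conc_M) < 4) {
      stop_validation("need >= 4 concentrations for stage-wise potency fitting")
    }
    for (st in names(stages)) {
      curve <- df |>
        dplyr::summarise(
          response = mean(.data[[stages[[st]]]] / .data[[refs[[st]]]] * 100),
          .by = "conc_M"
        ) |>
        dplyr::arrange(.data$conc_M)
      fit <- fit_hill4(curve$conc_M, curve$response, direction = "decreasing")
      pot <- ic50_from_fit(fit, max(curve$conc_M),
        no_response_max_effect = no_response_max_effect,
        lowest_tested = min(curve$conc_M)
      )
      out[[length(out) + 1]] <- tibble::tibble(
        compound = cmpd, stage = st,
        log10_potency = pot$value, censored = pot$censored, display = pot$display
      )
    }
  }
  dplyr::bind_rows(out)
}
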