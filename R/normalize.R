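# The normalization ledger. Every transformation here is affine and
# order-preserving, and each normalized curve records which anchor set
# its scale (vehicle mean, non-effective-concentration mean, own
# baseline, or the plate's glycolytic range).

#' Construct a normalized dose-response curve
#'
#' Container for a per-compound concentration-response series on a
#' percent scale, carrying anchor provenance.
#'
#' @param conc Ascending molar concentrations.
#' @param response Responses (percent scale).
#' @param sd Per-concentration SDs (percent).
#' @param n Per-concentration replicate counts.
#' @param anchor One of `vehicle`, `non_effective_mean`, `baseline`,
#'   `glycolytic_range`.
#' @param anchor_info Free-text provenance.
#' @return A `normalized_curve` tibble with attributes `anchor` and
#'   `anchor_info`.
#' @export
normalized_curve <- function(conc, response, sd = rep(NA_real_, length(conc)),
                             n = rep(1L, length(conc)),
                             anchor = c("vehicle", "non_effective_mean", "baseline", "glycolytic_range"),
                             anchor_info = "") {
  anchor <- match.arg(anchor)
  if (length(conc) != length(response) || length(conc) != length(sd) ||
      length(conc) != length(n)) {
    stop_validation("conc, response, sd and n must have equal lengths")
  }
  if (is.unsorted(conc, strictly = TRUE)) {
    stop_validation("concentrations must be strictly ascending")
  }
  out <- tibble::tibble(conc = conc, response = response, sd = sd, n = as.integer(n))
  attr(out, "anchor") <- anchor
  attr(out, "anchor_info") <- anchor_info
  class(out) <- c("normalized_curve", class(out))
  out
}

#' Normalize a kinetic trace to its own pre-injection baseline
#'
#' Rescales each well's OCR (and ECAR) so the mean of its baseline-phase
#' measurements maps to 100%; every later phase is scaled by the same
#' factor.
#'
#' @param traces Long trace tibble (raw instrument units).
#' @return The trace tibble with `ocr` and `ecar` on the
#'   percent-of-own-baseline scale.
#' @export
normalize_to_baseline <- function(traces) {
  if (!"baseline" %in% traces$phase) {
    stop_validation("trace has no baseline-phase measurements")
  }
  base <- traces |>
    dplyr::filter(.data$phase == "baseline") |>
    dplyr::summarise(
      base_ocr = mean(.data$ocr),
      base_ecar = mean(.data$ecar),
      .by = c("plate_id", "well")
    )
  if (any(base$base_ocr <= 0) || any(base$base_ecar <= 0)) {
    stop_validation("degenerate well: baseline OCR/ECAR mean is zero or negative")
  }
  missing_base <- dplyr::anti_join(
    dplyr::distinct(traces, .data$plate_id, .data$well), base,
    by = c("plate_id", "well")
  )
  if (nrow(missing_base) > 0) {
    stop_validation("some wells lack baseline-phase measurements")
  }
  traces |>
    dplyr::left_join(base, by = c("plate_id", "well")) |>
    dplyr::mutate(
      ocr = .data$ocr / .data$base_ocr * 100,
      ecar = .data$ecar / .data$base_ecar * 100
    ) |>
    dplyr::select(-dplyr::all_of(c("base_ocr", "base_ecar")))
}

#' Normalize values to vehicle control
#'
#' Expresses responses as percent of the vehicle (0.1% DMSO) mean.
#'
#' @param values Numeric responses.
#' @param vehicle_values Numeric vehicle-well responses (>= 1 value).
#' @return `values / mean(vehicle_values) * 100`.
#' @export
normalize_to_vehicle <- function(values, vehicle_values) {
  if (length(vehicle_values) < 1 || all(is.na(vehicle_values))) {
    stop_validation("no vehicle values supplied")
  }
  m <- mean(vehicle_values, na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop_validation("vehicle mean is zero or non-finite")
  values / m * 100
}

#' Re-anchor a curve to its non-effective concentrations
#'
#' Second-pass normalization: the low-concentration prefix of a
#' percent-of-vehicle curve that is both statistically non-significant
#' and within `delta` percent of control is taken as the true 100%
#' anchor (plate-position and handling offsets make the vehicle mean a
#' noisier anchor than the compound's own flat region). If the prefix
#' holds at least `k_min` concentrations the whole curve is rescaled so
#' the prefix mean maps to 100%; otherwise the curve is returned
#' unchanged with a `no_noneffective_prefix` flag. The operation is
#' idempotent.
#'
#' @param curve A `normalized_curve` on the percent-of-vehicle scale.
#' @param k_min Minimum prefix size (default 2).
#' @param delta Tolerance around 100% defining "non-effective" (percent).
#' @param signif Logical vector, one per concentration: TRUE where the
#'   response differs significantly from control (e.g. Dunnett flags).
#' @return A `normalized_curve`; attribute `anchor` becomes
#'   `non_effective_mean` on success, and attribute `flag` records the
#'   fallback.
#' @export
renormalize_to_noneffective <- function(curve, k_min = 2, delta = 10, signif = NULL) {
  if (is.null(signif)) signif <- rep(FALSE, nrow(curve))
  if (length(signif) != nrow(curve)) {
    stop_validation("signif must have one flag per concentration")
  }
  ok <- !signif & abs(curve$response - 100) <= delta
  prefix_len <- if (all(ok)) length(ok) else which(!ok)[1] - 1
  if (prefix_len < k_min) {
    attr(curve, "flag") <- "no_noneffective_prefix"
    return(curve)
  }
  anchor_mean <- mean(curve$response[seq_len(prefix_len)])
  out <- curve
  out$response <- curve$response * 100 / anchor_mean
  out$sd <- curve$sd * 100 / anchor_mean
  attr(out, "anchor") <- "non_effective_mean"
  attr(out, "anchor_info") <- sprintf(
    "rescaled by 100/%.6g over %d-point non-effective prefix", anchor_mean, prefix_len
  )
  attr(out, "flag") <- NULL
  out
}

#' Express ECAR on the plate's glycolytic-range scale
#'
#' Maps each well's ECAR onto a 0-100% scale where 0% is the well's own
#' basal (pre-injection) acidification and 100% is the plate's maximal
#' ECAR induction, taken as the maximum oligomycin-phase ECAR across
#' vehicle wells (vehicle-only, so a compound's own oligomycin response
#' cannot distort the scale). Note the double scale: 0% of the range
#' corresponds to 100% of basal acidification.
#'
#' @param traces Long trace tibble (raw units) containing baseline and
#'   oligomycin phases and at least one vehicle well (`conc_M == 0`).
#' @return `traces` with an added `ecar_range_pct` column.
#' @export
normalize_ecar_range <- function(traces) {
  needed <- c("baseline", "oligomycin")
  if (!all(needed %in% traces$phase)) {
    stop_validation("trace needs baseline and oligomycin phases for ECAR range scaling")
  }
  veh <- dplyr::filter(traces, .data$conc_M == 0, .data$phase == "oligomycin")
  if (nrow(veh) == 0) stop_validation("no vehicle oligomycin measurements on plate")
  oligo_max <- veh |>
    dplyr::summarise(m = max(.data$ecar), .by = "plate_id")
  base <- traces |>
    dplyr::filter(.data$phase == "baseline") |>
    dplyr::summarise(basal_ecar = mean(.data$ecar), .by = c("plate_id", "well"))
  out <- traces |>
    dplyr::left_join(base, by = c("plate_id", "well")) |>
    dplyr::left_join(oligo_max, by = "plate_id")
  if (any(out$m <= out$basal_ecar)) {
    stop_validation("degenerate plate: vehicle oligomycin ECAR maximum <= basal")
  }
  out |>
    dplyr::mutate(
      ecar_range_pct = (.data$ecar - .data$basal_ecar) /
        (.data$m - .data$basal_ecar) * 100
    ) |>
    dplyr::select(-dplyr::all_of(c("basal_ecar", "m")))
}

#' Normalize maximal (FCCP-phase) OCR to control
#'
#' Maximal respiration of a treated well as percent of the vehicle
#' wells' maximal respiration.
#'
#' @param fccp_ocr_pct Treated-well maximal OCR (percent of own baseline).
#' @param vehicle_fccp_ocr_pct Vehicle maximal OCR (same scale, > 0).
#' @return Percent of control maximal respiration.
#' @export
normalize_maximal_to_control <- function(fccp_ocr_pct, vehicle_fccp_ocr_pct) {
  if (length(vehicle_fccp_ocr_pct) < 1 || mean(vehicle_fccp_ocr_pct) <= 0) {
    stop_validation("vehicle maximal OCR must be positive")
  }
  fccp_ocr_pct / mean(vehicle_fccp_ocr_pct) * 100
}
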