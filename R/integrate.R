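# Cross-assay integration: potency fitting over mitostress curves,
# the compound-by-endpoint summary matrix, correlation plots'
# statistics, and per-compound mechanism-of-action calls.

#' Fit potencies for the three mitostress endpoints of every compound
#'
#' For each compound: `ocr_basal` and `ocr_maximal` are inhibition
#' endpoints (bounded Hill fit, 50%-crossing IC50, censored beyond the
#' ladder); `ecar` is an activation endpoint on the glycolytic-range
#' scale (point-to-point EC50). A compound whose basal OCR rises above
#' `rise_threshold` at the top doses (protonophore signature) is routed
#' to the activation branch for `ocr_basal` instead of a meaningless
#' inhibition fit.
#'
#' @param curves Curve tibble from [potency_curves_from_plate()].
#' @param rise_threshold Percent-of-baseline level marking an
#'   OCR-activation (uncoupling) profile.
#' @return Tibble: `compound`, `endpoint`, `kind`, `value`, `censored`,
#'   `display`.
#' @export
mitostress_potencies <- function(curves, rise_threshold = 115) {
  out <- list()
  for (cmpd in unique(curves$compound)) {
    for (ep in unique(curves$endpoint)) {
      cv <- curves |>
        dplyr::filter(.data$compound == cmpd, .data$endpoint == ep) |>
        dplyr::arrange(.data$conc_M)
      if (nrow(cv) == 0) next
      top_tested <- max(cv$conc_M)
      pot <- if (ep == "ecar") {
        ec50_pointwise(cv$conc_M, cv$response)
      } else if (ep == "ocr_basal" &&
                 mean(tail(cv$response, 2)) >= rise_threshold) {
        # uncoupler: basal OCR increases; report the half-rise EC50
        rise <- (cv$response - 100) / (max(cv$response) - 100) * 100
        ec50_pointwise(cv$conc_M, rise)
      } else {
        fit <- fit_hill4(cv$conc_M, cv$response, direction = "decreasing")
        ic50_from_fit(fit, top_tested)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        compound = cmpd, endpoint = ep, kind = pot$kind,
        value = pot$value, censored = pot$censored, display = pot$display
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Fit potencies for a 24-h endpoint panel
#'
#' Resazurin and MMP are inhibition endpoints (Hill IC50 on the
#' percent-of-control scale); lactate and PI are activation endpoints
#' (point-to-point EC50: lactate crosses at +50% over control, PI at a
#' 50% positive fraction).
#'
#' @param endpoints Endpoint tibble from [simulate_endpoint_panel()] or
#'   [read_endpoints()].
#' @return Tibble as for [mitostress_potencies()].
#' @export
endpoint_potencies <- function(endpoints) {
  out <- list()
  for (cmpd in unique(endpoints$compound)) {
    for (ep in unique(endpoints$endpoint)) {
      cv <- endpoints |>
        dplyr::filter(.data$compound == cmpd, .data$endpoint == ep) |>
        dplyr::arrange(.data$conc_M)
      if (nrow(cv) == 0) next
      top_tested <- max(cv$conc_M)
      pot <- switch(ep,
        resazurin_pct = ,
        mmp_pct = {
          fit <- fit_hill4(cv$conc_M, cv$mean_pct, direction = "decreasing")
          ic50_from_fit(fit, top_tested)
        },
        lactate_pct = ec50_pointwise(cv$conc_M, cv$mean_pct - 100),
        pi_fraction = ec50_pointwise(cv$conc_M, cv$mean_pct * 100),
        stop_validation(paste0("unknown endpoint: ", ep))
      )
      out[[length(out) + 1]] <- tibble::tibble(
        compound = cmpd, endpoint = ep, kind = pot$kind,
        value = pot$value, censored = pot$censored, display = pot$display
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Assemble the compound-by-endpoint summary matrix
#'
#' One row per compound (panel order), one column per endpoint x
#' cell-model combination, each cell a potency display string
#' (`"-6.62"`, `"> -5.00"`, `"NR"`); endpoints never measured for a
#' compound render `"NT"`.
#'
#' @param potencies Tibble with columns `compound`, `endpoint` and
#'   `display` (e.g. from [mitostress_potencies()], with `endpoint`
#'   already qualified by cell model where relevant).
#' @param compound_order Character vector fixing row order (defaults to
#'   the packaged panel order for panel compounds, appearance order
#'   otherwise).
#' @param endpoint_order Character vector fixing column order (defaults
#'   to appearance order).
#' @return Wide tibble: `compound` plus one character column per
#'   endpoint. Rendering is deterministic: identical inputs give
#'   byte-identical CSV output.
#' @export
build_summary_matrix <- function(potencies,
                                 compound_order = NULL,
                                 endpoint_order = NULL) {
  key <- paste(potencies$compound, potencies$endpoint, sep = "\r")
  if (anyDuplicated(key)) {
    per_key <- tapply(potencies$display, key, function(d) dplyr::n_distinct(d))
    if (any(per_key > 1)) stop_validation("conflicting duplicate potency entries")
    potencies <- potencies[!duplicated(key), ]
  }
  compound_order <- compound_order %||% unique(potencies$compound)
  endpoint_order <- endpoint_order %||% unique(potencies$endpoint)
  wide <- potencies |>
    dplyr::select(dplyr::all_of(c("compound", "endpoint", "display"))) |>
    tidyr::pivot_wider(names_from = "endpoint", values_from = "display")
  full <- tibble::tibble(compound = compound_order) |>
    dplyr::left_join(wide, by = "compound")
  for (ep in endpoint_order) {
    if (!ep %in% names(full)) full[[ep]] <- NA_character_
    full[[ep]][is.na(full[[ep]])] <- "NT"
  }
  full[c("compound", endpoint_order)]
}

#' Ordinary least-squares association between two endpoints
#'
#' Relates matched per-(compound, concentration) mean responses of two
#' endpoints: OLS slope and intercept plus the squared Pearson
#' correlation of the matched pairs.
#'
#' @param x,y Tibbles with columns `compound`, `conc_M`, `response`;
#'   pairs are matched on (compound, concentration).
#' @param endpoint_x,endpoint_y Labels carried into the result.
#' @return Tibble: `endpoint_x`, `endpoint_y`, `slope`, `intercept`,
#'   `r2`, `n`.
#' @export
correlate_endpoints <- function(x, y, endpoint_x = "x", endpoint_y = "y") {
  merged <- dplyr::inner_join(
    dplyr::select(x, dplyr::all_of(c("compound", "conc_M", "response"))),
    dplyr::select(y, dplyr::all_of(c("compound", "conc_M", "response"))),
    by = c("compound", "conc_M"), suffix = c("_x", "_y")
  )
  merged <- merged[stats::complete.cases(merged[c("response_x", "response_y")]), ]
  if (nrow(merged) < 3) stop_validation("need >= 3 matched pairs to correlate")
  fit <- stats::lm(response_y ~ response_x, data = merged)
  r <- stats::cor(merged$response_x, merged$response_y)
  tibble::tibble(
    endpoint_x = endpoint_x, endpoint_y = endpoint_y,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r2 = r^2, n = nrow(merged)
  )
}

#' Mechanism-of-action call for one compound
#'
#' Synthesizes all available evidence into a single mechanism label by
#' a fixed precedence rule (uncoupler > complex-specific inhibitor >
#' downstream inhibitor > inactive):
#'
#' 1. an uncoupling flag anywhere on the ladder calls `uncoupler`
#'    (mixed evidence of uncoupling plus a full ETC block is marked
#'    `contradictory` in the evidence but keeps this precedence);
#' 2. a permeabilized CII pattern calls `etc_inhibitor_CII_masked`
#'    (such compounds are by construction silent in intact cells);
#' 3. a CI/CIII/CIII-partial complex call makes the corresponding
#'    `etc_inhibitor_*` call - intact OCR inhibition plus an ECAR rise
#'    corroborates it, but a potency confined to the permeabilized
#'    assay (a weak inhibitor) still counts;
#' 4. a stage-3 (TMPD) inhibition pattern calls `downstream_inhibitor`;
#' 5. otherwise `inactive`.
#'
#' @param compound Compound name.
#' @param uncoupling Logical: any uncoupling flag across the ladder.
#' @param intact_ocr_censored Censoring state of the intact basal-OCR
#'   potency (`"none"` = measurable intact inhibition).
#' @param ecar_censored Censoring state of the intact ECAR EC50.
#' @param complex_call Per-compound permeabilized call (see
#'   [complex_call_per_compound()]); NA when not tested.
#' @param mmp_censored,lactate_censored Optional corroborating
#'   censoring states (recorded as evidence, not decisive).
#' @return List: `compound`, `call`, `evidence`.
#' @export
call_moa <- function(compound,
                     uncoupling,
                     intact_ocr_censored = "not_tested",
                     ecar_censored = "not_tested",
                     complex_call = NA_character_,
                     mmp_censored = "not_tested",
                     lactate_censored = "not_tested") {
  evidence <- list(
    uncoupling = uncoupling,
    intact_ocr_active = identical(intact_ocr_censored, "none"),
    ecar_active = identical(ecar_censored, "none"),
    complex_call = complex_call,
    mmp_active = identical(mmp_censored, "none"),
    lactate_active = identical(lactate_censored, "none"),
    contradictory = FALSE
  )
  cc <- if (is.na(complex_call)) "none" else complex_call
  call <- if (isTRUE(uncoupling)) {
    if (cc %in% c("CI", "CII", "CIII")) evidence$contradictory <- TRUE
    "uncoupler"
  } else if (cc == "CII") {
    "etc_inhibitor_CII_masked"
  } else if (cc %in% c("CI", "CIII", "CIII_partial")) {
    paste0("etc_inhibitor_", cc)
  } else if (cc == "CIV_CV_downstream") {
    "downstream_inhibitor"
  } else {
    "inactive"
  }
  list(compound = compound, call = call, evidence = evidence)
}

#' Mechanism-of-action table for a whole panel
#'
#' Vectorized wrapper around [call_moa()].
#'
#' @param evidence Tibble with one row per compound and columns
#'   matching [call_moa()]'s arguments.
#' @return Tibble: `compound`, `call`, plus the evidence columns.
#' @export
moa_table <- function(evidence) {
  calls <- vapply(seq_len(nrow(evidence)), function(i) {
    call_moa(
      compound = evidence$compound[i],
      uncoupling = evidence$uncoupling[i],
      intact_ocr_censored = evidence$intact_ocr_censored[i] %||% "not_tested",
      ecar_censored = evidence$ecar_censored[i] %||% "not_tested",
      complex_call = evidence$complex_call[i]
    )$call
  }, character(1))
  dplyr::mutate(evidence, call = calls, .after = "compound")
}
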