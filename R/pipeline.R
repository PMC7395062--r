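# End-to-end orchestration: simulate the full screening campaign and
# integrate every assay into the summary matrix and MoA calls.

#' Default pipeline configuration
#'
#' Collects every tunable of the simulated screening campaign and its
#' analysis in one list. Defaults encode the reference study
#' conditions: two cell models (low-spare-capacity glycolytic vs
#' high-spare-capacity oxidative), the 8-point 1-in-5 intact ladder
#' from 10 uM, the extended permeabilized ladder from 500 uM,
#' multiplicative measurement noise (CV 3%, per-well scale spread 5%),
#' triplicate vehicle anchoring, and the documented decision
#' thresholds.
#'
#' @param seed Master seed; all plate-level seeds derive from it.
#' @param profiles Named list of `cell_line_profile`s.
#' @param intact_series,perm_series Concentration ladders.
#' @param cv,well_scale_sd Noise parameters (see [noise_model()]).
#' @param n_vehicle Vehicle wells per plate.
#' @param sim_hill_slope Simulated occupancy Hill slope.
#' @param cii_masking Intact-cell CII masking degree.
#' @param dose_rule Per-compound complex-call rule (see
#'   [complex_call_per_compound()]).
#' @param medium,culture,exposures Endpoint-panel scenario.
#' @param rise_threshold,oligo_resistance Uncoupling thresholds (see
#'   [detect_uncoupling()]).
#' @param inhibition_frac,rescue_frac,partial_band Complex-call
#'   thresholds (see [classify_complex()]).
#' @param panel_path Compound panel CSV.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            profiles = list(
                              HepG2 = hepg2_profile(),
                              RPTEC = rptec_profile()
                            ),
                            intact_series = dilution_preset("intact_default"),
                            perm_series = dilution_preset("permeabilized_extended"),
                            cv = 0.03,
                            well_scale_sd = 0.05,
                            n_vehicle = 6,
                            sim_hill_slope = 1,
                            cii_masking = 1,
                            dose_rule = "consensus",
                            medium = "glucose",
                            culture = "monolayer_2d",
                            exposures = 1,
                            rise_threshold = 115,
                            oligo_resistance = 100,
                            inhibition_frac = 0.7,
                            rescue_frac = 0.7,
                            partial_band = c(0.4, 0.7),
                            panel_path = panel_fixture_path()) {
  structure(
    list(
      seed = as.integer(seed), profiles = profiles,
      intact_series = intact_series, perm_series = perm_series,
      cv = cv, well_scale_sd = well_scale_sd, n_vehicle = n_vehicle,
      sim_hill_slope = sim_hill_slope, cii_masking = cii_masking,
      dose_rule = dose_rule, medium = medium, culture = culture,
      exposures = exposures, rise_threshold = rise_threshold,
      oligo_resistance = oligo_resistance,
      inhibition_frac = inhibition_frac, rescue_frac = rescue_frac,
      partial_band = partial_band, panel_path = panel_path
    ),
    class = "pipeline_config"
  )
}

#' Run the full simulated screening campaign
#'
#' Simulates, for every configured cell model, a mitostress plate and a
#' 24-h endpoint panel, plus one permeabilized complex-assay plate;
#' then runs the complete analysis: normalization, mitostress
#' decomposition and uncoupler detection, potency fitting with
#' censoring, complex-specificity calls, endpoint correlations, the
#' summary matrix and per-compound MoA calls.
#'
#' @param config A [pipeline_config()] list.
#' @return List with elements `panel`, `potencies` (long),
#'   `summary_matrix`, `mitostress_params` (per profile),
#'   `curves` (per profile), `complex_calls` (per well),
#'   `complex_compound_calls`, `complex_potencies`, `endpoints`
#'   (per profile), `correlations`, `moa`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  panel <- load_panel(config$panel_path)
  potencies <- list()
  params_by_profile <- list()
  curves_by_profile <- list()
  endpoints_by_profile <- list()
  correlations <- list()
  uncoupling_any <- setNames(rep(FALSE, nrow(panel)), panel$name)

  for (i in seq_along(config$profiles)) {
    pname <- names(config$profiles)[i]
    profile <- config$profiles[[i]]
    traces <- simulate_mitostress_plate(
      panel, config$intact_series, profile,
      noise = noise_model(config$cv, config$well_scale_sd,
        seed = config$seed + 1000L * i
      ),
      n_vehicle = config$n_vehicle,
      cii_masking = config$cii_masking,
      sim_hill_slope = config$sim_hill_slope,
      plate_id = paste0("mitostress_", pname)
    )
    params <- decompose_plate(traces)
    params$uncoupling <- detect_uncoupling(
      params, config$rise_threshold, config$oligo_resistance
    )
    params_by_profile[[pname]] <- params
    flagged <- params |>
      dplyr::filter(.data$conc_M > 0) |>
      dplyr::summarise(u = any(.data$uncoupling), .by = "compound")
    uncoupling_any[flagged$compound] <- uncoupling_any[flagged$compound] | flagged$u

    curves <- potency_curves_from_plate(traces)
    curves_by_profile[[pname]] <- curves
    mp <- mitostress_potencies(curves, config$rise_threshold)
    mp$endpoint <- paste0(mp$endpoint, "_", pname)
    potencies[[length(potencies) + 1]] <- mp

    eps <- simulate_endpoint_panel(
      panel, config$intact_series, profile,
      medium = config$medium, culture = config$culture,
      exposures = config$exposures,
      noise = noise_model(config$cv, config$well_scale_sd,
        seed = config$seed + 1000L * i + 500L
      ),
      sim_hill_slope = config$sim_hill_slope,
      cii_masking = config$cii_masking
    )
    endpoints_by_profile[[pname]] <- eps
    ep_pots <- endpoint_potencies(eps)
    ep_pots$endpoint <- paste0(ep_pots$endpoint, "_", pname)
    potencies[[length(potencies) + 1]] <- ep_pots

    # correlation inputs: per-(compound, conc) means
    resp <- function(df, ep, value_col = "response") {
      df |>
        dplyr::filter(.data$endpoint == ep) |>
        dplyr::select(dplyr::all_of(c("compound", "conc_M", response = value_col)))
    }
    ocr <- resp(curves, "ocr_basal")
    ecar <- resp(curves, "ecar")
    res <- resp(eps, "resazurin_pct", "mean_pct")
    mmp <- resp(eps, "mmp_pct", "mean_pct")
    lac <- resp(eps, "lactate_pct", "mean_pct")
    correlations[[length(correlations) + 1]] <- dplyr::bind_rows(
      correlate_endpoints(ocr, ecar,
        paste0("ocr_basal_", pname), paste0("ecar_", pname)
      ),
      correlate_endpoints(ocr, res,
        paste0("ocr_basal_", pname), paste0("resazurin_", pname)
      ),
      correlate_endpoints(ocr, mmp,
        paste0("ocr_basal_", pname), paste0("mmp_", pname)
      ),
      correlate_endpoints(ecar, lac,
        paste0("ecar_", pname), paste0("lactate_", pname)
      )
    )
  }

  # permeabilized complex assay: run on the first (hepatic) profile
  cx_traces <- simulate_complex_assay_plate(
    panel, config$perm_series,
    noise = noise_model(config$cv, config$well_scale_sd, seed = config$seed + 777L),
    n_vehicle = config$n_vehicle,
    sim_hill_slope = config$sim_hill_slope
  )
  cx_calls <- complex_calls_from_plate(
    cx_traces,
    inhibition_frac = config$inhibition_frac,
    rescue_frac = config$rescue_frac,
    partial_band = config$partial_band
  )
  cx_compound <- complex_call_per_compound(cx_calls, dose_rule = config$dose_rule)
  cx_pots <- complex_potency(cx_calls)
  cx_wide <- cx_pots |>
    dplyr::mutate(endpoint = paste0(
      "perm_", gsub("/", "_", .data$stage)
    )) |>
    dplyr::select(dplyr::all_of(c(
      "compound", "endpoint",
      value = "log10_potency", "censored", "display"
    ))) |>
    dplyr::mutate(kind = "IC50")
  potencies[[length(potencies) + 1]] <- cx_wide

  all_pots <- dplyr::bind_rows(potencies)
  summary_matrix <- build_summary_matrix(all_pots, compound_order = panel$name)

  # MoA evidence: intact activity from the first profile's fits
  first_name <- names(config$profiles)[1]
  grab <- function(ep_prefix) {
    all_pots |>
      dplyr::filter(.data$endpoint == paste0(ep_prefix, "_", first_name)) |>
      dplyr::select(dplyr::all_of(c("compound", "censored")))
  }
  evidence <- tibble::tibble(compound = panel$name) |>
    dplyr::left_join(
      dplyr::rename(grab("ocr_basal"), intact_ocr_censored = "censored"),
      by = "compound"
    ) |>
    dplyr::left_join(
      dplyr::rename(grab("ecar"), ecar_censored = "censored"),
      by = "compound"
    ) |>
    dplyr::left_join(
      dplyr::select(cx_compound, dplyr::all_of(c("compound", complex_call = "call"))),
      by = "compound"
    ) |>
    dplyr::mutate(uncoupling = unname(uncoupling_any[.data$compound]))
  moa <- moa_table(evidence)

  list(
    panel = panel,
    potencies = all_pots,
    summary_matrix = summary_matrix,
    mitostress_params = params_by_profile,
    curves = curves_by_profile,
    complex_calls = cx_calls,
    complex_compound_calls = cx_compound,
    complex_potencies = cx_pots,
    endpoints = endpoints_by_profile,
    correlations = dplyr::bind_rows(correlations),
    moa = moa,
    config = config
  )
}
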