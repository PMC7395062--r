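#' Load the ETC-inhibitor compound panel
#'
#' Reads a compound-panel table: one row per compound with its annotated
#' target complex (CI = NADH:ubiquinone oxidoreductase, CII = succinate
#' dehydrogenase, CIII = cytochrome bc1 complex), CAS number, molecular
#' weight, ClogP and a flag for the starred core subset. The packaged
#' default is a 21-compound agrochemical panel (8 CI, 5 CII, 8 CIII
#' inhibitors, capsaicin included among the CI class).
#'
#' Two optional columns carry synthetic simulator ground truth
#' (`sim_mechanism`, `sim_potency_log10M`); they configure the trace
#' simulator only and are never consulted by any analysis stage.
#'
#' @param table_path Path to a CSV panel file. Defaults to the packaged
#'   panel fixture.
#' @return A tibble with columns `name`, `target_complex` (factor with
#'   levels CI/CII/CIII), `cas`, `mol_weight` (g/mol), `clogp`,
#'   `subset_flag`, and, when present, `sim_mechanism` and
#'   `sim_potency_log10M`.
#' @export
#' @examples
#' panel <- load_panel()
#' table(panel$target_complex)
load_panel <- function(table_path = panel_fixture_path()) {
  if (!file.exists(table_path)) {
    stop_format(paste0("panel file not found: ", table_path))
  }
  tab <- tryCatch(
    readr::read_csv(table_path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop_format(paste0("cannot parse panel CSV: ", conditionMessage(e)))
  )
  required <- c("name", "target_complex", "cas", "mol_weight", "clogp", "subset_flag")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0 || nrow(tab) == 0) {
    stop_format(paste0(
      "panel table is empty or lacks required columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(tab$name)) {
    stop_validation("duplicate compound names in panel")
  }
  bad_class <- setdiff(unique(tab$target_complex), c("CI", "CII", "CIII"))
  if (length(bad_class) > 0) {
    stop_validation(paste0(
      "unknown target_complex label(s): ", paste(bad_class, collapse = ", ")
    ))
  }
  if (any(!is.finite(tab$mol_weight) | tab$mol_weight <= 0)) {
    stop_validation("mol_weight must be positive")
  }
  if ("sim_potency_log10M" %in% names(tab)) {
    p <- tab$sim_potency_log10M
    if (any(!is.na(p) & (p < -12 | p > -2))) {
      stop_validation("sim_potency_log10M out of plausible range [-12, -2]")
    }
  }
  tab$target_complex <- factor(tab$target_complex, levels = c("CI", "CII", "CIII"))
  tab$subset_flag <- as.logical(tab$subset_flag)
  tibble::as_tibble(tab)
}

#' Path to the packaged compound-panel fixture
#' @return File path of the packaged panel CSV.
#' @export
panel_fixture_path <- function() {
  system.file("extdata", "etc_inhibitor_panel.csv", package = "mitoscreen", mustWork = TRUE)
}

#' Build a geometric dilution series
#'
#' Constructs an ascending concentration ladder of `n_points` values ending
#' at `top`, each a constant `fold` apart:
#' `values[k] = top / fold^(n_points - k)`. The standard intact-cell
#' screening ladder is 8 points of 1-in-5 dilutions from 10 uM, i.e.
#' `make_dilution_series(1e-5, 5, 8)`, whose lowest member is 1.28e-10 M.
#'
#' @param top Highest concentration (molar, > 0).
#' @param fold Dilution factor between adjacent points (> 1).
#' @param n_points Number of concentrations (>= 1).
#' @return An object of class `concentration_series`: a list with `top`,
#'   `fold`, `n_points` and ascending `values` (molar).
#' @export
#' @examples
#' s <- make_dilution_series(1e-5, 5, 8)
#' s$values[1]  # 1.28e-10
make_dilution_series <- function(top, fold, n_points) {
  if (!is.numeric(top) || length(top) != 1 || top <= 0) {
    stop_domain("top concentration must be a single positive number")
  }
  if (!is.numeric(fold) || length(fold) != 1 || fold <= 1) {
    stop_domain("dilution fold must be > 1")
  }
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 1 ||
      n_points != round(n_points)) {
    stop_domain("n_points must be an integer >= 1")
  }
  values <- top / fold^((n_points - 1):0)
  structure(
    list(top = top, fold = fold, n_points = as.integer(n_points), values = values),
    class = "concentration_series"
  )
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf(
    "<concentration_series> %d points, 1-in-%g from %.3g M\n",
    x$n_points, x$fold, x$top
  ))
  print(signif(x$values, 3))
  invisible(x)
}

#' Named concentration-ladder presets
#'
#' `"intact_default"` is the 8-point 1-in-5 ladder from 10 uM used for
#' intact-cell assays. `"permeabilized_extended"` is a wider 12-point
#' half-log (1-in-sqrt(10)) ladder from 500 uM down to about 1.6 nM used
#' for the permeabilized-cell complex assay: its top end reaches the
#' weak inhibitors (notably the CII class) that only act well above
#' 10 uM, while its low end still resolves potent nanomolar CI/CIII
#' inhibitors instead of saturating them at every tested dose.
#'
#' @param name Preset name.
#' @return A `concentration_series`.
#' @export
#' @examples
#' dilution_preset("intact_default")$values
dilution_preset <- function(name = c("intact_default", "permeabilized_extended")) {
  name <- match.arg(name)
  switch(name,
    intact_default = make_dilution_series(1e-5, 5, 8),
    permeabilized_extended = make_dilution_series(5e-4, sqrt(10), 12)
  )
}
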