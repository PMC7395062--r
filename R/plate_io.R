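# Plate I/O: long-format trace tables, plate maps and endpoint tables.
# CSV dialect: comma separator, "." decimal, UTF-8, header row required.
# All readers accept gzip-compressed files (handled transparently by
# readr). There is no parsing of vendor-native analyzer workbooks; the
# column mapping below is the interchange contract.

trace_columns <- c(
  "plate_id", "well", "compound", "conc_M", "phase", "time_min", "ocr", "ecar"
)

#' Read kinetic well traces from CSV
#'
#' Reads a long-format trace table (one row per well per measurement)
#' with columns `plate_id, well, compound, conc_M, phase, time_min, ocr,
#' ecar`. Rows are sorted by time within each well; row order in the file
#' is immaterial. Duplicate time points within a well, or phase labels
#' not present in a declared schedule, are rejected.
#'
#' @param path CSV (optionally gzipped) file path.
#' @param schedule Optional `injection_schedule` to validate phase labels
#'   against.
#' @return Long trace tibble.
#' @export
read_traces <- function(path, schedule = NULL) {
  if (!file.exists(path)) stop_format(paste0("trace file not found: ", path))
  tab <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop_format(paste0("cannot parse trace CSV: ", conditionMessage(e)))
  )
  missing <- setdiff(trace_columns, names(tab))
  if (length(missing) > 0) {
    stop_format(paste0("trace file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  tab <- dplyr::arrange(tab[trace_columns], .data$plate_id, .data$well, .data$time_min)
  dup <- tab |>
    dplyr::summarise(bad = anyDuplicated(.data$time_min) > 0, .by = c("plate_id", "well"))
  if (any(dup$bad)) {
    stop_format("non-monotone or duplicate time points within a well")
  }
  if (!is.null(schedule)) {
    unknown <- setdiff(unique(tab$phase), schedule$phase)
    if (length(unknown) > 0) {
      stop_format(paste0("unknown phase label(s): ", paste(unknown, collapse = ", ")))
    }
  }
  if (any(tab$ocr < 0, na.rm = TRUE) || any(tab$ecar < 0, na.rm = TRUE)) {
    stop_validation("negative OCR/ECAR values in trace file")
  }
  tibble::as_tibble(tab)
}

#' Write kinetic well traces to CSV
#'
#' Inverse of [read_traces()]: writes the canonical trace columns in
#' canonical (plate, well, time) order. Floats are serialized with
#' shortest round-trip formatting, so `write_traces()` then
#' [read_traces()] reproduces the table exactly.
#'
#' @param traces Long trace tibble.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  missing <- setdiff(trace_columns, names(traces))
  if (length(missing) > 0) {
    stop_validation(paste0("trace table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out <- dplyr::arrange(
    traces[trace_columns],
    .data$plate_id, .data$well, .data$time_min
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a plate map
#'
#' A plate map assigns each well a compound, a molar concentration and a
#' role (`vehicle`, `treatment` or `blank`). Wells must be unique and
#' vehicle wells must carry concentration 0.
#'
#' @param path CSV file with columns `well, compound, conc_M, role`.
#' @return Plate-map tibble.
#' @export
read_platemap <- function(path) {
  if (!file.exists(path)) stop_format(paste0("plate map not found: ", path))
  tab <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop_format(paste0("cannot parse plate map: ", conditionMessage(e)))
  )
  required <- c("well", "compound", "conc_M", "role")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop_format(paste0("plate map lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tab$well)) stop_validation("duplicate wells in plate map")
  bad_role <- setdiff(unique(tab$role), c("vehicle", "treatment", "blank"))
  if (length(bad_role) > 0) {
    stop_validation(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  if (any(tab$role == "vehicle" & tab$conc_M != 0)) {
    stop_validation("vehicle wells must have conc_M = 0")
  }
  tibble::as_tibble(tab[required])
}

#' Read an endpoint table
#'
#' Accepts either pre-aggregated rows (`compound, conc_M, endpoint,
#' mean_pct[, sd_pct, n]`) or per-replicate rows (`compound, conc_M,
#' endpoint, value`), which are aggregated to mean/SD/n per condition.
#'
#' @param path CSV file path.
#' @return Tibble with `compound, conc_M, endpoint, mean_pct, sd_pct, n`.
#' @export
read_endpoints <- function(path) {
  if (!file.exists(path)) stop_format(paste0("endpoint file not found: ", path))
  tab <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop_format(paste0("cannot parse endpoint CSV: ", conditionMessage(e)))
  )
  key <- c("compound", "conc_M", "endpoint")
  missing <- setdiff(key, names(tab))
  if (length(missing) > 0) {
    stop_format(paste0("endpoint file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if ("mean_pct" %in% names(tab)) {
    if (!"sd_pct" %in% names(tab)) tab$sd_pct <- NA_real_
    if (!"n" %in% names(tab)) tab$n <- NA_integer_
    return(tibble::as_tibble(tab[c(key, "mean_pct", "sd_pct", "n")]))
  }
  if (!"value" %in% names(tab)) {
    stop_format("endpoint file needs either a mean_pct or a value column")
  }
  tab |>
    dplyr::summarise(
      mean_pct = mean(.data$value),
      sd_pct = stats::sd(.data$value),
      n = dplyr::n(),
      .by = dplyr::all_of(key)
    ) |>
    tibble::as_tibble()
}
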