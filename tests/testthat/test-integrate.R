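test_that("endpoint correlation reproduces exact linear relations", {
  x <- tibble::tibble(compound = "A", conc_M = 10^seq(-9, -5), response = c(10, 30, 50, 70, 90))
  y_same <- x
  res <- correlate_endpoints(x, y_same, "a", "a")
  expect_equal(res$slope, 1)
  expect_equal(res$r2, 1)

  y_neg <- dplyr::mutate(x, response = 200 - response)
  res2 <- correlate_endpoints(x, y_neg)
  expect_equal(res2$slope, -1)
  expect_equal(res2$r2, 1)

  expect_error(
    correlate_endpoints(x[1:2, ], y_same[1:2, ]),
    class = "mitoscreen_validation_error"
  )
})

test_that("summary matrix fills untested cells and keeps the requested order", {
  pots <- tibble::tibble(
    compound = c("B", "A", "A"),
    endpoint = c("e1", "e1", "e2"),
    display = c("-6.10", "> -5.00", "NR")
  )
  m <- build_summary_matrix(pots, compound_order = c("A", "B"),
                            endpoint_order = c("e1", "e2"))
  expect_identical(m$compound, c("A", "B"))
  expect_identical(m$e1, c("> -5.00", "-6.10"))
  expect_identical(m$e2, c("NR", "NT"))
})

test_that("summary matrix rendering is byte-stable and rejects conflicts", {
  pots <- tibble::tibble(
    compound = rep(c("A", "B"), each = 2),
    endpoint = rep(c("e1", "e2"), 2),
    display = c("-6.00", "NR", "> -5.00", "-4.20")
  )
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  ords <- list(compound_order = c("A", "B"), endpoint_order = c("e1", "e2"))
  readr::write_csv(do.call(build_summary_matrix, c(list(pots), ords)),
    p1, progress = FALSE
  )
  readr::write_csv(do.call(build_summary_matrix, c(list(pots[sample.int(4), ]), ords)),
    p2, progress = FALSE
  )
  expect_identical(readLines(p1), readLines(p2))

  # identical duplicates collapse; conflicting duplicates error
  expect_silent(build_summary_matrix(dplyr::bind_rows(pots, pots[1, ])))
  conflict <- dplyr::bind_rows(pots, dplyr::mutate(pots[1, ], display = "-9.99"))
  expect_error(build_summary_matrix(conflict), class = "mitoscreen_validation_error")
})

test_that("the MoA rule table resolves each evidence pattern", {
  expect_identical(
    call_moa("r", uncoupling = FALSE, intact_ocr_censored = "none",
             ecar_censored = "none", complex_call = "CI")$call,
    "etc_inhibitor_CI"
  )
  expect_identical(
    call_moa("t", uncoupling = FALSE, intact_ocr_censored = "above_top_tested",
             complex_call = "CII")$call,
    "etc_inhibitor_CII_masked"
  )
  expect_identical(
    call_moa("c", uncoupling = TRUE, complex_call = NA_character_)$call,
    "uncoupler"
  )
  expect_identical(
    call_moa("p", uncoupling = FALSE, complex_call = "CIII_partial")$call,
    "etc_inhibitor_CIII_partial"
  )
  expect_identical(
    call_moa("d", uncoupling = FALSE, complex_call = "CIV_CV_downstream")$call,
    "downstream_inhibitor"
  )
  expect_identical(
    call_moa("n", uncoupling = FALSE, complex_call = "no_inhibition")$call,
    "inactive"
  )
  mixed <- call_moa("m", uncoupling = TRUE, complex_call = "CIII")
  expect_identical(mixed$call, "uncoupler") # precedence is fixed
  expect_true(mixed$evidence$contradictory)
})

test_that("a protonophore's basal-OCR curve is routed to the activation branch", {
  panel <- load_panel()
  pick <- panel[panel$name %in% c("Cyazofamid", "Rotenone"), ]
  tr <- simulate_mitostress_plate(
    pick, dilution_preset("intact_default"), rptec_profile(),
    noise = noise_free()
  )
  pots <- mitostress_potencies(potency_curves_from_plate(tr))
  cya <- dplyr::filter(pots, compound == "Cyazofamid", endpoint == "ocr_basal")
  rot <- dplyr::filter(pots, compound == "Rotenone", endpoint == "ocr_basal")
  expect_identical(cya$kind, "EC50")
  expect_identical(rot$kind, "IC50")
  expect_identical(rot$censored, "none")
})

test_that("CLI rejects bad usage with distinct exit codes", {
  expect_message(code <- mitoscreen_cli("frobnicate"), "usage")
  expect_identical(code, 2L)
  expect_message(code2 <- mitoscreen_cli(c("fitdr", "--curves")), "configuration error")
  expect_identical(code2, 2L)
  expect_message(code3 <- mitoscreen_cli(c("fitdr", "--out", "x.csv")), "configuration error")
  expect_identical(code3, 2L)
})

test_that("CLI fits and summarizes from CSV files", {
  curves <- withr::local_tempfile(fileext = ".csv")
  out <- withr::local_tempfile(fileext = ".csv")
  conc <- dilution_preset("intact_default")$values
  readr::write_csv(
    tibble::tibble(
      compound = "X", endpoint = "ocr_basal", conc_M = conc,
      response = 100 * (1 - hill_fraction(conc, 1e-7, 1))
    ),
    curves, progress = FALSE
  )
  expect_identical(mitoscreen_cli(c("fitdr", "--curves", curves, "--out", out)), 0L)
  fitted <- readr::read_csv(out, show_col_types = FALSE)
  expect_equal(fitted$value, -7, tolerance = 1e-3)

  pot_csv <- withr::local_tempfile(fileext = ".csv")
  mat_csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    tibble::tibble(compound = "X", endpoint = "e1", display = "-7.00"),
    pot_csv, progress = FALSE
  )
  expect_identical(
    mitoscreen_cli(c("summarize", "--potencies", pot_csv, "--out", mat_csv)), 0L
  )
  mat <- readr::read_csv(mat_csv,
    col_types = readr::cols(.default = readr::col_character())
  )
  expect_identical(mat$e1, "-7.00")
})

test_that("the pipeline produces a coherent integrated result", {
  res <- run_pipeline(pipeline_config(seed = 7))
  expect_equal(nrow(res$moa), 21)
  expect_equal(nrow(res$summary_matrix), 21)
  expect_true(all(res$moa$call %in% c(
    "etc_inhibitor_CI", "etc_inhibitor_CII_masked", "etc_inhibitor_CIII",
    "etc_inhibitor_CIII_partial", "uncoupler", "downstream_inhibitor", "inactive"
  )))
  # every summary cell is a rendered potency string
  cells <- unlist(res$summary_matrix[-1])
  expect_true(all(grepl("^(-?[0-9.]+|[<>] -?[0-9.]+|NR|NT)$", cells)))
  # rerunning with the same seed reproduces the matrix exactly
  res2 <- run_pipeline(pipeline_config(seed = 7))
  expect_identical(res$summary_matrix, res2$summary_matrix)
})
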