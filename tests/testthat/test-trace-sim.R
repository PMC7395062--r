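test_that("simulation is deterministic given the seed", {
  panel <- load_panel()[1:3, ]
  series <- make_dilution_series(1e-5, 5, 4)
  a <- simulate_mitostress_plate(panel, series, hepg2_profile(),
    noise = noise_model(0.05, 0.05, seed = 42)
  )
  b <- simulate_mitostress_plate(panel, series, hepg2_profile(),
    noise = noise_model(0.05, 0.05, seed = 42)
  )
  c_ <- simulate_mitostress_plate(panel, series, hepg2_profile(),
    noise = noise_model(0.05, 0.05, seed = 43)
  )
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$ocr, c_$ocr)))
})

test_that("simulation does not disturb the global RNG stream", {
  panel <- load_panel()[1:2, ]
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_mitostress_plate(
    panel, make_dilution_series(1e-5, 5, 4), hepg2_profile(),
    noise = noise_model(0.05, 0.05, seed = 7)
  ))
  expect_identical(.Random.seed, before)
})

test_that("noise-free vehicle traces follow the flux model exactly", {
  profile <- hepg2_profile()
  tr <- simulate_mitostress_plate(
    load_panel()[1, ], make_dilution_series(1e-5, 5, 2), profile,
    noise = noise_free(), n_vehicle = 1
  )
  veh <- dplyr::filter(tr, conc_M == 0)
  by_phase <- function(ph) unique(veh$ocr[veh$phase == ph])
  expect_equal(by_phase("baseline"), profile$basal_ocr)
  expect_equal(by_phase("compound"), profile$basal_ocr)
  expect_equal(
    by_phase("oligomycin"),
    (profile$nonmito_pct + profile$leak_pct) * profile$basal_ocr / 100
  )
  expect_equal(
    by_phase("fccp"),
    profile$maximal_ocr_pct * profile$basal_ocr / 100
  )
  expect_equal(by_phase("rot_aa"), profile$nonmito_pct * profile$basal_ocr / 100)
  # ECAR: basal at baseline, oligomycin plateau = basal * (1 + reserve)
  expect_equal(unique(veh$ecar[veh$phase == "baseline"]), profile$basal_ecar)
  expect_equal(
    unique(veh$ecar[veh$phase == "oligomycin"]),
    profile$basal_ecar * (1 + profile$glycolytic_reserve)
  )
})

test_that("compound-phase OCR decreases monotonically with dose for a CI inhibitor", {
  panel <- load_panel()
  rotenone <- panel[panel$name == "Rotenone", ]
  tr <- simulate_mitostress_plate(
    rotenone, dilution_preset("intact_default"), hepg2_profile(),
    noise = noise_free()
  )
  comp <- tr |>
    dplyr::filter(phase == "compound", conc_M > 0) |>
    dplyr::summarise(ocr = mean(ocr), .by = conc_M) |>
    dplyr::arrange(conc_M)
  expect_false(is.unsorted(rev(comp$ocr)))
  expect_lt(min(comp$ocr) / max(comp$ocr), 0.5)
})

test_that("CII inhibition is fully masked in intact cells at default masking", {
  panel <- load_panel()
  cii <- panel[panel$name == "Thifluzamide", ]
  series <- dilution_preset("intact_default")
  tr <- simulate_mitostress_plate(cii, series, hepg2_profile(),
    noise = noise_free(), n_vehicle = 2
  )
  top <- dplyr::filter(tr, conc_M == max(series$values))
  # every phase of the treated well equals the vehicle expectation
  veh_one <- dplyr::filter(tr, conc_M == 0) |>
    dplyr::summarise(ocr = mean(ocr), .by = phase)
  top_sum <- top |> dplyr::summarise(ocr = mean(ocr), .by = phase)
  expect_equal(top_sum$ocr, veh_one$ocr[match(top_sum$phase, veh_one$phase)])
})

test_that("partial masking exposes CII inhibition in intact cells", {
  panel <- load_panel()
  cii <- panel[panel$name == "Thifluzamide", ]
  series <- make_dilution_series(1e-3, 5, 4) # saturating for thifluzamide
  tr <- simulate_mitostress_plate(cii, series, hepg2_profile(),
    noise = noise_free(), cii_masking = 0.5
  )
  comp <- tr |>
    dplyr::filter(phase == "compound") |>
    dplyr::summarise(ocr = mean(ocr), .by = conc_M)
  expect_lt(comp$ocr[comp$conc_M == max(series$values)],
            comp$ocr[comp$conc_M == 0] * 0.8)
})

test_that("a protonophore raises basal OCR and resists oligomycin", {
  panel <- load_panel()
  unc <- panel[panel$sim_mechanism == "uncoupler", ]
  profile <- rptec_profile()
  tr <- simulate_mitostress_plate(unc, make_dilution_series(1e-4, 10, 4),
    profile,
    noise = noise_free()
  )
  top <- dplyr::filter(tr, conc_M == 1e-4)
  basal_pct <- mean(top$ocr[top$phase == "compound"]) /
    mean(top$ocr[top$phase == "baseline"]) * 100
  oligo_pct <- mean(top$ocr[top$phase == "oligomycin"]) /
    mean(top$ocr[top$phase == "baseline"]) * 100
  expect_gt(basal_pct, 250) # near the uncoupled maximum (337.4%)
  expect_gt(oligo_pct, 100) # oligomycin cannot suppress uncoupled flux
})

test_that("complex-assay stage pattern localizes the lesion", {
  panel <- mechanism_test_panel(potency = -6)
  series <- make_dilution_series(1e-3, 10, 1) # saturating single dose
  tr <- simulate_complex_assay_plate(panel, series, noise = noise_free())
  summ <- tr |>
    dplyr::group_split(well) |>
    lapply(summarize_stages) |>
    dplyr::bind_rows()
  ci <- dplyr::filter(summ, compound == "ci_like")
  cii <- dplyr::filter(summ, compound == "cii_like")
  down <- dplyr::filter(summ, compound == "downstream_like")
  veh <- dplyr::filter(summ, conc_M == 0)
  expect_lt(ci$m1_pct, 5)
  expect_gt(ci$m2_pct, 50) # succinate bypasses the CI block
  expect_gt(cii$m1_pct, 50) # CII inhibition spares CI-fed flux
  expect_lt(cii$m2_pct, 5)
  expect_lt(down$m3_pct, 5) # nothing rescues a distal block
  expect_gt(min(veh$m3_pct), 50)
})

test_that("galactose medium sensitizes viability loss in a glycolytic model", {
  panel <- load_panel()[load_panel()$name == "Rotenone", ]
  series <- dilution_preset("intact_default")
  glc <- simulate_endpoint_panel(panel, series, hepg2_profile(),
    medium = "glucose", noise = noise_free()
  )
  gal <- simulate_endpoint_panel(panel, series, hepg2_profile(),
    medium = "galactose", noise = noise_free()
  )
  top_res <- function(df) {
    df$mean_pct[df$endpoint == "resazurin_pct" & df$conc_M == max(series$values)]
  }
  expect_gt(top_res(glc), 90) # full glycolytic rescue in glucose
  expect_lt(top_res(gal), 10) # forced oxidative ATP: viability collapses
})

test_that("repeated exposure shifts the effective potency", {
  panel <- load_panel()[load_panel()$name == "Deguelin", ]
  series <- dilution_preset("intact_default")
  one <- simulate_endpoint_panel(panel, series, rptec_profile(),
    exposures = 1, noise = noise_free()
  )
  five <- simulate_endpoint_panel(panel, series, rptec_profile(),
    exposures = 5, noise = noise_free()
  )
  mid <- series$values[5]
  res <- function(df) df$mean_pct[df$endpoint == "resazurin_pct" & df$conc_M == mid]
  expect_lt(res(five), res(one))
})

test_that("simulators reject malformed configuration", {
  panel <- load_panel()[1:2, ]
  bad_schedule <- complex_schedule() # lacks mitostress phases
  expect_error(
    simulate_mitostress_plate(panel, make_dilution_series(1e-5, 5, 4),
      hepg2_profile(),
      schedule = bad_schedule, noise = noise_free()
    ),
    class = "mitoscreen_domain_error"
  )
  expect_error(noise_model(cv = -0.1), class = "mitoscreen_domain_error")
  expect_error(
    cell_line_profile("x",
      maximal_ocr_pct = 90, nonmito_pct = 10, leak_pct = 10,
      glycolytic_reserve = 1
    ),
    class = "mitoscreen_domain_error"
  )
  expect_error(
    simulate_endpoint_panel(panel, make_dilution_series(1e-5, 5, 4),
      hepg2_profile(),
      exposures = 1.5, noise = noise_free()
    ),
    class = "mitoscreen_domain_error"
  )
})
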