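test_that("baseline normalization anchors every well at 100%", {
  tr <- simulate_mitostress_plate(
    load_panel()[1:3, ], make_dilution_series(1e-5, 5, 3), hepg2_profile(),
    noise = noise_model(0.05, 0.08, seed = 5), n_vehicle = 2
  )
  norm <- normalize_to_baseline(tr)
  base_means <- norm |>
    dplyr::filter(phase == "baseline") |>
    dplyr::summarise(m = mean(ocr), e = mean(ecar), .by = well)
  expect_equal(base_means$m, rep(100, nrow(base_means)))
  expect_equal(base_means$e, rep(100, nrow(base_means)))
})

test_that("baseline normalization preserves within-well value order", {
  tr <- simulate_mitostress_plate(
    load_panel()[1, ], make_dilution_series(1e-5, 5, 2), hepg2_profile(),
    noise = noise_model(0.05, 0.05, seed = 6), n_vehicle = 1
  )
  norm <- normalize_to_baseline(tr)
  for (w in unique(tr$well)) {
    expect_identical(
      order(tr$ocr[tr$well == w]),
      order(norm$ocr[norm$well == w])
    )
  }
})

test_that("baseline normalization rejects degenerate input", {
  tr <- simulate_mitostress_plate(
    load_panel()[1, ], make_dilution_series(1e-5, 5, 2), hepg2_profile(),
    noise = noise_free(), n_vehicle = 1
  )
  expect_error(
    normalize_to_baseline(dplyr::filter(tr, phase != "baseline")),
    class = "mitoscreen_validation_error"
  )
})

test_that("vehicle normalization is a simple rescaling", {
  expect_equal(normalize_to_vehicle(c(50, 100), c(90, 110)), c(50, 100))
  expect_error(normalize_to_vehicle(1, numeric(0)), class = "mitoscreen_validation_error")
  expect_error(normalize_to_vehicle(1, c(0, 0)), class = "mitoscreen_validation_error")
})

test_that("non-effective re-anchoring rescales the flat prefix to 100%", {
  curve <- normalized_curve(
    conc = 10^seq(-10, -5, length.out = 6),
    response = c(108, 108, 108, 85, 50, 10),
    anchor = "vehicle"
  )
  out <- renormalize_to_noneffective(curve)
  expect_equal(attr(out, "anchor"), "non_effective_mean")
  expect_equal(mean(out$response[1:3]), 100)
  # order-preserving affine rescale
  expect_identical(order(out$response), order(curve$response))
})

test_that("non-effective re-anchoring is idempotent", {
  curve <- normalized_curve(
    conc = 10^seq(-10, -5, length.out = 6),
    response = c(104, 104, 104, 80, 40, 5),
    anchor = "vehicle"
  )
  once <- renormalize_to_noneffective(curve)
  twice <- renormalize_to_noneffective(once)
  expect_equal(twice$response, once$response)
})

test_that("too-short non-effective prefix leaves the curve flagged", {
  curve <- normalized_curve(
    conc = 10^seq(-9, -5, length.out = 5),
    response = c(104, 60, 40, 20, 5),
    anchor = "vehicle"
  )
  out <- renormalize_to_noneffective(curve)
  expect_equal(attr(out, "flag"), "no_noneffective_prefix")
  expect_equal(out$response, curve$response)
  expect_equal(attr(out, "anchor"), "vehicle")
})

test_that("significance flags veto the non-effective prefix", {
  curve <- normalized_curve(
    conc = 10^seq(-9, -5, length.out = 5),
    response = c(105, 105, 105, 50, 10),
    anchor = "vehicle"
  )
  gated <- renormalize_to_noneffective(curve, signif = c(FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(attr(gated, "flag"), "no_noneffective_prefix")
  expect_error(
    renormalize_to_noneffective(curve, signif = c(TRUE, FALSE)),
    class = "mitoscreen_validation_error"
  )
})

test_that("glycolytic-range scaling maps basal to 0% and the plate oligomycin max to 100%", {
  tr <- simulate_mitostress_plate(
    load_panel()[1:2, ], make_dilution_series(1e-5, 5, 3), hepg2_profile(),
    noise = noise_free(), n_vehicle = 2
  )
  out <- normalize_ecar_range(tr)
  veh_base <- out |>
    dplyr::filter(conc_M == 0, phase == "baseline")
  expect_equal(veh_base$ecar_range_pct, rep(0, nrow(veh_base)))
  veh_oligo <- out |>
    dplyr::filter(conc_M == 0, phase == "oligomycin")
  expect_equal(max(veh_oligo$ecar_range_pct), 100)
  expect_error(
    normalize_ecar_range(dplyr::filter(tr, conc_M > 0)),
    class = "mitoscreen_validation_error"
  )
})

test_that("maximal-to-control normalization rescales against vehicle mean", {
  expect_equal(normalize_maximal_to_control(150, c(140, 160)), 100)
  expect_error(
    normalize_maximal_to_control(150, numeric(0)),
    class = "mitoscreen_validation_error"
  )
})
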