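test_that("Hill fits are exact on noise-free decreasing curves", {
  conc <- make_dilution_series(1e-5, 5, 8)$values
  truth <- list(bottom = 5, top = 98, log_ic50 = -6.8, hill_slope = 1.3,
                direction = "decreasing")
  y <- predict_hill4(truth, conc)
  fit <- fit_hill4(conc, y, "decreasing")
  expect_lt(abs(fit$log_ic50 - truth$log_ic50), 1e-6)
  expect_lt(abs(fit$hill_slope - truth$hill_slope), 1e-4)
  expect_lt(abs(fit$top - truth$top), 1e-4)
  expect_true(fit$converged)
})

test_that("Hill fits handle increasing (activation) curves", {
  conc <- make_dilution_series(1e-4, 5, 8)$values
  truth <- list(bottom = 0, top = 100, log_ic50 = -6, hill_slope = 0.9,
                direction = "increasing")
  y <- predict_hill4(truth, conc)
  fit <- fit_hill4(conc, y, "increasing")
  expect_lt(abs(fit$log_ic50 - truth$log_ic50), 1e-6)
  expect_false(is.unsorted(predict_hill4(fit, conc)))
})

test_that("Hill fitting rejects unusable input", {
  expect_error(fit_hill4(c(1e-7, 1e-6, 1e-5), c(90, 50, 10)),
    class = "mitoscreen_domain_error"
  )
  expect_error(fit_hill4(c(0, 1e-7, 1e-6, 1e-5), c(100, 90, 50, 10)),
    class = "mitoscreen_domain_error"
  )
  expect_error(fit_hill4(c(1e-7, 1e-6, 1e-5, 1e-4), c(90, 50)),
    class = "mitoscreen_domain_error"
  )
})

test_that("IC50 extraction solves the fitted 50% crossing", {
  conc <- make_dilution_series(1e-5, 5, 8)$values
  fit <- fit_hill4(conc, predict_hill4(
    list(bottom = 0, top = 100, log_ic50 = -7, hill_slope = 1,
         direction = "decreasing"), conc
  ), "decreasing")
  pot <- ic50_from_fit(fit, max(conc))
  expect_identical(pot$censored, "none")
  expect_equal(predict_hill4(fit, 10^pot$value), 50, tolerance = 1e-6)
  expect_identical(pot$display, sprintf("%.2f", pot$value))
})

test_that("censoring monotonicity: any beyond-ladder potency renders the same bound", {
  conc <- dilution_preset("intact_default")$values
  displays <- vapply(c(-4.5, -4, -3, -2.5), function(true_l) {
    y <- 100 * (1 - hill_fraction(conc, 10^true_l, 1))
    fit <- fit_hill4(conc, y, "decreasing")
    ic50_from_fit(fit, max(conc))$display
  }, character(1))
  expect_true(all(displays == "> -5.00"))
})

test_that("the no-response rule reports NR only when the realized effect is small", {
  conc <- dilution_preset("permeabilized_extended")$values
  jitter <- rep(c(0.01, -0.01, 0), length.out = length(conc))
  flat <- fit_hill4(conc, rep(100, length(conc)) + jitter, "decreasing")
  expect_identical(ic50_from_fit(flat, max(conc), no_response_max_effect = 20)$display, "NR")
  # without the rule the same fit censors to the ladder top instead
  expect_identical(
    ic50_from_fit(flat, max(conc))$censored,
    "above_top_tested"
  )
})

test_that("pointwise EC50 interpolates the first 50% crossing", {
  pot <- ec50_pointwise(c(1e-7, 1e-5), c(0, 100))
  grid_step <- 2 / 999
  expect_lt(abs(pot$value - (-6)), grid_step + 1e-9)
  expect_identical(pot$kind, "EC50")
})

test_that("pointwise EC50 is invariant to interior collinear points", {
  conc <- c(1e-8, 1e-6)
  resp <- c(0, 100)
  base <- ec50_pointwise(conc, resp)
  # add collinear interior points (linear in log10 concentration)
  extra_x <- c(-7.5, -7, -6.5)
  extra_y <- (extra_x - (-8)) / 2 * 100
  aug <- ec50_pointwise(c(conc, 10^extra_x), c(resp, extra_y))
  expect_equal(aug$value, base$value)
})

test_that("flat activation curves render NR", {
  pot <- ec50_pointwise(10^seq(-9, -5), rep(0, 5))
  expect_identical(pot$display, "NR")
  expect_true(is.na(pot$value))
})

test_that("a curve saturating below the ladder censors toward lower concentrations", {
  conc <- dilution_preset("permeabilized_extended")$values
  # simulated potency two decades below the lowest tested dose
  y <- 100 * (1 - hill_fraction(conc, min(conc) / 100, 1))
  fit <- fit_hill4(conc, y, "decreasing")
  pot <- ic50_from_fit(fit, max(conc), lowest_tested = min(conc))
  expect_identical(pot$censored, "below_lowest_tested")
  expect_identical(pot$display, sprintf("< %.2f", log10(min(conc))))
  # without the lowest-tested bound the legacy behavior is unchanged
  expect_identical(ic50_from_fit(fit, max(conc))$censored, "above_top_tested")
})

test_that("potency rendering covers every censoring state", {
  expect_identical(render_potency(-6.62), "-6.62")
  expect_identical(render_potency(-5, "above_top_tested"), "> -5.00")
  expect_identical(render_potency(-8.8, "below_lowest_tested"), "< -8.80")
  expect_identical(render_potency(NA_real_, "not_tested"), "NT")
  expect_identical(render_potency(NA_real_, "no_response"), "NR")
  expect_error(render_potency(1, "weird"), class = "mitoscreen_domain_error")
  expect_output(print(potency_result(-6, "none", "IC50")), "-6.00")
})

test_that("Dunnett LOEC detects a forced top-dose effect", {
  set.seed(31)
  groups <- list(
    "1e-07" = rnorm(6, 100, 5),
    "1e-06" = rnorm(6, 100, 5),
    "1e-05" = rnorm(6, 100 - 25, 5) # 5 SD shift at the top dose
  )
  res <- dunnett_loec(groups, vehicle = rnorm(6, 100, 5))
  expect_equal(res$loec, 1e-05)
  expect_identical(res$flags$significant, c(FALSE, FALSE, TRUE))
})

test_that("Dunnett LOEC requires replicated groups and numeric names", {
  expect_error(
    dunnett_loec(list("1e-06" = 5), vehicle = c(1, 2)),
    class = "mitoscreen_domain_error"
  )
  expect_error(
    dunnett_loec(list(low = c(1, 2)), vehicle = c(1, 2)),
    class = "mitoscreen_domain_error"
  )
})

test_that("Dunnett adjustment never creates significance absent unadjusted evidence", {
  set.seed(77)
  for (rep in 1:20) {
    groups <- setNames(
      lapply(1:4, function(i) rnorm(5, 100 + (i == 4) * runif(1, 0, 15), 6)),
      10^-(7:4)
    )
    vehicle <- rnorm(6, 100, 6)
    res <- dunnett_loec(groups, vehicle)
    # pooled-variance unadjusted many-to-one p-values
    df <- data.frame(
      value = c(vehicle, unlist(groups)),
      group = factor(
        rep(c("control", names(groups)), times = c(length(vehicle), lengths(groups))),
        levels = c("control", names(groups))
      )
    )
    gl <- multcomp::glht(stats::aov(value ~ group, data = df),
      linfct = multcomp::mcp(group = "Dunnett")
    )
    p_unadj <- as.numeric(summary(gl, test = multcomp::adjusted("none"))$test$pvalues)
    flagged <- res$flags$significant
    expect_true(all(!flagged | (p_unadj < 0.05)))
  }
})
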