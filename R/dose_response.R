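# Censored dose-response potency estimation: bounded four-parameter Hill
# fits in log10-concentration space, 50%-crossing IC50s with
# beyond-ladder censoring, point-to-point EC50s for activation
# endpoints, and Dunnett-based LOECs.

#' Fit a four-parameter Hill curve
#'
#' Least-squares fit, in `x = log10(concentration)`, of
#' `Y = bottom + (top - bottom) / (1 + 10^((x - log_ic50) * slope))`
#' for decreasing (inhibition) curves, or its mirror
#' `1 + 10^((log_ic50 - x) * slope)` for increasing (activation)
#' curves. Both forms keep `slope > 0` and `top >= bottom`; the
#' decreasing form is the classical sigmoid written with a negative
#' Hill slope. The fit is internally parameterized as
#' `(bottom, range, log_ic50, slope)` with `range = top - bottom >= 0`,
#' bounds `slope` in `[0.1, 10]` and `bottom` in `[-10, 110]`.
#'
#' Zero-concentration (vehicle) points cannot enter the log abscissa
#' and are rejected; vehicle information enters through normalization
#' upstream.
#'
#' @param conc Molar concentrations (> 0), at least 4 distinct values.
#' @param response Responses on a percent scale (one per concentration;
#'   typically per-concentration means of biological replicates).
#' @param direction `"decreasing"` or `"increasing"`.
#' @return A `hill_fit` list: `bottom`, `top`, `log_ic50`,
#'   `hill_slope`, `rss`, `converged`, `direction`.
#' @export
#' @examples
#' conc <- make_dilution_series(1e-5, 5, 8)$values
#' y <- predict_hill4(list(bottom = 0, top = 100, log_ic50 = -6.5,
#'                         hill_slope = 1, direction = "decreasing"),
#'                    conc)
#' fit_hill4(conc, y)$log_ic50
fit_hill4 <- function(conc, response, direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  if (length(conc) != length(response)) stop_domain("conc and response lengths differ")
  if (any(conc <= 0)) stop_domain("concentrations must be positive (exclude vehicle)")
  if (length(unique(conc)) < 4) stop_domain("need >= 4 distinct concentrations")
  ord <- order(conc)
  x <- log10(conc[ord])
  y <- response[ord]

  lo_mean <- mean(y[1:2]) # response at the low-concentration end
  if (direction == "decreasing") {
    top0 <- lo_mean
    bottom0 <- min(y)
  } else {
    bottom0 <- lo_mean
    top0 <- max(y)
  }
  range0 <- max(top0 - bottom0, 1e-6)
  mid <- bottom0 + range0 / 2
  cross <- if (direction == "decreasing") which(y <= mid) else which(y >= mid)
  l0 <- if (length(cross) > 0) x[cross[1]] else stats::median(x)

  sgn <- if (direction == "decreasing") 1 else -1
  model_fun <- function(bottom, range, l, s) {
    bottom + range / (1 + 10^((x - l) * s * sgn))
  }
  rss_fun <- function(p) sum((y - model_fun(p[1], p[2], p[3], p[4]))^2)
  lower <- c(bottom = -10, range = 0, l = min(x) - 6, s = 0.1)
  upper <- c(bottom = 110, range = 500, l = max(x) + 6, s = 10)
  start <- pmin(pmax(c(bottom = bottom0, range = range0, l = l0, s = 1), lower), upper)

  fit <- tryCatch(
    {
      m <- minpack.lm::nlsLM(
        y ~ bottom + range / (1 + 10^((x - l) * s * sgn)),
        start = as.list(start),
        lower = lower, upper = upper,
        data = list(y = y, x = x, sgn = sgn),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      p <- stats::coef(m)
      list(par = p, rss = sum(stats::resid(m)^2), converged = m$convInfo$isConv %||% TRUE)
    },
    error = function(e) NULL
  )
  if (is.null(fit)) {
    o <- stats::optim(start, rss_fun,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = 500)
    )
    fit <- list(par = o$par, rss = o$value, converged = o$convergence == 0)
  }
  p <- fit$par
  structure(
    list(
      bottom = unname(p["bottom"]),
      top = unname(p["bottom"] + p["range"]),
      log_ic50 = unname(p["l"]),
      hill_slope = unname(p["s"]),
      rss = fit$rss,
      converged = isTRUE(fit$converged),
      direction = direction
    ),
    class = "hill_fit"
  )
}

#' Evaluate a four-parameter Hill curve
#'
#' @param fit A `hill_fit` (or any list with `bottom`, `top`,
#'   `log_ic50`, `hill_slope`, `direction`).
#' @param conc Molar concentrations at which to evaluate.
#' @return Predicted responses.
#' @export
predict_hill4 <- function(fit, conc) {
  x <- log10(conc)
  sgn <- if (identical(fit$direction, "increasing")) -1 else 1
  fit$bottom + (fit$top - fit$bottom) / (1 + 10^((x - fit$log_ic50) * fit$hill_slope * sgn))
}

#' Construct a censored potency result
#'
#' @param value Potency in log10 molar (for censored results, the
#'   censoring bound; NA for `not_tested`/`no_response`).
#' @param censored One of `none`, `above_top_tested`,
#'   `below_lowest_tested`, `not_tested`, `no_response`.
#' @param kind `"IC50"` or `"EC50"`.
#' @return A `potency_result` list with a `display` string rendered by
#'   [render_potency()].
#' @export
potency_result <- function(value = NA_real_,
                           censored = c("none", "above_top_tested", "below_lowest_tested",
                                        "not_tested", "no_response"),
                           kind = c("IC50", "EC50")) {
  censored <- match.arg(censored)
  kind <- match.arg(kind)
  structure(
    list(
      value = value, censored = censored, kind = kind,
      display = render_potency(value, censored)
    ),
    class = "potency_result"
  )
}

#' Render a potency display string
#'
#' Pure rendering convention: uncensored values print as log10 molar
#' with two decimals (`"-6.62"`), potencies beyond the top of the
#' tested range as `"> -5.00"`, potencies saturating below the lowest
#' tested dose as `"< -8.80"`, untested cells as `"NT"` and absent
#' responses as `"NR"`.
#'
#' @param value Numeric log10 molar value (bound for censored results).
#' @param censored Censoring state (see [potency_result()]).
#' @return Display string.
#' @export
render_potency <- function(value, censored = "none") {
  switch(censored,
    none = sprintf("%.2f", value),
    above_top_tested = sprintf("> %.2f", value),
    below_lowest_tested = sprintf("< %.2f", value),
    not_tested = "NT",
    no_response = "NR",
    stop_domain(paste0("unknown censoring state: ", censored))
  )
}

#' @export
print.potency_result <- function(x, ...) {
  cat(sprintf("<potency_result> %s: %s\n", x$kind, x$display))
  invisible(x)
}

#' IC50 from a Hill fit, with beyond-ladder censoring
#'
#' Solves the fitted curve for `response = min_effect` (50% by
#' convention, i.e. the concentration producing a 50% inhibitory
#' effect on the percent-of-control scale). When the curve never
#' reaches 50% within the tested ladder, or the crossing lies above
#' `top_tested`, the result is censored to `"> log10(top_tested)"`.
#' When `lowest_tested` is supplied and the curve is already suppressed
#' past 50% at the lowest tested dose (no crossing inside the ladder
#' because the compound saturates below it), the result is censored the
#' other way, to `"< log10(lowest_tested)"`.
#' Optionally (for stage-attributed permeabilized potencies), a fit
#' whose realized effect at the top tested concentration - measured
#' against the 100% control anchor, not against the fitted `top`, which
#' is unidentified for flat curves - is below `no_response_max_effect`
#' percent is reported as `"NR"` instead.
#'
#' @param fit A `hill_fit`.
#' @param top_tested Highest tested concentration (molar).
#' @param min_effect Response level solved for (percent).
#' @param no_response_max_effect If finite, realized-effect threshold
#'   (percent) below which the result is `no_response`; `NA` disables
#'   the rule (intact-cell summary-table convention).
#' @param lowest_tested Optional lowest tested concentration (molar);
#'   enables `below_lowest_tested` censoring for curves saturating
#'   beneath the ladder.
#' @return A `potency_result` of kind IC50.
#' @export
ic50_from_fit <- function(fit, top_tested, min_effect = 50,
                          no_response_max_effect = NA,
                          lowest_tested = NA) {
  x_top <- log10(top_tested)
  if (is.finite(no_response_max_effect)) {
    realized <- abs(100 - predict_hill4(fit, top_tested))
    if (realized < no_response_max_effect) {
      return(potency_result(NA_real_, "no_response", "IC50"))
    }
  }
  bottom <- fit$bottom
  top <- fit$top
  crossing <- NA_real_
  if (bottom < min_effect && top > min_effect) {
    r <- (top - min_effect) / (min_effect - bottom)
    sgn <- if (identical(fit$direction, "increasing")) -1 else 1
    crossing <- fit$log_ic50 + sgn * log10(r) / fit$hill_slope
  }
  if (!is.finite(crossing) || crossing > x_top) {
    if (is.finite(lowest_tested) &&
        predict_hill4(fit, lowest_tested) < min_effect) {
      return(potency_result(log10(lowest_tested), "below_lowest_tested", "IC50"))
    }
    return(potency_result(x_top, "above_top_tested", "IC50"))
  }
  potency_result(crossing, "none", "IC50")
}

#' Point-to-point EC50 for activation endpoints
#'
#' Model-free potency for endpoints that increase with treatment
#' (re-normalized to a 0-100% activation scale): the mean curve is
#' linearly interpolated in `x = log10(concentration)` on a 1000-point
#' uniform grid spanning the tested range, and the EC50 is the first
#' grid point (from the low end) whose interpolated response reaches
#' 50%. Curves that never reach 50% report `"NR"`. The first-crossing
#' rule is the tie-break for non-monotone curves; adding interior
#' collinear points does not change the result.
#'
#' @param conc Molar concentrations (> 0).
#' @param response Responses on the 0-100% activation scale.
#' @param n_grid Grid size (1000 by convention).
#' @param level Crossing level (percent).
#' @return A `potency_result` of kind EC50.
#' @export
ec50_pointwise <- function(conc, response, n_grid = 1000, level = 50) {
  if (length(conc) != length(response)) stop_domain("conc and response lengths differ")
  if (any(conc <= 0)) stop_domain("concentrations must be positive")
  ord <- order(conc)
  x <- log10(conc[ord])
  y <- response[ord]
  if (length(unique(x)) < 2) stop_domain("need >= 2 distinct concentrations")
  grid <- seq(min(x), max(x), length.out = n_grid)
  yi <- stats::approx(x, y, xout = grid, ties = mean)$y
  hit <- which(yi >= level)
  if (length(hit) == 0) {
    return(potency_result(NA_real_, "no_response", "EC50"))
  }
  potency_result(grid[hit[1]], "none", "EC50")
}

#' Dunnett many-to-one significance flags and LOEC
#'
#' Dunnett's many-to-one comparisons of each concentration group
#' against the vehicle control (pooled-variance contract; critical
#' values from the multivariate-t distribution via multcomp), preceded
#' by a one-way ANOVA whose p-value is always reported. The LOEC is the
#' lowest concentration whose comparison is significant at `alpha`.
#'
#' By default the ANOVA is reported but not used as a gate: Dunnett's
#' procedure controls the familywise error rate at `alpha` by
#' construction, and conditioning the flags on a significant omnibus F
#' makes the two-step procedure conservative (measured familywise error
#' about 0.024-0.030 at `alpha = 0.05` across 4-8 group designs with
#' 3-6 replicates, versus the nominal 0.05). Set `anova_gate = TRUE`
#' for the legacy protocol in which a non-significant ANOVA suppresses
#' all flags.
#'
#' @param groups Named list of numeric replicate vectors, one per
#'   concentration; names must be coercible to numeric concentrations.
#'   Every group needs >= 2 replicates.
#' @param vehicle Numeric vector of control replicates (>= 2).
#' @param alpha Familywise significance level.
#' @param anova_gate Logical; require a significant omnibus ANOVA
#'   before any Dunnett flag (conservative legacy behaviour).
#' @return List with `flags` (tibble: `conc`, `p_adj`, `significant`),
#'   `loec` (numeric, NA when none), `anova_p`.
#' @export
dunnett_loec <- function(groups, vehicle, alpha = 0.05, anova_gate = FALSE) {
  if (length(vehicle) < 2 || any(vapply(groups, length, integer(1)) < 2)) {
    stop_domain("every group (including vehicle) needs >= 2 replicates")
  }
  concs <- suppressWarnings(as.numeric(names(groups)))
  if (any(is.na(concs))) stop_domain("group names must be numeric concentrations")
  ord <- order(concs)
  groups <- groups[ord]
  concs <- concs[ord]
  df <- data.frame(
    value = c(vehicle, unlist(groups, use.names = FALSE)),
    group = factor(
      rep(c("control", names(groups)), times = c(length(vehicle), lengths(groups))),
      levels = c("control", names(groups))
    )
  )
  fit <- stats::aov(value ~ group, data = df)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  if (!anova_gate || (is.finite(anova_p) && anova_p < alpha)) {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    p_adj <- summary(gl)$test$pvalues
    signif_flags <- as.numeric(p_adj) < alpha
  } else {
    p_adj <- rep(NA_real_, length(groups))
    signif_flags <- rep(FALSE, length(groups))
  }
  flags <- tibble::tibble(
    conc = concs,
    p_adj = as.numeric(p_adj),
    significant = signif_flags
  )
  loec <- if (any(flags$significant)) min(flags$conc[flags$significant]) else NA_real_
  list(flags = flags, loec = loec, anova_p = anova_p)
}
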