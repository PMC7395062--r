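# Internal helpers shared across modules.

# Abort with a classed condition so callers/tests can distinguish
# format errors (malformed files) from validation errors (bad content)
# and domain errors (bad arguments).
stop_format <- function(msg) rlang::abort(msg, class = "mitoscreen_format_error")
stop_validation <- function(msg) rlang::abort(msg, class = "mitoscreen_validation_error")
stop_domain <- function(msg) rlang::abort(msg, class = "mitoscreen_domain_error")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Local RNG scope: runs `expr` under `seed` without disturbing the caller's
# RNG state. All simulator randomness goes through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Multiplicative lognormal noise with unit mean and coefficient of
# variation `cv` (cv = 0 returns exact 1s).
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Format a molar potency as log10 molar with two decimals
#'
#' Display convention used in compound-by-endpoint summary tables:
#' potencies are reported in log10 molar units rounded to two decimals
#' (e.g. `1e-6` M becomes `"-6.00"`).
#'
#' @param molar Numeric vector of molar concentrations (> 0).
#' @return Character vector of formatted log10 molar values.
#' @export
#' @examples
#' format_log10M(c(1e-5, 2.57e-4))
format_log10M <- function(molar) {
  if (any(molar <= 0, na.rm = TRUE)) {
    stop_domain("molar concentrations must be positive to take log10")
  }
  sprintf("%.2f", log10(molar))
}
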