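## A-priori power for MR with a binary outcome.

#' Specify a power calculation
#'
#' @param r2 Proportion of exposure variance explained by the instrument,
#'   in (0, 1).
#' @param n_cases,n_controls Outcome case and control counts.
#' @param alpha Two-sided significance level; default 0.05.
#' @param power Target power; default 0.80.
#' @return Object of class `power_spec`.
#' @export
power_spec <- function(r2, n_cases, n_controls, alpha = 0.05,
                       power = 0.80) {
  stopifnot(r2 > 0, r2 < 1, n_cases > 0, n_controls > 0,
            alpha > 0, alpha < 1, power > 0, power < 1)
  structure(list(r2 = r2, n_cases = n_cases, n_controls = n_controls,
                 alpha = alpha, power = power), class = "power_spec")
}

#' Minimum detectable odds ratio for an MR design
#'
#' The smallest odds ratio (per SD of exposure) detectable at two-sided
#' level `alpha` with the target power, given the instrument strength and
#' case-control design:
#' \deqn{OR_{min} = \exp\left[\frac{z_{1-\alpha/2} + z_{power}}
#'   {\sqrt{N\, r^2\, p(1-p)}}\right]}
#' with `N = n_cases + n_controls` and case fraction `p`. The asymptotic
#' variance of the causal log OR is `1 / (N r2 p(1-p))`, the standard
#' summary-level approximation for a binary outcome.
#'
#' @param spec A [power_spec()], or `r2` directly with the design given in
#'   `...` (forwarded to [power_spec()]).
#' @param ... Design arguments when `spec` is a bare `r2` value.
#' @return The minimum detectable OR (always > 1).
#' @examples
#' min_detectable_or(power_spec(0.06, 25042, 34915))  # ~1.10
#' @export
min_detectable_or <- function(spec, ...) {
  if (!inherits(spec, "power_spec")) spec <- power_spec(spec, ...)
  n <- spec$n_cases + spec$n_controls
  p <- spec$n_cases / n
  if (p <= 0 || p >= 1)
    stop("min_detectable_or: degenerate case fraction", call. = FALSE)
  z <- stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$power)
  exp(z / sqrt(n * spec$r2 * p * (1 - p)))
}

#' Power to detect a given odds ratio
#'
#' Inverse of [min_detectable_or()]:
#' `power = Phi(|ln OR| sqrt(N r2 p(1-p)) - z_{1-alpha/2})`, monotone
#' increasing in the effect size, sample size and instrument strength.
#'
#' @inheritParams min_detectable_or
#' @param or_alt Alternative-hypothesis odds ratio (> 0). At `or_alt = 1`
#'   the formula degenerates to the one-sided rejection probability
#'   `alpha / 2`, returned by convention.
#' @return Power in (0, 1).
#' @export
power_at_or <- function(spec, or_alt, ...) {
  if (!inherits(spec, "power_spec")) spec <- power_spec(spec, ...)
  stopifnot(or_alt > 0)
  n <- spec$n_cases + spec$n_controls
  p <- spec$n_cases / n
  stats::pnorm(abs(log(or_alt)) * sqrt(n * spec$r2 * p * (1 - p)) -
                 stats::qnorm(1 - spec$alpha / 2))
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf(
    "MR power design: r2 = %g, %d cases / %d controls, alpha = %g\n",
    x$r2, x$n_cases, x$n_controls, x$alpha))
  cat(sprintf("  minimum detectable OR at %.0f%% power: %.2f\n",
              100 * x$power, min_detectable_or(x)))
  invisible(x)
}

#' Power report for a set of instruments against one outcome design
#'
#' @param r2 Named vector of instrument variances explained.
#' @param n_cases,n_controls Outcome design.
#' @param alpha,power Passed to [power_spec()].
#' @return Data frame with one row per instrument: `exposure`, `r2`,
#'   `min_detectable_or`.
#' @export
power_table <- function(r2, n_cases, n_controls, alpha = 0.05,
                        power = 0.80) {
  mdor <- vapply(r2, function(v)
    min_detectable_or(power_spec(v, n_cases, n_controls, alpha, power)),
    numeric(1))
  data.frame(exposure = if (is.null(names(r2)))
               paste0("exposure", seq_along(r2)) else names(r2),
             r2 = unname(r2), n_cases = n_cases, n_controls = n_controls,
             min_detectable_or = unname(mdor),
             stringsAsFactors = FALSE, row.names = NULL)
}
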