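## Fixed-effect heterogeneity between two disease-subtype causal estimates.

#' Heterogeneity between CD and UC causal estimates
#'
#' Fixed-effect Q test on one degree of freedom comparing two causal
#' estimates of the same exposure on two disease subtypes. The pooled
#' effect is the inverse-variance-weighted mean
#' `theta_bar = (theta_1/se_1^2 + theta_2/se_2^2) / (1/se_1^2 + 1/se_2^2)`
#' and `Q = (theta_1 - theta_bar)^2/se_1^2 + (theta_2 - theta_bar)^2/se_2^2`
#' is referred to a chi-square with 1 df.
#'
#' @param est_cd,est_uc The two estimates: either `mr_fit` objects or
#'   lists/vectors with elements `theta` and `se` on the log-odds scale.
#'   If either is `NA` (e.g. a method not estimable on a 2-SNP
#'   instrument), the test is recorded as `NA` rather than computed
#'   one-sided.
#' @return Object of class `subtype_het`: list with `q`, `df` (always 1),
#'   `pvalue`, `pooled`.
#' @examples
#' cd <- estimate_from_or_ci(1.22, 1.09, 1.37)
#' uc <- estimate_from_or_ci(0.90, 0.81, 1.01)
#' disease_heterogeneity(cd, uc)
#' @export
disease_heterogeneity <- function(est_cd, est_uc) {
  get_ts <- function(e) {
    if (length(e) == 1L && is.na(e[[1]])) return(NULL)
    c(theta = as.numeric(e[["theta"]]), se = as.numeric(e[["se"]]))
  }
  cd <- get_ts(est_cd); uc <- get_ts(est_uc)
  if (is.null(cd) || is.null(uc) || any(is.na(c(cd, uc))))
    return(structure(list(q = NA_real_, df = 1L, pvalue = NA_real_,
                          pooled = NA_real_), class = "subtype_het"))
  if (cd["se"] <= 0 || uc["se"] <= 0)
    stop("disease_heterogeneity: standard errors must be positive",
         call. = FALSE)
  w <- c(1 / cd["se"]^2, 1 / uc["se"]^2)
  th <- c(cd["theta"], uc["theta"])
  pooled <- sum(w * th) / sum(w)
  q <- sum(w * (th - pooled)^2)
  structure(list(q = unname(q), df = 1L,
                 pvalue = stats::pchisq(unname(q), 1, lower.tail = FALSE),
                 pooled = unname(pooled)),
            class = "subtype_het")
}

#' Reconstruct a log-scale estimate from a printed OR and 95% CI
#'
#' Published MR results usually print the odds ratio with its 95%
#' confidence interval; the log OR and its SE are recovered as
#' `theta = ln(OR)` and `se = (ln(hi) - ln(lo)) / (2 * 1.96)`.
#'
#' @param or Odds ratio.
#' @param ci_low,ci_high 95% confidence bounds.
#' @return List with `theta` and `se`.
#' @export
estimate_from_or_ci <- function(or, ci_low, ci_high) {
  stopifnot(or > 0, ci_low > 0, ci_high > ci_low)
  list(theta = log(or),
       se = (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975)))
}

#' @export
print.subtype_het <- function(x, ...) {
  if (is.na(x$q)) cat("Subtype heterogeneity: NA (estimate missing)\n")
  else cat(sprintf(
    "Subtype heterogeneity: Q = %.4g on %d df, p = %.3g (pooled log OR %.3f)\n",
    x$q, x$df, x$pvalue, x$pooled))
  invisible(x)
}
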