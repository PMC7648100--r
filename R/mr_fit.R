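## Causal-effect estimators for a harmonized instrument.
##
## All estimators return an "mr_fit" object: theta is the causal log odds
## ratio per SD of the exposure, with normal-theory 95% CI
## (theta +/- 1.96 se) and a two-sided z p-value.

#' Per-SNP Wald ratios
#'
#' The Wald ratio for SNP j is the outcome effect divided by the exposure
#' effect, `y_j / x_j`. Its first-order standard error is `sy_j / |x_j|`;
#' the second-order delta expansion additionally carries the exposure
#' uncertainty, `sqrt(sy_j^2 / x_j^2 + y_j^2 sx_j^2 / x_j^4)`.
#'
#' @param inst An [mr_instrument()].
#' @param se_order `"first"` (default) or `"second"`.
#' @return Data frame with columns `rsid`, `theta`, `se`.
#' @export
wald_ratios <- function(inst, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  if (any(inst$x == 0))
    stop("wald_ratios: zero exposure effect for SNP(s) ",
         paste(inst$rsid[inst$x == 0], collapse = ", "),
         "; instrument is degenerate", call. = FALSE)
  theta <- inst$y / inst$x
  se <- if (se_order == "first") inst$sy / abs(inst$x)
        else sqrt(inst$sy^2 / inst$x^2 + inst$y^2 * inst$sx^2 / inst$x^4)
  data.frame(rsid = inst$rsid, theta = theta, se = se,
             stringsAsFactors = FALSE)
}

new_mr_fit <- function(method, theta, se, n_snp, inst = NULL,
                       extra = list()) {
  z <- theta / se
  out <- c(list(method = method, theta = theta, se = se,
                ci_low = theta - stats::qnorm(0.975) * se,
                ci_high = theta + stats::qnorm(0.975) * se,
                pvalue = 2 * stats::pnorm(-abs(z)),
                n_snp = n_snp, instrument = inst),
           extra)
  class(out) <- c(paste0("mr_", method), "mr_fit")
  out
}

#' Fit a two-sample MR causal effect
#'
#' Combines the per-SNP exposure and outcome effects of a harmonized
#' instrument into one causal log odds ratio per SD of exposure.
#'
#' Methods:
#' \describe{
#'   \item{`"ml"`}{Likelihood-based estimator (the headline method). The
#'     observed effects are modelled as `x_j ~ N(xi_j, sx_j^2)` and
#'     `y_j ~ N(theta * xi_j, sy_j^2)`, independently; maximizing over the
#'     nuisance true effects `xi_j` profiles the likelihood down to
#'     minimizing `sum_j (y_j - theta x_j)^2 / (sy_j^2 + theta^2 sx_j^2)`
#'     in `theta`. The SE comes from the observed information of the
#'     profile log-likelihood.}
#'   \item{`"ivw"`}{Inverse-variance-weighted: zero-intercept regression of
#'     `y` on `x` with weights `1/sy^2`, fixed-effect SE. Requires 2 SNPs.}
#'   \item{`"egger"`}{MR-Egger: weighted regression `y = alpha + theta x`
#'     after orienting every SNP to `x_j >= 0`; the intercept `alpha`
#'     estimates directional pleiotropy and its z-test is reported as
#'     `intercept_p`. SEs carry the multiplicative random-effects
#'     inflation `max(1, sigma)` so balanced pleiotropy widens rather
#'     than biases the test. Requires 3 SNPs.}
#'   \item{`"weighted_median"`}{Weighted median of the Wald ratios with
#'     inverse-variance weights; SE by parametric bootstrap. Requires 3
#'     SNPs.}
#'   \item{`"mode"`}{Mode of the weighted kernel density of the Wald
#'     ratios (modified Silverman bandwidth scaled by `phi`); SE by
#'     parametric bootstrap. Requires 3 SNPs.}
#'   \item{`"wald"`}{Single-SNP Wald ratio (J = 1 only).}
#' }
#'
#' @param inst An [mr_instrument()].
#' @param method Estimator name; see Details.
#' @param n_boot Bootstrap replicates for the median/mode SE (default
#'   1000).
#' @param seed Seed for the bootstrap; mandatory for the resampling
#'   methods so results are reproducible.
#' @param phi Bandwidth multiplier for the mode estimator (default 1).
#' @param se_order Wald-ratio SE order for ratio-based methods.
#' @return An object of class `mr_fit` (for `"egger"`, additionally
#'   `mr_egger` with `intercept`, `intercept_se`, `intercept_p`).
#' @examples
#' set.seed(1)
#' inst <- mr_instrument(x = runif(10, 0.05, 0.2), sx = rep(0.005, 10),
#'                       y = runif(10, 0.05, 0.2) * 0.5,
#'                       sy = rep(0.02, 10))
#' mr_fit(inst, "ml")
#' @export
mr_fit <- function(inst, method = c("ml", "ivw", "egger",
                                    "weighted_median", "mode", "wald"),
                   n_boot = 1000L, seed = NULL, phi = 1,
                   se_order = c("first", "second")) {
  method <- match.arg(method)
  se_order <- match.arg(se_order)
  switch(method,
    ml = ml_estimate(inst),
    ivw = ivw_estimate(inst),
    egger = egger_estimate(inst),
    weighted_median = weighted_median_estimate(inst, n_boot = n_boot,
                                               seed = seed,
                                               se_order = se_order),
    mode = mode_estimate(inst, phi = phi, n_boot = n_boot, seed = seed,
                         se_order = se_order),
    wald = {
      if (n_snp(inst) != 1L)
        stop("mr_fit: method 'wald' is for single-SNP instruments",
             call. = FALSE)
      wr <- wald_ratios(inst, se_order = se_order)
      new_mr_fit("wald", wr$theta, wr$se, 1L, inst)
    })
}

## ---- likelihood-based (profile ML) ------------------------------------

ml_profile_objective <- function(theta, x, sx, y, sy) {
  sum((y - theta * x)^2 / (sy^2 + theta^2 * sx^2))
}

#' @rdname mr_fit
#' @export
ml_estimate <- function(inst) {
  x <- inst$x; sx <- inst$sx; y <- inst$y; sy <- inst$sy
  if (any(x == 0))
    stop("ml_estimate: zero exposure effect for SNP(s) ",
         paste(inst$rsid[x == 0], collapse = ", "), call. = FALSE)
  obj <- function(th) ml_profile_objective(th, x, sx, y, sy)
  ratios <- y / x
  lo <- min(ratios) - 1; hi <- max(ratios) + 1
  # widen until the minimizer is interior (profile objective is smooth and
  # tends to a finite limit at +/-Inf, so an interior minimum exists)
  for (i in 1:50) {
    opt <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
    margin <- 1e-6 * (hi - lo)
    if (opt$minimum - lo > margin && hi - opt$minimum > margin) break
    lo <- lo - (hi - lo); hi <- hi + (hi - lo)
    if (i == 50)
      stop("ml_estimate: profile optimization did not converge ",
           "(final bracket [", lo, ", ", hi, "])", call. = FALSE)
  }
  theta <- opt$minimum
  # -2 logL = objective (up to a constant), so the observed information of
  # the profile log-likelihood is g''(theta)/2.
  h <- 1e-4 * (1 + abs(theta))
  g2 <- (obj(theta + h) - 2 * obj(theta) + obj(theta - h)) / h^2
  if (!is.finite(g2) || g2 <= 0)
    stop("ml_estimate: non-positive curvature at the optimum; ",
         "cannot form a standard error", call. = FALSE)
  new_mr_fit("ml", theta, sqrt(2 / g2), n_snp(inst), inst)
}

## ---- IVW ---------------------------------------------------------------

#' @rdname mr_fit
#' @export
ivw_estimate <- function(inst) {
  J <- n_snp(inst)
  if (J < 2L)
    stop("ivw_estimate: at least 2 SNPs required", call. = FALSE)
  w <- 1 / inst$sy^2
  sxx <- sum(w * inst$x^2)
  theta <- sum(w * inst$x * inst$y) / sxx
  new_mr_fit("ivw", theta, sqrt(1 / sxx), J, inst)
}

## ---- MR-Egger ----------------------------------------------------------

#' @rdname mr_fit
#' @export
egger_estimate <- function(inst) {
  J <- n_snp(inst)
  if (J < 3L)
    stop("egger_estimate: at least 3 SNPs required", call. = FALSE)
  sgn <- ifelse(inst$x < 0, -1, 1)       # orient exposure effects positive
  x <- sgn * inst$x; y <- sgn * inst$y
  w <- 1 / inst$sy^2
  # weighted normal equations for y = alpha + theta x, fixed-effect SEs
  sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  if (det <= 0)
    stop("egger_estimate: degenerate design (constant exposure effects)",
         call. = FALSE)
  theta <- (sw * swxy - swx * swy) / det
  alpha <- (swxx * swy - swx * swxy) / det
  # multiplicative random-effects inflation: residual overdispersion
  # beyond the outcome SEs (pleiotropy spread) widens both SEs, but the
  # fit is never allowed to claim less noise than the SEs imply
  rss <- sum(w * (y - alpha - theta * x)^2)
  sigma <- max(1, sqrt(rss / (J - 2)))
  se_theta <- sigma * sqrt(sw / det)
  se_alpha <- sigma * sqrt(swxx / det)
  fit <- new_mr_fit("egger", theta, se_theta, J, inst,
                    extra = list(
                      intercept = alpha,
                      intercept_se = se_alpha,
                      intercept_p = 2 * stats::pnorm(-abs(alpha / se_alpha))))
  fit
}

## ---- weighted median ---------------------------------------------------

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(theta[1])
  if (p[length(p)] <= 0.5) return(theta[length(theta)])
  stats::approx(p, theta, xout = 0.5, ties = "ordered")$y
}

#' @rdname mr_fit
#' @export
weighted_median_estimate <- function(inst, n_boot = 1000L, seed = NULL,
                                     se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  J <- n_snp(inst)
  if (J < 3L)
    stop("weighted_median_estimate: at least 3 SNPs required",
         call. = FALSE)
  wr <- wald_ratios(inst, se_order)
  w <- 1 / wr$se^2
  theta <- weighted_median_point(wr$theta, w)
  se <- ratio_bootstrap_se(inst, n_boot, seed, se_order,
                           function(th, wt) weighted_median_point(th, wt))
  new_mr_fit("weighted_median", theta, se, J, inst)
}

## ---- mode-based estimate ----------------------------------------------

weighted_sd <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  sqrt(sum(w * (x - m)^2))
}

## weighted MAD with normal-consistency handled by the caller
weighted_mad <- function(x, w) {
  weighted_median_point(abs(x - weighted_median_point(x, w)), w)
}

mode_bandwidth <- function(theta, w, phi) {
  s <- weighted_sd(theta, w)
  m <- weighted_mad(theta, w) / 0.6745
  spread <- if (m > 0) min(s, m) else s
  phi * 0.9 * spread * length(theta)^(-1 / 5)
}

mode_point <- function(theta, w, phi, n_grid = 1e5L) {
  w <- w / sum(w)
  h <- mode_bandwidth(theta, w, phi)
  if (!is.finite(h) || h <= 0) return(theta[1])   # all ratios identical
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = n_grid)
  dens <- colSums(w * stats::dnorm(outer(theta, grid, "-") / h))
  grid[which.max(dens)]
}

#' @rdname mr_fit
#' @export
mode_estimate <- function(inst, phi = 1, n_boot = 1000L, seed = NULL,
                          se_order = c("first", "second"),
                          n_grid = 1e5L) {
  se_order <- match.arg(se_order)
  J <- n_snp(inst)
  if (J < 3L)
    stop("mode_estimate: at least 3 SNPs required", call. = FALSE)
  stopifnot(phi > 0)
  wr <- wald_ratios(inst, se_order)
  w <- 1 / wr$se^2
  h <- mode_bandwidth(wr$theta, w / sum(w), phi)
  if (!is.finite(h) || h <= 0) {
    # all ratios identical: the density is a point mass
    return(new_mr_fit("mode", wr$theta[1], 0, J, inst))
  }
  theta <- mode_point(wr$theta, w, phi, n_grid)
  se <- ratio_bootstrap_se(inst, n_boot, seed, se_order,
                           function(th, wt)
                             mode_point(th, wt, phi, n_grid = 1e4L))
  new_mr_fit("mode", theta, se, J, inst)
}

## Parametric bootstrap over the summary statistics: redraw x*, y* from
## their sampling distributions, recompute ratios, weights, and the point
## estimate.
ratio_bootstrap_se <- function(inst, n_boot, seed, se_order, point_fun) {
  if (is.null(seed))
    stop("a bootstrap seed is required for reproducible SEs", call. = FALSE)
  if (n_boot < 1L) return(NA_real_)
  J <- n_snp(inst)
  est <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      xb <- stats::rnorm(J, inst$x, inst$sx)
      yb <- stats::rnorm(J, inst$y, inst$sy)
      th <- yb / xb
      se <- if (se_order == "first") inst$sy / abs(xb)
            else sqrt(inst$sy^2 / xb^2 + yb^2 * inst$sx^2 / xb^4)
      point_fun(th, 1 / se^2)
    }, numeric(1))
  })
  stats::sd(est)
}

## Evaluate expr under a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## ---- Cochran Q ---------------------------------------------------------

#' Cochran Q heterogeneity across per-SNP Wald ratios
#'
#' `Q = sum_j w_j (theta_j - theta_ivw)^2` with inverse-variance weights
#' `w_j = (x_j / sy_j)^2`, referred to a chi-square with `J - 1` degrees of
#' freedom. Large Q signals that the SNPs do not estimate a common causal
#' effect (heterogeneity / pleiotropy).
#'
#' @param inst An [mr_instrument()] with at least 2 SNPs.
#' @return Object of class `mr_q`: list with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(inst) {
  J <- n_snp(inst)
  if (J < 2L)
    stop("cochran_q: at least 2 SNPs required", call. = FALSE)
  wr <- wald_ratios(inst, "first")
  w <- (inst$x / inst$sy)^2
  theta_ivw <- ivw_estimate(inst)$theta
  q <- sum(w * (wr$theta - theta_ivw)^2)
  df <- J - 1L
  structure(list(q = q, df = df,
                 pvalue = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "mr_q")
}

#' @export
print.mr_q <- function(x, ...) {
  cat(sprintf("Cochran Q = %.4g on %d df, p = %.3g\n", x$q, x$df, x$pvalue))
  invisible(x)
}

## ---- mr_fit methods ----------------------------------------------------

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("MR estimate (%s), %d SNP(s)\n", x$method, x$n_snp))
  cat(sprintf("  theta (log OR/SD) = %.*f (SE %.*f)\n", digits, x$theta,
              digits, x$se))
  cat(sprintf("  OR = %.*f [%.*f, %.*f], p = %.3g\n", digits,
              exp(x$theta), digits, exp(x$ci_low), digits, exp(x$ci_high),
              x$pvalue))
  if (inherits(x, "mr_egger"))
    cat(sprintf("  Egger intercept = %.*f (SE %.*f), p = %.3g\n", digits,
                x$intercept, digits, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$instrument)) {
    cat("\nPer-SNP Wald ratios:\n")
    print(wald_ratios(object$instrument), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.mr_fit <- function(object, ...) {
  if (inherits(object, "mr_egger"))
    c(intercept = object$intercept, slope = object$theta)
  else c(theta = object$theta)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$theta - z * object$se,
                object$theta + z * object$se), nrow = 1,
              dimnames = list("theta",
                              sprintf("%g %%", c((1 - level) / 2,
                                                 1 - (1 - level) / 2) * 100)))
  m
}

#' Scatter plot of SNP effects with the fitted causal slope
#'
#' @param x An `mr_fit` holding its instrument.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  inst <- x$instrument
  if (is.null(inst))
    stop("plot.mr_fit: fit does not carry its instrument", call. = FALSE)
  graphics::plot(inst$x, inst$y,
                 xlab = "SNP effect on exposure (SD units)",
                 ylab = "SNP effect on outcome (log OR)",
                 pch = 19, ...)
  graphics::segments(inst$x - 1.96 * inst$sx, inst$y,
                     inst$x + 1.96 * inst$sx, inst$y, col = "grey60")
  graphics::segments(inst$x, inst$y - 1.96 * inst$sy,
                     inst$x, inst$y + 1.96 * inst$sy, col = "grey60")
  if (inherits(x, "mr_egger"))
    graphics::abline(a = x$intercept, b = x$theta, col = "firebrick")
  else graphics::abline(a = 0, b = x$theta, col = "firebrick")
  invisible(x)
}

#' One-row results record for an MR fit
#'
#' Serializes an estimate into the tabular form used by study reports:
#' method, SNP count, theta and SE on the log-odds scale, OR with 95% CI,
#' and the two-sided p-value.
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return One-row data frame.
#' @export
as.data.frame.mr_fit <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, theta = x$theta,
             se = x$se, or = exp(x$theta), ci_low = exp(x$ci_low),
             ci_high = exp(x$ci_high), pvalue = x$pvalue,
             stringsAsFactors = FALSE)
}
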