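## MR-PRESSO: pleiotropy residual sum and outlier test by parametric
## resampling, with the distortion test on outlier removal.

## Leave-one-out IVW slopes for all SNPs at once.
loo_ivw_slopes <- function(x, y, w) {
  sxy <- sum(w * x * y); sxx <- sum(w * x^2)
  (sxy - w * x * y) / (sxx - w * x^2)
}

presso_rss <- function(x, y, w) {
  th <- loo_ivw_slopes(x, y, w)
  r <- y - th * x
  list(rss = sum(w * r^2), resid2w = w * r^2, loo = th)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Detects horizontal pleiotropy as excess residual heterogeneity around
#' the inverse-variance-weighted slope, localizes it to individual SNPs,
#' and asks whether removing the flagged SNPs materially shifts the causal
#' estimate.
#'
#' The observed statistic is a leave-one-out weighted residual sum of
#' squares: for each SNP j the IVW slope is refit without it, the residual
#' `r_j = y_j - theta_{-j} x_j` formed, and `RSS = sum_j w_j r_j^2` with
#' `w_j = 1 / sy_j^2`. The null distribution comes from `n_sim` parametric
#' draws `x_j* ~ N(x_j, sx_j^2)`, `y_j* ~ N(theta_{-j} x_j, sy_j^2)` with
#' the RSS recomputed each time; `p_global` is the add-one tail
#' probability, so its smallest representable value is `1/(n_sim + 1)`.
#' Per-SNP outlier p-values compare each observed weighted squared
#' residual with its simulated counterparts, Bonferroni-multiplied by the
#' SNP count, and flag SNPs below `outlier_alpha`. When outliers are
#' flagged, the distortion statistic is the relative change in the IVW
#' slope after removing them; its null distribution comes from removing
#' equally many SNPs at random, and `p_distortion` is the two-sided tail.
#'
#' @param inst An [mr_instrument()] with at least 4 SNPs.
#' @param n_sim Number of parametric simulations; default 5000. Values
#'   below 1000 trigger a warning (the resolution `1/(n_sim+1)` becomes
#'   too coarse to call small p-values).
#' @param seed Mandatory RNG seed; the full result is reproducible given
#'   the seed.
#' @param outlier_alpha Threshold on the Bonferroni-adjusted per-SNP
#'   p-values; default 0.05.
#' @return Object of class `mr_presso`: list with `rss_obs`, `p_global`,
#'   `outlier_p` (Bonferroni-adjusted, capped at 1), `outlier_idx`,
#'   `outlier_rsid`, `p_distortion` (NA when no outliers),
#'   `estimate_raw` and `estimate_corrected` (IVW fits before/after
#'   removal; the latter NULL when nothing was flagged).
#' @examples
#' set.seed(7)
#' x <- runif(8, 0.05, 0.2); sy <- rep(0.02, 8)
#' inst <- mr_instrument(x, rep(0.004, 8), 0.4 * x + rnorm(8, 0, 0.02), sy)
#' mr_presso(inst, n_sim = 1000, seed = 42)
#' @export
mr_presso <- function(inst, n_sim = 5000L, seed = NULL,
                      outlier_alpha = 0.05) {
  J <- n_snp(inst)
  if (J < 4L)
    stop("mr_presso: at least 4 SNPs required (leave-one-out needs 3)",
         call. = FALSE)
  if (is.null(seed))
    stop("mr_presso: a seed is required for reproducible resampling",
         call. = FALSE)
  if (n_sim < 1000L)
    warning("mr_presso: n_sim < 1000 gives a coarse p-value resolution of ",
            signif(1 / (n_sim + 1), 2), call. = FALSE)

  x <- inst$x; y <- inst$y; sx <- inst$sx; sy <- inst$sy
  w <- 1 / sy^2
  obs <- presso_rss(x, y, w)

  sim <- withr_seed(seed, {
    xs <- matrix(stats::rnorm(n_sim * J, rep(x, each = n_sim),
                              rep(sx, each = n_sim)), n_sim, J)
    ys <- matrix(stats::rnorm(n_sim * J, rep(obs$loo * x, each = n_sim),
                              rep(sy, each = n_sim)), n_sim, J)
    # vectorized leave-one-out RSS per simulated dataset
    wm <- matrix(w, n_sim, J, byrow = TRUE)
    sxy <- rowSums(wm * xs * ys); sxx <- rowSums(wm * xs^2)
    th <- (sxy - wm * xs * ys) / (sxx - wm * xs^2)
    r2w <- wm * (ys - th * xs)^2
    list(rss = rowSums(r2w), resid2w = r2w,
         removal = matrix(stats::runif(n_sim * J), n_sim, J))
  })

  p_global <- (1 + sum(sim$rss >= obs$rss)) / (n_sim + 1)
  outlier_p_raw <- (1 + colSums(sim$resid2w >=
                                  rep(obs$resid2w, each = n_sim))) /
    (n_sim + 1)
  outlier_p <- pmin(outlier_p_raw * J, 1)
  outlier_idx <- which(outlier_p < outlier_alpha)

  estimate_raw <- ivw_estimate(inst)
  estimate_corrected <- NULL
  p_distortion <- NA_real_
  if (length(outlier_idx) > 0 && J - length(outlier_idx) >= 2) {
    keep <- setdiff(seq_len(J), outlier_idx)
    estimate_corrected <- ivw_estimate(subset_instrument(inst, keep))
    th_all <- estimate_raw$theta
    d_obs <- (estimate_corrected$theta - th_all) / abs(th_all)
    # null: remove the same number of SNPs at random (ranks of pre-drawn
    # uniforms give the random subsets, keeping the result seed-determined)
    k <- length(outlier_idx)
    d_null <- apply(sim$removal, 1, function(u) {
      kp <- order(u)[seq_len(J - k)]
      ivw_slope_raw(x[kp], y[kp], w[kp]) - th_all
    }) / abs(th_all)
    p_distortion <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  }

  structure(list(rss_obs = obs$rss, p_global = p_global,
                 outlier_p = outlier_p, outlier_idx = outlier_idx,
                 outlier_rsid = inst$rsid[outlier_idx],
                 p_distortion = p_distortion,
                 estimate_raw = estimate_raw,
                 estimate_corrected = estimate_corrected,
                 n_sim = n_sim, seed = seed,
                 outlier_alpha = outlier_alpha),
            class = "mr_presso")
}

ivw_slope_raw <- function(x, y, w) sum(w * x * y) / sum(w * x^2)

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (%d simulations)\n", x$n_sim))
  cat(sprintf("  Global test: RSS = %.4g, p = %.3g\n", x$rss_obs,
              x$p_global))
  if (length(x$outlier_idx))
    cat("  Outliers:", paste(x$outlier_rsid, collapse = ", "),
        sprintf("; distortion p = %.3g\n", x$p_distortion))
  else cat("  No outlier SNPs flagged\n")
  invisible(x)
}
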