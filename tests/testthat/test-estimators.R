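test_that("Wald ratios follow the ratio and first-order SE formulas", {
  inst <- mr_instrument(x = c(0.1, 0.2), sx = c(0.01, 0.01),
                        y = c(0.2, 0), sy = c(0.02, 0.02))
  wr <- wald_ratios(inst)
  expect_equal(wr$theta, c(2, 0))
  expect_equal(wr$se, c(0.2, 0.1))

  wr2 <- wald_ratios(inst, "second")
  expect_equal(wr2$se[1],
               sqrt(0.02^2 / 0.1^2 + 0.2^2 * 0.01^2 / 0.1^4))
  # null outcome effect: second-order collapses to first-order
  expect_equal(wr2$se[2], 0.1)

  bad <- mr_instrument(x = c(0, 0.1), sx = c(0.01, 0.01),
                       y = c(0.1, 0.1), sy = c(0.02, 0.02))
  expect_error(wald_ratios(bad), "snp1")
})

test_that("single-SNP likelihood estimate reduces to the Wald ratio", {
  inst <- mr_instrument(x = 0.12, sx = 0.01, y = 0.06, sy = 0.03)
  fit <- ml_estimate(inst)
  expect_equal(fit$theta, 0.5, tolerance = 1e-8)
  expect_equal(mr_fit(inst, "wald")$theta, 0.5)
})

test_that("likelihood estimate converges to IVW as exposure SEs vanish", {
  inst <- random_instrument(12, seed = 21, theta = 0.4)
  tiny <- mr_instrument(inst$x, rep(1e-8, 12), inst$y, inst$sy)
  expect_equal(ml_estimate(tiny)$theta, ivw_estimate(tiny)$theta,
               tolerance = 1e-6)
})

test_that("likelihood estimate matches a profile grid-search oracle", {
  inst <- random_instrument(5, seed = 31, theta = 0.7,
                            sx = 0.03, sy = 0.05)
  # oracle: direct evaluation of the profile objective on a refined grid
  obj <- function(th)
    sum((inst$y - th * inst$x)^2 / (inst$sy^2 + th^2 * inst$sx^2))
  grid <- seq(-2, 3, length.out = 20001)
  best <- grid[which.min(vapply(grid, obj, numeric(1)))]
  for (k in 1:3) {
    grid <- seq(best - 1e-2 * 10^(1 - k), best + 1e-2 * 10^(1 - k),
                length.out = 2001)
    best <- grid[which.min(vapply(grid, obj, numeric(1)))]
  }
  expect_equal(ml_estimate(inst)$theta, best, tolerance = 1e-5)
})

test_that("IVW equals the weighted least-squares closed form", {
  # consensus: identical ratios are returned exactly
  inst <- mr_instrument(x = c(0.1, 0.2, 0.3), sx = rep(0.01, 3),
                        y = c(0.05, 0.10, 0.15), sy = c(0.02, 0.03, 0.04))
  expect_equal(ivw_estimate(inst)$theta, 0.5)

  two <- mr_instrument(x = c(1, 1), sx = c(0.1, 0.1),
                       y = c(1, 3), sy = c(0.5, 0.5))
  expect_equal(ivw_estimate(two)$theta, 2)

  inst <- random_instrument(15, seed = 5, theta = -0.3)
  fit <- ivw_estimate(inst)
  # oracle: normal equations assembled independently
  w <- 1 / inst$sy^2
  expect_equal(fit$theta, sum(w * inst$x * inst$y) / sum(w * inst$x^2))
  expect_equal(fit$se, sqrt(1 / sum(w * inst$x^2)))
  # cross-check the slope against weighted lm through the origin
  expect_equal(fit$theta,
               unname(coef(lm(inst$y ~ 0 + inst$x, weights = w))))

  one <- mr_instrument(0.1, 0.01, 0.05, 0.02)
  expect_error(ivw_estimate(one), "at least 2")
})

test_that("Egger regression recovers intercept and slope", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  # points through the origin: no pleiotropy signal
  inst0 <- mr_instrument(x, rep(0.01, 4), 0.5 * x, rep(0.02, 4))
  fit0 <- egger_estimate(inst0)
  expect_equal(fit0$intercept, 0, tolerance = 1e-12)
  expect_equal(fit0$theta, 0.5)

  # exact affine fit
  inst <- mr_instrument(x, rep(0.01, 4), 0.1 + 0.5 * x, rep(0.02, 4))
  fit <- egger_estimate(inst)
  expect_equal(fit$intercept, 0.1)
  expect_equal(fit$theta, 0.5)

  # random data: coefficients agree with weighted lm
  inst <- random_instrument(10, seed = 13, theta = 0.2)
  fit <- egger_estimate(inst)
  sgn <- ifelse(inst$x < 0, -1, 1)
  lmfit <- lm(sgn * inst$y ~ I(sgn * inst$x), weights = 1 / inst$sy^2)
  expect_equal(unname(coef(lmfit)), c(fit$intercept, fit$theta))

  expect_error(egger_estimate(mr_instrument(x[1:2], rep(0.01, 2),
                                            x[1:2], rep(0.02, 2))),
               "at least 3")
})

test_that("weighted median interpolates the cumulative-weight polyline", {
  inst <- mr_instrument(x = c(1, 1, 1), sx = rep(1e-6, 3),
                        y = c(1, 2, 9), sy = c(1, 1, 1))
  fit <- weighted_median_estimate(inst, n_boot = 50, seed = 1)
  expect_equal(fit$theta, 2)

  # degenerate: identical ratios, shrinking uncertainty
  instc <- mr_instrument(x = rep(0.2, 4), sx = rep(1e-7, 4),
                         y = rep(0.1, 4), sy = rep(1e-7, 4))
  fitc <- weighted_median_estimate(instc, n_boot = 100, seed = 1)
  expect_equal(fitc$theta, 0.5)
  expect_lt(fitc$se, 1e-4)

  # 7 random SNPs vs direct polyline evaluation
  for (seed in c(2, 3, 4)) {
    inst <- random_instrument(7, seed = seed, theta = 0.3)
    fit <- weighted_median_estimate(inst, n_boot = 10, seed = 1)
    th <- inst$y / inst$x
    w <- (inst$x / inst$sy)^2
    ord <- order(th)
    th <- th[ord]; w <- w[ord] / sum(w)
    p <- cumsum(w) - w / 2
    k <- max(which(p < 0.5))
    oracle <- th[k] + (th[k + 1] - th[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
    expect_equal(fit$theta, oracle)
  }
})

test_that("mode estimate maximizes the weighted kernel density", {
  instc <- mr_instrument(x = rep(0.2, 4), sx = rep(1e-7, 4),
                         y = rep(0.1, 4), sy = rep(1e-7, 4))
  fitc <- mode_estimate(instc, n_boot = 0, seed = 1)
  expect_equal(fitc$theta, 0.5)
  expect_equal(fitc$se, 0)

  # majority mode: three ratios at 0, one at 5
  inst <- mr_instrument(x = rep(1, 4), sx = rep(1e-6, 4),
                        y = c(0, 0, 0, 5), sy = rep(1, 4))
  fit <- mode_estimate(inst, phi = 0.25, n_boot = 10, seed = 1)
  expect_lt(abs(fit$theta), 0.1)

  # 9 random SNPs vs brute-force dense-grid evaluation
  for (seed in c(6, 7)) {
    inst <- random_instrument(9, seed = seed, theta = 0.3, sy = 0.05)
    fit <- mode_estimate(inst, n_boot = 10, seed = 1)
    th <- inst$y / inst$x
    se <- inst$sy / abs(inst$x)
    w <- (1 / se^2); w <- w / sum(w)
    s <- sqrt(sum(w * (th - sum(w * th))^2))
    med <- function(v, ww) {
      o <- order(v); v <- v[o]; ww <- ww[o] / sum(ww)
      pp <- cumsum(ww) - ww / 2
      if (pp[1] >= 0.5) v[1]
      else if (pp[length(pp)] <= 0.5) v[length(v)]
      else approx(pp, v, xout = 0.5, ties = "ordered")$y
    }
    m <- med(abs(th - med(th, w)), w) / 0.6745
    h <- 0.9 * min(s, m) * 9^(-0.2)
    grid <- seq(min(th) - 3 * h, max(th) + 3 * h, length.out = 1e5)
    dens <- vapply(grid, function(g)
      sum(w * dnorm((th - g) / h)), numeric(1))
    expect_equal(fit$theta, grid[which.max(dens)])
  }
})

test_that("Cochran Q measures ratio heterogeneity around IVW", {
  homog <- mr_instrument(x = c(0.1, 0.2, 0.3), sx = rep(0.01, 3),
                         y = c(0.05, 0.10, 0.15), sy = rep(0.02, 3))
  q <- cochran_q(homog)
  expect_equal(q$q, 0)
  expect_equal(q$pvalue, 1)
  expect_equal(q$df, 2L)

  two <- random_instrument(2, seed = 8)
  expect_equal(cochran_q(two)$df, 1L)

  inst <- random_instrument(12, seed = 9, theta = 0.2, sy = 0.05)
  q <- cochran_q(inst)
  th <- inst$y / inst$x
  w <- (inst$x / inst$sy)^2
  ivw <- sum((1 / inst$sy^2) * inst$x * inst$y) /
    sum((1 / inst$sy^2) * inst$x^2)
  expect_equal(q$q, sum(w * (th - ivw)^2))
  expect_equal(q$pvalue, pchisq(q$q, 11, lower.tail = FALSE))
})

test_that("estimators are sign-equivariant in the outcome", {
  inst <- random_instrument(8, seed = 14, theta = 0.4)
  neg <- mr_instrument(inst$x, inst$sx, -inst$y, inst$sy)
  for (method in c("ml", "ivw", "egger")) {
    a <- mr_fit(inst, method)
    b <- mr_fit(neg, method)
    expect_equal(b$theta, -a$theta, tolerance = 1e-7,
                 label = paste(method, "theta"))
    expect_equal(b$se, a$se, tolerance = 1e-7,
                 label = paste(method, "se"))
    expect_equal(b$pvalue, a$pvalue, tolerance = 1e-7,
                 label = paste(method, "p"))
  }
  # bootstrap SEs are sign-invariant only in distribution
  for (method in c("weighted_median", "mode")) {
    a <- mr_fit(inst, method, n_boot = 400, seed = 2)
    b <- mr_fit(neg, method, n_boot = 400, seed = 2)
    expect_equal(b$theta, -a$theta, tolerance = 1e-7,
                 label = paste(method, "theta"))
    expect_equal(b$se, a$se, tolerance = 0.25,
                 label = paste(method, "se"))
  }
})

test_that("estimators are scale-equivariant in the exposure", {
  inst <- random_instrument(8, seed = 15, theta = 0.4)
  c0 <- 2.5
  scaled <- mr_instrument(c0 * inst$x, c0 * inst$sx, inst$y, inst$sy)
  for (method in c("ml", "ivw", "egger", "weighted_median", "mode")) {
    a <- mr_fit(inst, method, n_boot = 50, seed = 2)
    b <- mr_fit(scaled, method, n_boot = 50, seed = 2)
    expect_equal(b$theta, a$theta / c0, tolerance = 1e-6,
                 label = paste(method, "theta"))
  }
})

test_that("fit objects expose coef, confint and serialization", {
  inst <- random_instrument(6, seed = 16, theta = 0.3)
  fit <- ml_estimate(inst)
  expect_equal(unname(coef(fit)), fit$theta)
  ci <- confint(fit)
  expect_lt(ci[1], fit$theta)
  expect_gt(ci[2], fit$theta)
  expect_equal(unname(ci[1]), fit$ci_low)
  df <- as.data.frame(fit)
  expect_equal(df$or, exp(fit$theta))
  expect_equal(df$ci_high, exp(fit$ci_high))
  eg <- egger_estimate(inst)
  expect_named(coef(eg), c("intercept", "slope"))
})
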