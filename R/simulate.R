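## Synthetic two-sample GWAS summary statistics with known truth.

#' Configure a synthetic two-sample MR dataset
#'
#' Describes a pair of exposure/outcome GWAS summary tables with a known
#' causal effect, instrument strength and pleiotropy structure, so that
#' every stage of the pipeline can be exercised against ground truth.
#'
#' @param n_snp Number of instrument SNPs.
#' @param theta True causal log OR per SD of exposure.
#' @param r2_target Total exposure variance explained by the instrument,
#'   in (0, 1); the drawn per-SNP effects are rescaled so the realized
#'   value is exact.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome case-control design.
#' @param maf_range Interval within (0, 0.5\] for the uniform minor-allele
#'   frequencies.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean pleiotropic
#'   effects), `"directional"` (mean `pleio_mean`), or `"outlier"`
#'   (`n_outliers` SNPs displaced by `outlier_shift` outcome SEs).
#' @param pleio_sd SD of the pleiotropic effects for the balanced and
#'   directional modes.
#' @param pleio_mean Mean pleiotropic effect for the directional mode.
#' @param n_outliers,outlier_shift Outlier count and displacement (in
#'   units of the SNP's outcome SE) for the outlier mode.
#' @param palindromic_frac Fraction of SNPs assigned A/T or C/G allele
#'   pairs, to exercise harmonization.
#' @param seed RNG seed; [simulate_pair()] is bit-reproducible given it.
#' @param name Optional label.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_snp, theta = 0, r2_target = 0.05,
                       n_exposure = 3e5, n_cases = 25042,
                       n_controls = 34915, maf_range = c(0.05, 0.5),
                       pleiotropy_mode = c("none", "balanced",
                                           "directional", "outlier"),
                       pleio_sd = 0, pleio_mean = 0, n_outliers = 0,
                       outlier_shift = 0, palindromic_frac = 0,
                       seed = 1L, name = "synthetic") {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snp >= 1, r2_target > 0, r2_target < 1,
            n_outliers <= n_snp, palindromic_frac >= 0,
            palindromic_frac <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  structure(list(n_snp = as.integer(n_snp), theta = theta,
                 r2_target = r2_target, n_exposure = n_exposure,
                 n_cases = n_cases, n_controls = n_controls,
                 maf_range = maf_range, pleiotropy_mode = pleiotropy_mode,
                 pleio_sd = pleio_sd, pleio_mean = pleio_mean,
                 n_outliers = as.integer(n_outliers),
                 outlier_shift = outlier_shift,
                 palindromic_frac = palindromic_frac,
                 seed = as.integer(seed), name = name),
            class = "sim_config")
}

NONPALINDROMIC_PAIRS <- list(c("A", "G"), c("A", "C"),
                             c("T", "G"), c("T", "C"),
                             c("G", "A"), c("C", "A"),
                             c("G", "T"), c("C", "T"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"),
                          c("C", "G"), c("G", "C"))

#' Simulate a two-sample GWAS summary-statistic pair
#'
#' Draws minor-allele frequencies uniformly over the configured range,
#' draws true instrument effects `gamma_j` from a normal and rescales them
#' so the realized variance explained
#' `sum_j 2 maf_j (1 - maf_j) gamma_j^2` equals `r2_target` exactly, forms
#' the sampling SEs from the sample sizes
#' (`sx_j = 1 / sqrt(2 maf_j (1-maf_j) n_exposure)`; outcome SEs use the
#' case-control effective sample size `n_cases n_controls / N` on the
#' log-odds scale), adds the configured pleiotropic effects `alpha_j`, and
#' draws the observed effects
#' `x_j ~ N(gamma_j, sx_j^2)`, `y_j ~ N(theta gamma_j + alpha_j, sy_j^2)`.
#' P-values are two-sided z-tests. Alleles are assigned with the requested
#' palindromic fraction, and outcome rows are randomly allele-swapped or
#' strand-complemented so that harmonization is genuinely exercised.
#'
#' @param cfg A [sim_config()].
#' @return List with `exposure` and `outcome` association data frames (the
#'   same format [read_summary_table()] reads), and `truth`: a data frame
#'   with `rsid`, `gamma`, `alpha`, `is_outlier`, plus the attribute-level
#'   scalars `theta` and `seed` carried as attributes.
#' @examples
#' sim <- simulate_pair(sim_config(n_snp = 20, theta = 0.3, seed = 42))
#' head(sim$exposure)
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr_seed(cfg$seed, {
    J <- cfg$n_snp
    maf <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])
    v <- 2 * maf * (1 - maf)
    gamma <- stats::rnorm(J)
    achievable <- sum(v * gamma^2)
    if (achievable <= 0)
      stop("simulate_pair: degenerate instrument draw", call. = FALSE)
    gamma <- gamma * sqrt(cfg$r2_target / achievable)

    sx <- 1 / sqrt(v * cfg$n_exposure)
    n_eff <- cfg$n_cases * cfg$n_controls / (cfg$n_cases + cfg$n_controls)
    sy <- 1 / sqrt(v * n_eff)

    alpha <- numeric(J)
    is_outlier <- rep(FALSE, J)
    if (cfg$pleiotropy_mode == "balanced")
      alpha <- stats::rnorm(J, 0, cfg$pleio_sd)
    else if (cfg$pleiotropy_mode == "directional") {
      # directional pleiotropy acts along the exposure-increasing allele;
      # on the table's orientation that is sign(gamma) * alpha
      alpha <- sign(gamma) * stats::rnorm(J, cfg$pleio_mean, cfg$pleio_sd)
    }
    else if (cfg$pleiotropy_mode == "outlier" && cfg$n_outliers > 0) {
      idx <- sample(J, cfg$n_outliers)
      is_outlier[idx] <- TRUE
      alpha[idx] <- cfg$outlier_shift * sy[idx]
    }

    x <- stats::rnorm(J, gamma, sx)
    y <- stats::rnorm(J, cfg$theta * gamma + alpha, sy)
    rsid <- sprintf("rs%06d", seq_len(J))
    # two-sided z p-values, floored at the smallest positive double so
    # strong instruments do not underflow to an invalid p of zero
    pval <- function(b, s) pmax(2 * stats::pnorm(-abs(b / s)),
                                .Machine$double.xmin)

    n_pal <- round(cfg$palindromic_frac * J)
    pal <- rep(FALSE, J)
    if (n_pal > 0) pal[sample(J, n_pal)] <- TRUE
    pick <- function(pairs, n)
      pairs[sample(length(pairs), n, replace = TRUE)]
    alleles <- vector("list", J)
    alleles[pal] <- pick(PALINDROMIC_PAIRS, sum(pal))
    alleles[!pal] <- pick(NONPALINDROMIC_PAIRS, sum(!pal))
    ea <- vapply(alleles, `[`, character(1), 1)
    oa <- vapply(alleles, `[`, character(1), 2)

    exposure <- data.frame(
      rsid = rsid, effect_allele = ea, other_allele = oa, eaf = maf,
      beta = x, se = sx, pvalue = pval(x, sx),
      stringsAsFactors = FALSE)

    # scramble outcome representation: random allele swap and random
    # strand complement (non-palindromic only), preserving meaning
    swap <- stats::runif(J) < 0.5
    strand <- stats::runif(J) < 0.5 & !pal
    o_ea <- ea; o_oa <- oa; o_beta <- y; o_eaf <- maf
    o_ea[swap] <- oa[swap]; o_oa[swap] <- ea[swap]
    o_beta[swap] <- -y[swap]; o_eaf[swap] <- 1 - maf[swap]
    o_ea[strand] <- unname(COMPLEMENT[o_ea[strand]])
    o_oa[strand] <- unname(COMPLEMENT[o_oa[strand]])
    outcome <- data.frame(
      rsid = rsid, effect_allele = o_ea, other_allele = o_oa, eaf = o_eaf,
      beta = o_beta, se = sy, pvalue = pval(y, sy),
      stringsAsFactors = FALSE)

    truth <- data.frame(rsid = rsid, gamma = gamma, alpha = alpha,
                        is_outlier = is_outlier, stringsAsFactors = FALSE)
    attr(truth, "theta") <- cfg$theta
    attr(truth, "seed") <- cfg$seed
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Write a simulated pair to disk
#'
#' Emits `<prefix>_exposure.tsv`, `<prefix>_outcome.tsv` in the canonical
#' summary-statistic format and `<prefix>_truth.tsv`
#' (`rsid  gamma  alpha  is_outlier`).
#'
#' @param sim Result of [simulate_pair()].
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_simulated_pair <- function(sim, prefix) {
  paths <- paste0(prefix, c("_exposure.tsv", "_outcome.tsv", "_truth.tsv"))
  write_summary_table(sim$exposure, paths[1])
  write_summary_table(sim$outcome, paths[2])
  utils::write.table(sim$truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Study-scale instrument designs
#'
#' The 13 genetic instruments of the IBD risk-factor study, as simulation
#' configs: SNP counts and variance explained per exposure, against the
#' 25,042-case / 34,915-control IBD outcome design. Useful for end-to-end
#' dry runs shaped like the real study.
#'
#' @param theta True causal effect shared by all configs (default 0).
#' @param seed Base seed; config i uses `seed + i`.
#' @return Named list of 13 [sim_config()] objects.
#' @export
study_instrument_designs <- function(theta = 0, seed = 100L) {
  specs <- list(
    smoking_status        = c(n_snp = 331, r2 = 0.023),
    cigarettes_per_day    = c(n_snp = 44,  r2 = 0.011),
    body_mass_index       = c(n_snp = 816, r2 = 0.060),
    waist_hip_ratio       = c(n_snp = 403, r2 = 0.030),
    body_fat_percentage   = c(n_snp = 378, r2 = 0.035),
    physical_activity     = c(n_snp = 2,   r2 = 0.0008),
    vitamin_d             = c(n_snp = 59,  r2 = 0.034),
    vitamin_b9            = c(n_snp = 2,   r2 = 0.010),
    vitamin_b12           = c(n_snp = 10,  r2 = 0.063),
    omega3_fatty_acids    = c(n_snp = 4,   r2 = 0.024),
    omega6_fatty_acids    = c(n_snp = 8,   r2 = 0.046),
    monounsaturated_fa    = c(n_snp = 4,   r2 = 0.024),
    total_fatty_acids     = c(n_snp = 8,   r2 = 0.037)
  )
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (i in seq_along(specs)) {
    out[[i]] <- sim_config(n_snp = specs[[i]]["n_snp"], theta = theta,
                           r2_target = specs[[i]]["r2"],
                           seed = seed + i, name = names(specs)[i])
  }
  out
}
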