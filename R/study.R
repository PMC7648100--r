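## Full-study orchestration: every exposure x outcome pair through
## harmonization, all estimators, sensitivity tests, Bonferroni,
## CD-vs-UC heterogeneity and the power table.

#' Configure a multi-exposure MR study
#'
#' @param exposures,outcomes Named lists; each element is a list with
#'   either `file` (path to a summary table) or `data` (an association
#'   data frame), and optionally `meta` (a [trait_meta()]). Continuous
#'   exposures with a `meta$sd` are standardized on load.
#' @param cd_uc Length-2 character vector naming the outcome elements that
#'   form the CD/UC subtype pair for the heterogeneity test, or `NULL` to
#'   skip it.
#' @param alpha Base significance level; default 0.05.
#' @param n_tests Number of exposures counted in the Bonferroni
#'   correction; defaults to `length(exposures)`.
#' @param n_boot Bootstrap replicates for the median/mode SEs.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param phi Mode-estimator bandwidth multiplier.
#' @param p_threshold Genome-wide significance filter applied to exposure
#'   tables (strict `<`); set `NULL` to accept pre-selected instruments.
#' @param drop_palindromic Passed to [harmonize()].
#' @param seed Master seed; per-pair seeds are derived deterministically.
#' @return Object of class `study_config`.
#' @export
study_config <- function(exposures, outcomes, cd_uc = NULL, alpha = 0.05,
                         n_tests = length(exposures), n_boot = 1000L,
                         presso_n_sim = 5000L, phi = 1,
                         p_threshold = 5e-8, drop_palindromic = TRUE,
                         seed = 1L) {
  stopifnot(length(exposures) >= 1L, length(outcomes) >= 1L,
            !is.null(names(exposures)), !is.null(names(outcomes)),
            n_tests >= 1L)
  if (!is.null(cd_uc)) {
    stopifnot(length(cd_uc) == 2L, all(cd_uc %in% names(outcomes)))
  }
  structure(list(exposures = exposures, outcomes = outcomes,
                 cd_uc = cd_uc, alpha = alpha, n_tests = n_tests,
                 n_boot = as.integer(n_boot),
                 presso_n_sim = as.integer(presso_n_sim), phi = phi,
                 p_threshold = p_threshold,
                 drop_palindromic = drop_palindromic,
                 seed = as.integer(seed)),
            class = "study_config")
}

load_trait_table <- function(entry, name, standardize = FALSE) {
  df <- if (!is.null(entry$data)) validate_associations(entry$data, name)
        else read_summary_table(entry$file, entry$meta)
  if (standardize && !is.null(entry$meta) &&
      !isTRUE(entry$meta$is_binary) && !is.na(entry$meta$sd))
    df <- standardize_to_sd(df, entry$meta)
  df
}

na_fit_row <- function(method) {
  data.frame(method = method, n_snp = NA_integer_, theta = NA_real_,
             se = NA_real_, or = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, pvalue = NA_real_,
             stringsAsFactors = FALSE)
}

## Run every estimator applicable to one harmonized pair; preconditions
## that fail yield NA rows rather than errors (2-SNP instruments keep
## their ML/IVW/Q results but record NA for Egger, median, mode, PRESSO).
analyze_pair <- function(inst, cfg, pair_seed) {
  J <- n_snp(inst)
  fits <- list()
  fits$ml <- as.data.frame(ml_estimate(inst))
  fits$ml$method <- "ml"
  fits$ivw <- if (J >= 2) as.data.frame(ivw_estimate(inst))
              else na_fit_row("ivw")
  egger <- if (J >= 3) egger_estimate(inst) else NULL
  fits$egger <- if (!is.null(egger)) as.data.frame(egger)
                else na_fit_row("egger")
  fits$weighted_median <- if (J >= 3)
    as.data.frame(weighted_median_estimate(inst, n_boot = cfg$n_boot,
                                           seed = pair_seed))
    else na_fit_row("weighted_median")
  fits$mode <- if (J >= 3)
    as.data.frame(mode_estimate(inst, phi = cfg$phi, n_boot = cfg$n_boot,
                                seed = pair_seed + 1L))
    else na_fit_row("mode")
  primary <- do.call(rbind, fits)

  q <- if (J >= 2) cochran_q(inst) else NULL
  presso <- if (J >= 4) mr_presso(inst, n_sim = cfg$presso_n_sim,
                                  seed = pair_seed + 2L)
            else NULL
  sens <- data.frame(
    n_snp = J,
    egger_intercept = if (!is.null(egger)) egger$intercept else NA_real_,
    egger_intercept_p = if (!is.null(egger)) egger$intercept_p
                        else NA_real_,
    q = if (!is.null(q)) q$q else NA_real_,
    q_df = if (!is.null(q)) q$df else NA_integer_,
    q_p = if (!is.null(q)) q$pvalue else NA_real_,
    presso_rss = if (!is.null(presso)) presso$rss_obs else NA_real_,
    presso_p_global = if (!is.null(presso)) presso$p_global else NA_real_,
    n_outliers = if (!is.null(presso)) length(presso$outlier_idx)
                 else NA_integer_,
    outlier_rsids = if (!is.null(presso) && length(presso$outlier_rsid))
                      paste(presso$outlier_rsid, collapse = ",")
                    else NA_character_,
    presso_p_distortion = if (!is.null(presso)) presso$p_distortion
                          else NA_real_,
    stringsAsFactors = FALSE)
  list(primary = primary, sensitivity = sens, inst = inst,
       ml_theta = fits$ml$theta)
}

#' Run the full MR study
#'
#' For every exposure x outcome pair: load, optionally filter to
#' genome-wide significance, harmonize, fit the likelihood-based estimate
#' (primary) plus the IVW, Egger, weighted-median and mode sensitivity
#' estimators, compute Cochran Q and MR-PRESSO, flag
#' Bonferroni-significant primary results at `alpha / n_tests`, test
#' CD-vs-UC heterogeneity on the declared subtype pair, and assemble the
#' power table. Per-pair failures are recorded and the run continues.
#'
#' @param cfg A [study_config()].
#' @return Object of class `study_report`: list of data frames `primary`,
#'   `sensitivity`, `heterogeneity`, `power`, plus `instruments` (the
#'   harmonized `mr_instrument` per pair), `failures`, and the config.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  exposures <- lapply(seq_along(cfg$exposures), function(i)
    load_trait_table(cfg$exposures[[i]], names(cfg$exposures)[i],
                     standardize = TRUE))
  names(exposures) <- names(cfg$exposures)
  outcomes <- lapply(seq_along(cfg$outcomes), function(i)
    load_trait_table(cfg$outcomes[[i]], names(cfg$outcomes)[i]))
  names(outcomes) <- names(cfg$outcomes)

  if (!is.null(cfg$p_threshold))
    exposures <- lapply(exposures, filter_genomewide, cfg$p_threshold)

  primary <- list(); sens <- list(); insts <- list()
  ml_by_pair <- list(); failures <- list()
  pair_id <- 0L
  for (e in names(exposures)) {
    for (o in names(outcomes)) {
      pair_id <- pair_id + 1L
      pair_seed <- cfg$seed + 17L * pair_id
      key <- paste(e, o, sep = ":")
      res <- tryCatch({
        inst <- harmonize(exposures[[e]], outcomes[[o]],
                          drop_palindromic = cfg$drop_palindromic)
        analyze_pair(inst, cfg, pair_seed)
      }, error = function(err) err)
      if (inherits(res, "error")) {
        failures[[key]] <- conditionMessage(res)
        next
      }
      res$primary <- cbind(exposure = e, outcome = o, res$primary,
                           stringsAsFactors = FALSE)
      res$sensitivity <- cbind(exposure = e, outcome = o,
                               res$sensitivity, stringsAsFactors = FALSE)
      primary[[key]] <- res$primary
      sens[[key]] <- res$sensitivity
      insts[[key]] <- res$inst
      ml_by_pair[[key]] <- res$primary[res$primary$method == "ml", ]
    }
  }
  primary <- do.call(rbind, c(primary, list(make.row.names = FALSE)))
  sens <- do.call(rbind, c(sens, list(make.row.names = FALSE)))

  threshold <- cfg$alpha / cfg$n_tests
  primary$bonferroni_significant <-
    primary$method == "ml" & !is.na(primary$pvalue) &
    primary$pvalue < threshold

  het <- NULL
  if (!is.null(cfg$cd_uc)) {
    het <- do.call(rbind, lapply(names(exposures), function(e) {
      pick <- function(o) ml_by_pair[[paste(e, o, sep = ":")]]
      cd <- pick(cfg$cd_uc[1]); uc <- pick(cfg$cd_uc[2])
      h <- if (is.null(cd) || is.null(uc)) NULL
           else disease_heterogeneity(cd, uc)
      data.frame(exposure = e,
                 q = if (is.null(h)) NA_real_ else h$q,
                 pooled = if (is.null(h)) NA_real_ else h$pooled,
                 p_disease_het = if (is.null(h)) NA_real_ else h$pvalue,
                 stringsAsFactors = FALSE)
    }))
  }

  power <- NULL
  r2 <- vapply(cfg$exposures, function(e)
    if (!is.null(e$meta)) e$meta$r2 else NA_real_, numeric(1))
  binar <- vapply(cfg$outcomes, function(o)
    !is.null(o$meta) && isTRUE(o$meta$is_binary) &&
      !is.na(o$meta$n_cases), logical(1))
  if (any(!is.na(r2)) && any(binar)) {
    power <- do.call(rbind, lapply(names(cfg$outcomes)[binar],
      function(o) {
        m <- cfg$outcomes[[o]]$meta
        ok <- !is.na(r2)
        cbind(outcome = o,
              power_table(r2[ok], m$n_cases, m$n_controls,
                          alpha = cfg$alpha),
              stringsAsFactors = FALSE)
      }))
  }

  structure(list(primary = primary, sensitivity = sens,
                 heterogeneity = het, power = power,
                 instruments = insts, failures = failures,
                 bonferroni_threshold = threshold, config = cfg),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  np <- length(x$instruments)
  cat("MR study report:", np, "exposure-outcome pair(s)\n")
  cat(sprintf("  Bonferroni threshold: %.4g (alpha %.3g / %d tests)\n",
              x$bonferroni_threshold, x$config$alpha, x$config$n_tests))
  ml <- x$primary[x$primary$method == "ml", ]
  nsig <- sum(ml$bonferroni_significant, na.rm = TRUE)
  cat("  Bonferroni-significant primary results:", nsig, "\n")
  if (length(x$failures))
    cat("  Failed pairs:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Write the study report tables
#'
#' Writes `primary.tsv`, `sensitivity.tsv`, and when available
#' `heterogeneity.tsv` and `power.tsv`, all tab-separated with headers;
#' byte-identical across runs on the same report.
#'
#' @param report A [run_study()] result.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, fname) {
    if (is.null(df)) return()
    p <- file.path(out_dir, fname)
    utils::write.table(format(df, digits = 10, trim = TRUE,
                              scientific = NA),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  emit(report$primary, "primary.tsv")
  emit(report$sensitivity, "sensitivity.tsv")
  emit(report$heterogeneity, "heterogeneity.tsv")
  emit(report$power, "power.tsv")
  invisible(written)
}

#' Emit plot-data tables for scatter and forest plots
#'
#' Per pair, a scatter file (`rsid, x, sx, y, sy, ml_slope`) whose slope
#' column is constant and equal to the pair's likelihood-based estimate;
#' per outcome, a forest file (`exposure, or, ci_low, ci_high, pvalue,
#' p_disease_het`). These tables are sufficient to redraw the standard MR
#' scatter and forest figures.
#'
#' @param report A [run_study()] result.
#' @param out_dir Output directory.
#' @return Data frame manifest (`file`, `kind`), invisibly.
#' @export
emit_plot_data <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  ml <- report$primary[report$primary$method == "ml", ]
  for (key in names(report$instruments)) {
    inst <- report$instruments[[key]]
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    slope <- ml$theta[ml$exposure == parts[1] & ml$outcome == parts[2]]
    df <- data.frame(rsid = inst$rsid, x = inst$x, sx = inst$sx,
                     y = inst$y, sy = inst$sy, ml_slope = slope,
                     stringsAsFactors = FALSE)
    fname <- file.path(out_dir,
                       sprintf("scatter_%s_%s.tsv", parts[1], parts[2]))
    utils::write.table(format(df, digits = 10, trim = TRUE), fname,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = fname, kind = "scatter", stringsAsFactors = FALSE)
  }
  het <- report$heterogeneity
  for (o in unique(ml$outcome)) {
    sub <- ml[ml$outcome == o, c("exposure", "or", "ci_low", "ci_high",
                                 "pvalue")]
    sub$p_disease_het <- if (is.null(het)) NA_real_
      else het$p_disease_het[match(sub$exposure, het$exposure)]
    fname <- file.path(out_dir, sprintf("forest_%s.tsv", o))
    utils::write.table(format(sub, digits = 10, trim = TRUE), fname,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = fname, kind = "forest", stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, manifest))
}
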