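## Allele harmonization of exposure and outcome summary statistics.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Align exposure and outcome associations into an analysis-ready instrument
#'
#' For every rsid shared between the two tables the outcome record is
#' oriented to the exposure's effect allele:
#' \itemize{
#'   \item alleles already match: kept as is (`"kept"`);
#'   \item alleles swapped: outcome beta negated and `eaf` reflected
#'     (`"flipped"`);
#'   \item alleles match only after complementing the outcome strand
#'     (A<->T, C<->G; non-palindromic pairs only): complemented, then the
#'     match/swap rule applies (`"strand-complemented"`);
#'   \item palindromic exposure pair (A/T or C/G): the strand cannot be
#'     resolved from alleles alone, so the SNP is dropped by default
#'     (`"dropped-palindromic"`); with
#'     `palindromic_action = "infer"` it is instead aligned by allele
#'     frequency when both `eaf` values are informative
#'     (minor-allele frequency below `eaf_threshold` on both sides);
#'   \item irreconcilable alleles: `"dropped-missing"`.
#' }
#'
#' Exposure SNPs absent from the outcome table are not part of the
#' instrument (a two-sample analysis needs both effects).
#'
#' @param exposure,outcome Association data frames (see
#'   [read_summary_table()]), keyed by `rsid`.
#' @param drop_palindromic Drop A/T and C/G SNPs (default `TRUE`).
#' @param palindromic_action `"drop"` (default) or `"infer"`
#'   (frequency-based resolution, used only when `drop_palindromic` is
#'   `FALSE`).
#' @param eaf_threshold Palindromic SNPs are frequency-resolvable only when
#'   `min(eaf, 1 - eaf) < eaf_threshold` in both samples; default 0.42.
#' @return An object of class `mr_instrument`: a list with numeric vectors
#'   `rsid`, `x`, `sx` (exposure betas, SEs), `y`, `sy` (outcome betas,
#'   SEs), and a `data` data frame additionally holding the per-SNP
#'   harmonization `flag` for every shared rsid, dropped ones included.
#' @examples
#' exp <- data.frame(rsid = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'                   other_allele = c("G", "T"), eaf = c(0.3, 0.4),
#'                   beta = c(0.1, 0.2), se = c(0.01, 0.02),
#'                   pvalue = c(1e-10, 1e-12))
#' out <- data.frame(rsid = c("rs1", "rs2"), effect_allele = c("G", "C"),
#'                   other_allele = c("A", "T"), eaf = c(0.7, 0.4),
#'                   beta = c(-0.05, 0.04), se = c(0.02, 0.02),
#'                   pvalue = c(0.01, 0.04))
#' harmonize(exp, out)
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = TRUE,
                      palindromic_action = c("drop", "infer"),
                      eaf_threshold = 0.42) {
  palindromic_action <- match.arg(palindromic_action)
  if (drop_palindromic) palindromic_action <- "drop"
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0L)
    stop("harmonize: no shared rsids between exposure and outcome",
         call. = FALSE)
  ei <- match(shared, exposure$rsid)
  oi <- match(shared, outcome$rsid)

  n <- length(shared)
  flag <- character(n)
  y <- numeric(n); eaf_out <- numeric(n)

  for (k in seq_len(n)) {
    e_ea <- exposure$effect_allele[ei[k]]
    e_oa <- exposure$other_allele[ei[k]]
    o_ea <- outcome$effect_allele[oi[k]]
    o_oa <- outcome$other_allele[oi[k]]
    ob <- outcome$beta[oi[k]]
    of <- outcome$eaf[oi[k]]

    if (is_palindromic(e_ea, e_oa)) {
      ef <- exposure$eaf[ei[k]]
      resolvable <- palindromic_action == "infer" &&
        !is.na(ef) && !is.na(of) &&
        min(ef, 1 - ef) < eaf_threshold && min(of, 1 - of) < eaf_threshold
      if (!resolvable) {
        flag[k] <- "dropped-palindromic"; next
      }
      # Alleles cannot distinguish strand for A/T and C/G pairs; align so
      # the minor/major status of the effect allele agrees across samples.
      same_alleles <- (o_ea == e_ea && o_oa == e_oa) ||
        (o_ea == e_oa && o_oa == e_ea)
      if (!same_alleles) { flag[k] <- "dropped-missing"; next }
      aligned_f <- if (o_ea == e_ea) of else 1 - of
      aligned_b <- if (o_ea == e_ea) ob else -ob
      if ((ef < 0.5) == (aligned_f < 0.5)) {
        y[k] <- aligned_b; eaf_out[k] <- aligned_f; flag[k] <- "kept"
      } else {
        y[k] <- -aligned_b; eaf_out[k] <- 1 - aligned_f
        flag[k] <- "strand-complemented"
      }
      next
    }

    complemented <- FALSE
    if (!(o_ea %in% c(e_ea, e_oa)) || !(o_oa %in% c(e_ea, e_oa)) ||
        o_ea == o_oa) {
      # try the opposite strand
      c_ea <- unname(COMPLEMENT[o_ea]); c_oa <- unname(COMPLEMENT[o_oa])
      if ((c_ea %in% c(e_ea, e_oa)) && (c_oa %in% c(e_ea, e_oa)) &&
          c_ea != c_oa) {
        o_ea <- c_ea; o_oa <- c_oa; complemented <- TRUE
      } else {
        flag[k] <- "dropped-missing"; next
      }
    }
    if (o_ea == e_ea && o_oa == e_oa) {
      y[k] <- ob; eaf_out[k] <- of
      flag[k] <- if (complemented) "strand-complemented" else "kept"
    } else if (o_ea == e_oa && o_oa == e_ea) {
      y[k] <- -ob; eaf_out[k] <- if (is.na(of)) NA_real_ else 1 - of
      flag[k] <- if (complemented) "strand-complemented" else "flipped"
    } else {
      flag[k] <- "dropped-missing"
    }
  }

  keep <- !startsWith(flag, "dropped")
  data <- data.frame(
    rsid = shared,
    effect_allele = exposure$effect_allele[ei],
    other_allele = exposure$other_allele[ei],
    eaf_exposure = exposure$eaf[ei],
    eaf_outcome = ifelse(keep, eaf_out, NA_real_),
    x = exposure$beta[ei], sx = exposure$se[ei],
    y = ifelse(keep, y, NA_real_), sy = outcome$se[oi],
    pvalue_exposure = exposure$pvalue[ei],
    flag = flag,
    stringsAsFactors = FALSE
  )
  if (!any(keep))
    stop("harmonize: all shared SNPs were dropped; empty instrument",
         call. = FALSE)
  new_mr_instrument(data)
}

new_mr_instrument <- function(data) {
  keep <- !startsWith(data$flag, "dropped")
  kept <- data[keep, , drop = FALSE]
  stopifnot(all(kept$sx > 0), all(kept$sy > 0))
  structure(list(rsid = kept$rsid, x = kept$x, sx = kept$sx,
                 y = kept$y, sy = kept$sy, data = data),
            class = "mr_instrument")
}

#' Build an instrument directly from aligned effect vectors
#'
#' Convenience constructor for simulation and testing when alleles are
#' already aligned.
#'
#' @param x,sx Exposure betas and SEs (SD units).
#' @param y,sy Outcome betas and SEs (log odds).
#' @param rsid Optional identifiers.
#' @return An `mr_instrument`.
#' @export
mr_instrument <- function(x, sx, y, sy,
                          rsid = paste0("snp", seq_along(x))) {
  stopifnot(length(x) >= 1L,
            length(sx) == length(x), length(y) == length(x),
            length(sy) == length(x), all(sx > 0), all(sy > 0))
  data <- data.frame(rsid = rsid, effect_allele = NA_character_,
                     other_allele = NA_character_,
                     eaf_exposure = NA_real_, eaf_outcome = NA_real_,
                     x = x, sx = sx, y = y, sy = sy,
                     pvalue_exposure = NA_real_, flag = "kept",
                     stringsAsFactors = FALSE)
  new_mr_instrument(data)
}

#' Number of SNPs in an instrument
#' @param inst An `mr_instrument`.
#' @return Integer count of retained SNPs.
#' @export
n_snp <- function(inst) length(inst$x)

#' @export
print.mr_instrument <- function(x, ...) {
  tab <- table(x$data$flag)
  cat("Harmonized MR instrument:", n_snp(x), "SNP(s)\n")
  cat("  flags:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.mr_instrument <- function(x, ...) x$data

subset_instrument <- function(inst, idx) {
  keep_rows <- which(!startsWith(inst$data$flag, "dropped"))
  new_mr_instrument(inst$data[keep_rows[idx], , drop = FALSE])
}
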