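## Reading, validation, standardization and instrument selection for
## per-SNP GWAS summary statistics.

SUMMARY_COLUMNS <- c("rsid", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pvalue")

#' Validate a data frame of SNP associations
#'
#' Checks each row against the per-SNP invariants (single-base alleles,
#' distinct alleles, `se > 0`, `pvalue` in (0, 1], `eaf` in (0, 1) when
#' present) and drops offending rows with a warning naming the reason.
#' Allele letters are uppercased.
#'
#' @param df Data frame carrying at least the seven canonical columns
#'   `rsid, effect_allele, other_allele, eaf, beta, se, pvalue`.
#' @param source Label used in warnings.
#' @return The validated data frame (possibly with fewer rows).
#' @export
validate_associations <- function(df, source = "associations") {
  missing_cols <- setdiff(SUMMARY_COLUMNS, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing mandatory column(s): %s", source,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df$rsid <- as.character(df$rsid)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue"))
    df[[col]] <- as.numeric(df[[col]])

  bases <- c("A", "C", "G", "T")
  reasons <- character(nrow(df))
  bad <- function(cond, why) {
    cond <- !is.na(cond) & cond
    reasons[cond & !nzchar(reasons)] <<- why
  }
  bad(!(df$effect_allele %in% bases) | !(df$other_allele %in% bases),
      "allele not a single base A/C/G/T")
  bad(df$effect_allele == df$other_allele, "identical alleles")
  bad(is.na(df$beta), "missing beta")
  bad(is.na(df$se) | df$se <= 0, "se not > 0")
  bad(is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1,
      "pvalue outside (0, 1]")
  bad(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf outside (0, 1)")

  drop <- nzchar(reasons)
  if (any(drop)) {
    warning(sprintf(
      "%s: dropped %d row(s): %s", source, sum(drop),
      paste(sprintf("%s (%s)", df$rsid[drop], reasons[drop]),
            collapse = "; ")), call. = FALSE)
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0L)
    stop(sprintf("%s: no valid rows", source), call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated table with header
#' `rsid effect_allele other_allele eaf beta se pvalue` (missing `eaf`
#' encoded as `NA`), validates every row, and returns one record per valid
#' SNP. Rows violating the invariants are rejected with a warning naming the
#' SNP and reason.
#'
#' @param path File path.
#' @param trait Optional [trait_meta()] attached to the result as the
#'   `"trait"` attribute (read by [standardize_to_sd()]).
#' @return Data frame of SNP associations, one row per SNP.
#' @export
read_summary_table <- function(path, trait = NULL) {
  if (!file.exists(path))
    stop("read_summary_table: file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  df <- validate_associations(df, source = basename(path))
  if (!is.null(trait)) attr(df, "trait") <- trait
  df
}

#' Write a summary-statistic table
#'
#' Inverse of [read_summary_table()]: tab-separated, canonical column order,
#' `NA` for missing allele frequencies.
#'
#' @param df Association data frame.
#' @param path Output file path.
#' @export
write_summary_table <- function(df, path) {
  utils::write.table(df[, SUMMARY_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rescale effects to the phenotype-SD scale
#'
#' GWAS frequently report continuous-trait effects in native units; MR
#' estimates here are per standard deviation of the exposure, so native-unit
#' `beta` and `se` are divided by the phenotype SD. The z-score (and hence
#' the p-value) is unchanged. Binary-trait effects are already log odds and
#' pass through untouched.
#'
#' @param assoc Association data frame (rows of SNP associations).
#' @param trait A [trait_meta()]; its `sd` is required for continuous traits
#'   (use `sd = 1` for tables already on the SD scale).
#' @return The rescaled data frame.
#' @examples
#' a <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
#'                 eaf = 0.3, beta = 0.93, se = 0.093, pvalue = 1e-9)
#' standardize_to_sd(a, trait_meta("BMI", sd = 4.65))$beta  # 0.2
#' @export
standardize_to_sd <- function(assoc, trait) {
  stopifnot(inherits(trait, "trait_meta"))
  if (isTRUE(trait$is_binary)) return(assoc)
  if (is.na(trait$sd))
    stop("standardize_to_sd: trait sd required for continuous trait '",
         trait$name, "'", call. = FALSE)
  assoc$beta <- assoc$beta / trait$sd
  assoc$se <- assoc$se / trait$sd
  assoc
}

#' Keep genome-wide significant SNPs
#'
#' Strict `pvalue < threshold` filter (a SNP at exactly the threshold is
#' excluded); input order is preserved.
#'
#' @param assocs Association data frame.
#' @param threshold Significance threshold, default the genome-wide
#'   5e-8.
#' @return The filtered data frame.
#' @export
filter_genomewide <- function(assocs, threshold = 5e-8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  out <- assocs[assocs$pvalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pairwise LD R-squared matrix
#'
#' Square tab-separated numeric table whose first column and header row are
#' rsids.
#'
#' @param path File path.
#' @return Numeric matrix with rsid dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}

#' Prune instruments to near-independence by LD
#'
#' Greedy p-value-ordered pruning (the standard clumping behaviour):
#' SNPs are visited by ascending p-value (ties broken by input order) and a
#' SNP is kept only if its R-squared with every already-kept SNP is strictly
#' below `threshold`.
#'
#' @param assocs Association data frame.
#' @param ld_r2 Square symmetric matrix of pairwise LD R-squared in
#'   \[0, 1\] with unit diagonal. Row/column order must match `assocs`
#'   (rsid dimnames, when present, are checked).
#' @param threshold Keep threshold on R-squared; default 0.01.
#' @return The pruned data frame, in original input order.
#' @export
ld_prune <- function(assocs, ld_r2, threshold = 0.01) {
  n <- nrow(assocs)
  if (!is.matrix(ld_r2) || nrow(ld_r2) != n || ncol(ld_r2) != n)
    stop("ld_prune: LD matrix dimension does not match the SNP list",
         call. = FALSE)
  if (!is.null(rownames(ld_r2)) &&
      !identical(unname(rownames(ld_r2)), assocs$rsid))
    stop("ld_prune: LD matrix rsids do not match the SNP list",
         call. = FALSE)
  ord <- order(assocs$pvalue, seq_len(n))
  kept <- integer(0)
  for (i in ord) {
    if (all(ld_r2[i, kept] < threshold)) kept <- c(kept, i)
  }
  out <- assocs[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}
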