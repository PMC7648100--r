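#' Describe the trait behind a summary-statistic table
#'
#' Metadata attached to one GWAS trait: whether it is binary, the phenotype
#' standard deviation used to rescale native-unit effects, sample sizes, and
#' the variance explained by its genetic instrument (liability scale for
#' binary exposures). Power calculations and standardization read from this.
#'
#' @param name Trait label, e.g. `"BMI"` or `"CD"`.
#' @param is_binary Logical; `TRUE` for case-control traits whose betas are
#'   log odds ratios.
#' @param sd Phenotype standard deviation in native units, used by
#'   [standardize_to_sd()] for continuous traits; `NA` when effects are
#'   already per SD (or the trait is binary).
#' @param n Total sample size.
#' @param n_cases,n_controls Case and control counts for binary traits; must
#'   sum to `n` when all three are given.
#' @param r2 Proportion of phenotype variance explained by the instrument,
#'   in (0, 1).
#'
#' @return An object of class `trait_meta`.
#' @examples
#' trait_meta("BMI", sd = 4.65, r2 = 0.06)
#' trait_meta("IBD", is_binary = TRUE, n_cases = 25042, n_controls = 34915)
#' @export
trait_meta <- function(name, is_binary = FALSE, sd = NA_real_, n = NA_real_,
                       n_cases = NA_real_, n_controls = NA_real_,
                       r2 = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.na(sd) && sd <= 0) stop("trait_meta: sd must be > 0", call. = FALSE)
  if (!is.na(r2) && (r2 <= 0 || r2 >= 1))
    stop("trait_meta: r2 must lie in (0, 1)", call. = FALSE)
  if (is_binary && !is.na(n_cases) && !is.na(n_controls)) {
    if (is.na(n)) n <- n_cases + n_controls
    if (!isTRUE(all.equal(n_cases + n_controls, n)))
      stop("trait_meta: n_cases + n_controls must equal n", call. = FALSE)
  }
  structure(list(name = name, is_binary = is_binary, sd = sd, n = n,
                 n_cases = n_cases, n_controls = n_controls, r2 = r2),
            class = "trait_meta")
}

#' @export
print.trait_meta <- function(x, ...) {
  cat("Trait:", x$name, if (x$is_binary) "(binary)" else "(continuous)", "\n")
  if (!is.na(x$sd)) cat("  SD:", x$sd, "\n")
  if (!is.na(x$n)) cat("  n:", x$n, "\n")
  if (x$is_binary && !is.na(x$n_cases))
    cat("  cases/controls:", x$n_cases, "/", x$n_controls, "\n")
  if (!is.na(x$r2)) cat("  instrument r2:", x$r2, "\n")
  invisible(x)
}
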