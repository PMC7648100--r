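test_that("well-formed tables parse row-for-row with uppercased alleles", {
  df <- assoc_df(c("rs1", "rs2", "rs3"), c("a", "C", "g"),
                 c("g", "T", "a"), c(0.2, 0.5, NA),
                 c(0.1, -0.2, 0.05), c(0.01, 0.02, 0.01),
                 c(1e-9, 1e-10, 1e-8))
  path <- write_assoc_file(df)
  got <- read_summary_table(path)
  expect_equal(nrow(got), 3L)
  expect_equal(got$effect_allele, c("A", "C", "G"))
  expect_true(is.na(got$eaf[3]))
  expect_equal(got$beta, df$beta)
})

test_that("invariant-violating rows are rejected with a warning", {
  df <- assoc_df(c("rs1", "rs2", "rs3"), c("A", "C", "G"),
                 c("G", "T", "A"), c(0.2, 0.5, 0.3),
                 c(0.1, -0.2, 0.05), c(0.01, 0, 0.01),
                 c(1e-9, 1e-10, 1e-8))
  path <- write_assoc_file(df)
  expect_warning(got <- read_summary_table(path), "se not > 0")
  expect_equal(nrow(got), 2L)
  expect_false("rs2" %in% got$rsid)

  # indels and identical alleles are likewise rejected
  df2 <- df
  df2$se[2] <- 0.01
  df2$other_allele[1] <- "AT"
  df2$effect_allele[3] <- "A"
  expect_warning(got2 <- validate_associations(df2), "single base")
  expect_equal(got2$rsid, "rs2")
})

test_that("structurally broken inputs raise errors", {
  df <- assoc_df("rs1", "A", "G", 0.2, 0.1, 0.01, 1e-9)
  path <- write_assoc_file(df[, setdiff(names(df), "se")])
  expect_error(read_summary_table(path), "missing mandatory column")

  bad <- assoc_df("rs1", "A", "G", 0.2, 0.1, -1, 1e-9)
  expect_error(suppressWarnings(validate_associations(bad)),
               "no valid rows")
})

test_that("standardization divides beta and se by the trait SD", {
  a <- assoc_df("rs1", "A", "G", 0.3, 0.93, 0.093, 1e-9)
  bmi <- trait_meta("BMI", sd = 4.65)
  out <- standardize_to_sd(a, bmi)
  expect_equal(out$beta, 0.2)
  expect_equal(out$se, 0.02)
  expect_equal(out$pvalue, a$pvalue)

  expect_identical(standardize_to_sd(a, trait_meta("x", sd = 1)), a)
  expect_identical(
    standardize_to_sd(a, trait_meta("CD", is_binary = TRUE)), a)
  expect_error(standardize_to_sd(a, trait_meta("x")), "sd required")
})

test_that("standardization preserves the z-score for random inputs", {
  set.seed(42)
  for (i in 1:20) {
    a <- assoc_df("rs1", "A", "G", 0.3, rnorm(1), runif(1, 0.01, 1),
                  runif(1))
    sdv <- runif(1, 0.1, 10)
    out <- standardize_to_sd(a, trait_meta("t", sd = sdv))
    expect_equal(out$beta / out$se, a$beta / a$se)
  }
})

test_that("genome-wide filter is strictly below the threshold", {
  df <- assoc_df(c("rs1", "rs2", "rs3"), "A", "G", 0.2, 0.1, 0.01,
                 c(1e-9, 5e-8, 1e-7))
  kept <- filter_genomewide(df)
  expect_equal(kept$rsid, "rs1")  # 5e-8 itself is excluded

  all_pass <- assoc_df(c("a", "b"), "A", "G", 0.2, 0.1, 0.01,
                       c(1e-10, 1e-9))
  expect_equal(filter_genomewide(all_pass), all_pass)
})

test_that("genome-wide filter matches a brute-force scan", {
  df <- random_assocs(100, seed = 7)
  df$pvalue <- 10^runif(100, -12, 0)
  thr <- 5e-8
  kept <- filter_genomewide(df, thr)
  brute <- df[vapply(df$pvalue, function(p) p < thr, logical(1)), ]
  rownames(brute) <- NULL
  expect_equal(kept, brute)
})

test_that("LD pruning keeps uncorrelated SNPs and prefers smaller p", {
  df <- random_assocs(5, seed = 1)
  eye <- diag(5)
  dimnames(eye) <- list(df$rsid, df$rsid)
  expect_equal(ld_prune(df, eye), df)

  two <- assoc_df(c("rs1", "rs2"), "A", "G", 0.2, 0.1, 0.01,
                  c(1e-9, 1e-10))
  m <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
              dimnames = list(two$rsid, two$rsid))
  expect_equal(ld_prune(two, m)$rsid, "rs2")  # the 1e-10 SNP wins

  expect_error(ld_prune(two, diag(3)), "dimension")
})

test_that("LD pruning equals an independent greedy re-implementation", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 20
    df <- random_assocs(n, seed = rep)
    df$pvalue <- runif(n)
    r <- matrix(runif(n * n), n)
    m <- (r + t(r)) / 2
    diag(m) <- 1
    thr <- 0.3
    # oracle: explicit greedy over the p-sorted index list
    ord <- order(df$pvalue, seq_len(n))
    kept <- integer(0)
    for (i in ord) if (!length(kept) || max(m[i, kept]) < thr)
      kept <- c(kept, i)
    oracle <- df[sort(kept), ]
    rownames(oracle) <- NULL
    expect_equal(ld_prune(df, m, thr), oracle)
  }
})

test_that("harmonization applies keep / flip / complement / drop rules", {
  exp <- assoc_df(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                  c("A", "A", "A", "A", "A"),
                  c("G", "G", "G", "T", "G"),
                  c(0.3, 0.3, 0.3, 0.3, 0.3),
                  c(0.1, 0.1, 0.1, 0.1, 0.1),
                  0.01, 1e-9)
  out <- assoc_df(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                  c("A", "G", "T", "A", "C"),
                  c("G", "A", "C", "T", "A"),
                  c(0.3, 0.7, 0.3, 0.3, 0.5),
                  c(0.05, 0.05, 0.05, 0.05, 0.05),
                  0.02, 0.01)
  inst <- harmonize(exp, out)
  d <- as.data.frame(inst)
  expect_equal(d$flag,
               c("kept", "flipped", "strand-complemented",
                 "dropped-palindromic", "dropped-missing"))
  expect_equal(inst$y, c(0.05, -0.05, 0.05))
  expect_equal(d$eaf_outcome[1:3], c(0.3, 0.3, 0.3))

  expect_error(harmonize(exp, transform(out, rsid = paste0("x", rsid))),
               "no shared")
})

test_that("harmonization is idempotent on its own output", {
  sim <- simulate_pair(sim_config(n_snp = 30, theta = 0.2, seed = 5,
                                  palindromic_frac = 0.2))
  inst <- harmonize(sim$exposure, sim$outcome)
  d <- as.data.frame(inst)
  kept <- d[!startsWith(d$flag, "dropped"), ]
  exp2 <- data.frame(rsid = kept$rsid, effect_allele = kept$effect_allele,
                     other_allele = kept$other_allele,
                     eaf = kept$eaf_exposure, beta = kept$x, se = kept$sx,
                     pvalue = kept$pvalue_exposure)
  out2 <- data.frame(rsid = kept$rsid, effect_allele = kept$effect_allele,
                     other_allele = kept$other_allele,
                     eaf = kept$eaf_outcome, beta = kept$y, se = kept$sy,
                     pvalue = 0.5)
  inst2 <- harmonize(exp2, out2)
  expect_true(all(as.data.frame(inst2)$flag == "kept"))
  expect_equal(inst2$x, inst$x)
  expect_equal(inst2$y, inst$y)
  expect_equal(inst2$rsid, inst$rsid)
})

test_that("flipping outcome alleles and beta signs leaves the instrument
           unchanged", {
  sim <- simulate_pair(sim_config(n_snp = 25, theta = 0.2, seed = 9))
  inst <- harmonize(sim$exposure, sim$outcome)
  flipped <- sim$outcome
  flipped$effect_allele <- sim$outcome$other_allele
  flipped$other_allele <- sim$outcome$effect_allele
  flipped$beta <- -sim$outcome$beta
  flipped$eaf <- 1 - sim$outcome$eaf
  inst2 <- harmonize(sim$exposure, flipped)
  expect_equal(inst2$x, inst$x)
  expect_equal(inst2$y, inst$y)
  expect_equal(inst2$sy, inst$sy)
})

test_that("significance filtering commutes with p-value-ordered pruning", {
  set.seed(3)
  n <- 15
  df <- random_assocs(n, seed = 3)
  df$pvalue <- 10^runif(n, -10, -5)
  r <- matrix(runif(n * n), n); m <- (r + t(r)) / 2; diag(m) <- 1
  dimnames(m) <- list(df$rsid, df$rsid)
  thr <- 1e-7

  a <- filter_genomewide(ld_prune(df, m, 0.3), thr)
  keep <- df$pvalue < thr
  bdf <- df[keep, ]; rownames(bdf) <- NULL
  b <- ld_prune(bdf, m[keep, keep, drop = FALSE], 0.3)
  # all filter survivors precede all failures in the greedy p-order, so
  # their keep/drop decisions cannot depend on the failures
  expect_equal(a, b)
})
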