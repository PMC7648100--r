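# Shared fixtures: small association tables and instruments built in code.

assoc_df <- function(rsid, ea, oa, eaf, beta, se, pvalue) {
  data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue,
             stringsAsFactors = FALSE)
}

random_assocs <- function(n, seed = 1) {
  set.seed(seed)
  pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  al <- pairs[sample(4, n, replace = TRUE)]
  assoc_df(sprintf("rs%04d", seq_len(n)),
           vapply(al, `[`, "", 1), vapply(al, `[`, "", 2),
           runif(n, 0.05, 0.95), rnorm(n, 0, 0.1),
           runif(n, 0.005, 0.05), runif(n))
}

random_instrument <- function(J, seed, theta = 0.5,
                              sx = 0.01, sy = 0.03) {
  set.seed(seed)
  x <- runif(J, 0.05, 0.3) * sample(c(-1, 1), J, replace = TRUE)
  mr_instrument(x = x, sx = rep(sx, J),
                y = theta * x + rnorm(J, 0, sy), sy = rep(sy, J))
}

# weighted-median oracle used by the brute-force checks: explicit
# cumulative-weight polyline interpolation
med_oracle_w <- function(v, w) {
  o <- order(v); v <- v[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(v[1])
  if (p[length(p)] <= 0.5) return(v[length(v)])
  approx(p, v, xout = 0.5, ties = "ordered")$y
}

write_assoc_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
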