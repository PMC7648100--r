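---
title: "Methods: two-sample Mendelian randomization in ivmr"
author: "ivmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in ivmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivmr)
```

# The causal model and its assumptions

Two-sample Mendelian randomization treats genetic variants as
instrumental variables for an exposure. For SNP $j$ the exposure GWAS
reports an effect $x_j$ (standard error $s_{xj}$), the outcome GWAS an
effect $y_j$ (log odds, SE $s_{yj}$), estimated in non-overlapping
samples. Under the instrumental-variable assumptions — the SNP is
associated with the exposure, independent of confounders, and affects
the outcome only through the exposure — and a linear exposure-outcome
relationship, every SNP satisfies $y_j = \theta\,x_j$ where $\theta$ is
the causal log odds ratio per SD of exposure.

The package's primary estimator models the observed effects as
bivariate normal around the true instrument effects $\xi_j$:

$$\hat x_j \sim N(\xi_j, s_{xj}^2), \qquad
  \hat y_j \sim N(\theta\,\xi_j, s_{yj}^2),$$

independently across SNPs and samples. Maximizing the likelihood over
the nuisance effects $\xi_j$ in closed form leaves the profile
objective

$$g(\theta) \;=\; \sum_j \frac{(y_j - \theta x_j)^2}
                              {s_{yj}^2 + \theta^2 s_{xj}^2},$$

minimized over $\theta$ by Brent search on an automatically widened
bracket around the range of Wald ratios (cap: 50 doublings; the
profile objective is smooth with a finite limit at $\pm\infty$, so an
interior minimum exists). Since $g = -2\log L$ up to a constant, the
standard error is $\sqrt{2/g''(\hat\theta)}$ with $g''$ by central
finite difference at step $10^{-4}(1+|\hat\theta|)$. When the exposure
SEs vanish the objective collapses to inverse-variance weighting, so
the estimator continuously degenerates to IVW — a property the test
suite checks at $s_x = 10^{-8}$ against a $10^{-6}$ tolerance.

All estimators report 95% intervals as $\hat\theta \pm 1.96\,SE$ on the
log-odds scale and two-sided normal z p-values. A single convention is
used everywhere (including the Egger intercept test) in preference to
mixing z and small-sample t references across methods; with the 3-SNP
minimum that Egger enforces, the z-based intercept test is mildly
anticonservative at very small $J$, which is one reason the pipeline
treats Egger as a sensitivity analysis rather than a primary result.

# Sensitivity estimators

**IVW** is the zero-intercept weighted regression of $y$ on $x$ with
weights $1/s_{yj}^2$ and fixed-effect SE $1/\sqrt{\sum_j x_j^2/s_{yj}^2}$.

**MR-Egger** frees the intercept: $y_j = \alpha + \theta x_j$, after
re-signing each SNP so $x_j \ge 0$ (the intercept is only meaningful
relative to the exposure-increasing allele). A non-zero $\alpha$
estimates the average directional pleiotropic effect. Both SEs carry
the multiplicative random-effects inflation $\max(1, \hat\sigma)$ with
$\hat\sigma^2 = RSS_w/(J-2)$: balanced pleiotropy then widens the
intervals instead of inflating the intercept test's size, while the fit
is never allowed to claim less noise than the outcome SEs imply. This
is the convention of the originating Egger-regression literature; a
plain fixed-effect version rejects far too often precisely in the
regime the test exists for.

**Weighted median**: Wald ratios are sorted, weighted by the
first-order inverse variance of the ratio $w_j = (x_j/s_{yj})^2$
(normalized), and the estimate interpolates the cumulative mid-weight
polyline $p_j = \sum_{k\le j} w_k - w_j/2$ at $p = 0.5$. The weighted
(not simple or penalized) variant is the default because it is the
originating method's headline form; consistency requires $\ge 50\%$ of
weight on valid instruments.

**Mode-based estimate**: a weighted normal-kernel density over the
ratios with the modified Silverman bandwidth
$h = \phi \cdot 0.9\,\min(\mathrm{sd}_w, \mathrm{MAD}_w/0.6745)\,J^{-1/5}$,
$\phi = 1$ by default; the estimate is the density argmax on a uniform
grid of $10^5$ points spanning the ratio range $\pm 3h$. If all ratios
coincide the bandwidth is zero and the common ratio is returned with
SE 0. The simple-vs-weighted and $\phi$ choices are not identifiable
from the source study; the weighted variant with $\phi = 1$ matches the
method's published defaults.

Both resampling-based SEs come from a parametric bootstrap (default
1000 draws of $x_j^* \sim N(x_j, s_{xj}^2)$,
$y_j^* \sim N(y_j, s_{yj}^2)$, re-deriving ratios and weights each
time); a seed is mandatory, so results are bit-reproducible. The
bootstrap mode search uses a $10^4$-point grid per replicate — the
point estimate keeps the fine grid, the bootstrap only needs the SE of
the argmax location.

**Cochran Q** uses ratio weights $(x_j/s_{yj})^2$ around the IVW slope
with $J-1$ degrees of freedom.

# MR-PRESSO

The global statistic is a leave-one-out weighted residual sum of
squares: $RSS = \sum_j w_j (y_j - \hat\theta_{-j} x_j)^2$,
$w_j = 1/s_{yj}^2$, with $\hat\theta_{-j}$ the IVW slope excluding SNP
$j$. Its null distribution comes from parametric draws
$x_j^* \sim N(x_j, s_{xj}^2)$, $y_j^* \sim N(\hat\theta_{-j}x_j,
s_{yj}^2)$ with the full leave-one-out RSS recomputed per draw;
p-values use the add-one convention $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$,
so the smallest representable p is $1/(n_{sim}+1)$. The default
$n_{sim} = 5000$ resolves p-values to $2\times10^{-4}$; reporting
bounds like $p < 10^{-4}$ requires $n_{sim} \ge 10^4$, which the CLI
exposes as `--presso-sims`. Per-SNP outlier p-values compare each
observed weighted squared residual to its simulated counterparts,
Bonferroni-multiplied by $J$, flagged below 0.05. The distortion test
compares the outlier-removed IVW slope to the full one against a null
of equally many random removals (two-sided).

*Known limitation.* Because the simulated null seeds each SNP's mean
with the observed leave-one-out slopes, a single large outlier on the
highest-leverage SNP of a small instrument contaminates the other SNPs'
slopes and with them the null draws; the outlier test can then fail to
flag it. The effect dilutes roughly as $1/J$ and is immaterial at the
instrument sizes this package targets (tens of SNPs); the test suite
exercises detection at $J = 40$, the scale of the mid-size instruments
in the motivating study design, where a 10-SE outlier is flagged in
100/100 seeded runs while the global test stays at its nominal 5% size
under the null.

# Harmonization and instrument selection

Summary tables are tab-separated with header
`rsid effect_allele other_allele eaf beta se pvalue`. Rows violating
the per-SNP invariants (single-base distinct alleles, $se > 0$,
$p \in (0,1]$, $eaf \in (0,1)$ when present) are dropped with a logged
reason; indels are rejected, alleles uppercased. Continuous-trait
effects in native units are divided by the phenotype SD (e.g. 4.65
kg/m² for BMI), leaving z-scores untouched.

Instrument selection is a strict $p < 5\times10^{-8}$ filter followed
by greedy LD pruning: SNPs visited by ascending p-value (ties by input
order, for determinism), kept only if $R^2 < 0.01$ with every SNP
already kept. The source study does not state its pruning algorithm;
greedy p-ordered pruning is the standard clumping behaviour and is
deterministic. The pipeline accepts pre-pruned instrument lists equally
(set `p_threshold = NULL`), since published instrument sets may have
been pruned jointly in their discovery GWAS.

Harmonization aligns each shared rsid to the exposure's effect allele:
matching alleles are kept; swapped alleles negate the outcome beta and
reflect its frequency; alleles matching only after A↔T/C↔G
complementing are strand-corrected first. Palindromic SNPs (A/T, C/G)
are dropped by default — their strand cannot be resolved from alleles,
and proxy substitution from an LD reference panel is outside this
package's scope. Users with reliable allele frequencies can instead set
`palindromic_action = "infer"`, which aligns by minor-allele status
when $\min(eaf, 1-eaf) < 0.42$ in both samples (beyond 0.42 the minor
allele is too ambiguous to trust).

# Power and subtype heterogeneity

For a binary outcome with $N$ samples, case fraction $p$, and an
instrument explaining $r^2$ of exposure variance, the causal log OR has
asymptotic variance $1/(N r^2 p(1-p))$, giving the minimum detectable
OR $\exp[(z_{1-\alpha/2} + z_{power})/\sqrt{N r^2 p(1-p)}]$ and its
inverse, the power at a postulated OR. The target power defaults to
0.80, the design convention of the method this reproduces. Subtype
(CD/UC) designs require subtype-specific control counts; with shared
controls the subtype columns of a published design table are not
reproducible from printed numbers alone, so only the combined-IBD
design is used as a reference point.

CD-vs-UC heterogeneity for one exposure is the two-study fixed-effect
Q: inverse-variance pooled mean, $Q = \sum (\theta_i - \bar\theta)^2 /
se_i^2$ on 1 df. When one subtype estimate is not estimable (2-SNP
instruments for Egger/median/mode), the test records NA rather than
degrade to a one-sided comparison. Published estimates enter through
`estimate_from_or_ci()`, which inverts the printed OR and 95% CI
($se = \log(\text{hi}/\text{lo})/3.92$); printed rounding propagates
roughly one significant digit of slack into reconstructed p-values.

# The synthetic-data generator

`simulate_pair()` emulates the statistical structure the estimators
assume: MAFs uniform on [0.05, 0.5]; true effects $\gamma_j$ normal,
rescaled so $\sum_j 2\,maf_j(1-maf_j)\gamma_j^2$ equals the target
$r^2$ exactly (drawn-then-rescaled, to produce realistic weight
heterogeneity rather than equal effects); SEs from the standard
summary-statistic asymptotics, with the case-control effective sample
size $n_{ca}n_{co}/N$ on the log-odds scale; exposure and outcome draws
independent (a true two-sample setting). Defaults mirror the motivating
study's scale: 25,042 cases, 34,915 controls, exposure GWAS of 300,000
(the scale of the anthropometric-trait discovery GWAS). Pleiotropy
modes: `none`; `balanced` ($N(0,\tau^2)$); `directional`
($N(\mu,\tau^2)$, applied along the exposure-increasing allele — a
constant shift on an arbitrary allele orientation would cancel under
Egger's orientation and is not what directional pleiotropy means);
`outlier` (a chosen number of SNPs displaced by a multiple of their
outcome SE). Allele pairs are assigned with a configurable palindromic
fraction, and the outcome table is randomly allele-swapped and
strand-complemented so harmonization is genuinely exercised. P-values
are floored at the smallest positive double to respect the $(0,1]$
invariant under extreme z-scores.

What the generator does **not** emulate: LD between instrument SNPs
(pruning is tested against user-supplied matrices), sample overlap
between the two GWAS, winner's-curse in instrument discovery,
non-collapsibility of the odds ratio, and MAF-dependent effect-size
architecture. Passing tests therefore demonstrate correctness of the
estimators under their own model, not robustness to those real-data
features.

`study_instrument_designs()` packages the 13 instrument designs of the
motivating study (SNP counts from 2 to 816, variance explained from
0.08% to 6.3%) for end-to-end dry runs shaped like the real analysis.

# Pipeline conventions

`run_study()` runs every exposure × outcome pair through harmonization
and all estimators; the likelihood-based estimate is the primary
result, everything else sensitivity. Bonferroni divides $\alpha$ by the
number of *exposures* (13 in the reference design, threshold
0.05/13 ≈ 0.0038), not exposure × outcome pairs, and is applied to the
primary estimate's p-value only. Instruments with 2 SNPs keep valid
likelihood/IVW/Q results and record NA for Egger, weighted median,
mode, and PRESSO (which needs 4); pair-level failures are logged and
the run continues. Per-pair seeds derive deterministically from the
master seed, so the whole report is byte-reproducible. The test suite
runs its studies at desk scale — instruments of 2–50 SNPs, simulation
batches of 100–500 replicates, PRESSO at 1000 resamples — sizes chosen
so the full statistical checks (type-I error within binomial error of
0.05 over 500 null instruments, recovery of $\theta = 0.3$ within
±0.02 over 200 replicates, 100-seed outlier detection) remain sharp.

# Known limitations

Beyond the generator's scope above: no multivariable MR, no
correlated-instrument (GLS) variants, no Steiger direction filtering,
no LD-proxy lookup (pre-resolve proxies upstream), no genome-build
liftover, and no multi-allelic variants. The Egger intercept is weakly
identified when instrument strengths are homogeneous (all $x_j$
similar): its SE grows with the extrapolation to $x = 0$, and the
intercept test then has low power regardless of implementation.
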