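# ivmr — two-sample Mendelian randomization from GWAS summary statistics

`ivmr` estimates the causal effect of a modifiable exposure (body-mass
index, smoking, circulating nutrient levels, ...) on a binary disease
outcome such as inflammatory bowel disease (IBD) and its subtypes,
Crohn's disease (CD) and ulcerative colitis (UC), using genetic variants
as instrumental variables. It is written for epidemiologists and
statistical geneticists working from published GWAS summary statistics:
no individual-level data are needed, only per-SNP association tables for
the exposure (one GWAS sample) and the outcome (an independent GWAS
sample).

## The model

For SNP *j*, let *x<sub>j</sub>* be its effect on the exposure (in SD
units, with standard error *s<sub>xj</sub>*) and *y<sub>j</sub>* its
effect on the outcome (log odds, SE *s<sub>yj</sub>*). A valid
instrument satisfies *y<sub>j</sub>* = θ·*x<sub>j</sub>*, where θ is the
causal log odds ratio per SD of exposure — each SNP's Wald ratio
*y<sub>j</sub>/x<sub>j</sub>* estimates θ. The headline estimator is the
likelihood-based one: observed effects are modelled as

> x<sub>j</sub> ~ N(ξ<sub>j</sub>, s<sub>xj</sub>²),  y<sub>j</sub> ~ N(θ ξ<sub>j</sub>, s<sub>yj</sub>²)

and profiling out the true effects ξ<sub>j</sub> reduces maximum
likelihood to minimizing Σ<sub>j</sub> (y<sub>j</sub> − θx<sub>j</sub>)² / (s<sub>yj</sub>² + θ²s<sub>xj</sub>²).
Around it sit the standard sensitivity analyses — IVW, MR-Egger (with
its directional-pleiotropy intercept test), weighted median, mode-based
estimate, Cochran Q, and the MR-PRESSO global/outlier/distortion
resampling tests — plus a-priori power (minimum detectable OR), a
CD-vs-UC fixed-effect heterogeneity test, instrument selection
(genome-wide significance filter, LD pruning), allele harmonization,
and a synthetic summary-statistic generator with known causal effect
and controllable pleiotropy.

## Worked example

```r
library(ivmr)

# a synthetic study: 40 SNPs, true theta = 0.3, 5% variance explained,
# IBD-scale outcome (25,042 cases / 34,915 controls)
sim  <- simulate_pair(sim_config(n_snp = 40, theta = 0.3, r2_target = 0.05,
                                 palindromic_frac = 0.1, seed = 2024))
inst <- harmonize(sim$exposure, sim$outcome)
inst
#> Harmonized MR instrument: 36 SNP(s)
#>   flags: dropped-palindromic=4, flipped=7, kept=15, strand-complemented=14

mr_fit(inst, "ml")
#> MR estimate (ml), 36 SNP(s)
#>   theta (log OR/SD) = 0.326 (SE 0.041)
#>   OR = 1.385 [1.277, 1.503], p = 3.59e-15

egger_estimate(inst)
#> MR estimate (egger), 36 SNP(s)
#>   theta (log OR/SD) = 0.403 (SE 0.070)
#>   OR = 1.497 [1.305, 1.716], p = 7.54e-09
#>   Egger intercept = -0.005 (SE 0.004), p = 0.165

cochran_q(inst)
#> Cochran Q = 30.8 on 35 df, p = 0.671

mr_presso(inst, n_sim = 5000, seed = 1)
#> MR-PRESSO (5000 simulations)
#>   Global test: RSS = 32.24, p = 0.692
#>   No outlier SNPs flagged

power_spec(0.06, 25042, 34915)
#> MR power design: r2 = 0.06, 25042 cases / 34915 controls, alpha = 0.05
#>   minimum detectable OR at 80% power: 1.10
```

Reading: the 4 palindromic (A/T, C/G) SNPs are dropped because their
strand cannot be resolved from alleles alone; the remaining 36 are
aligned to the exposure's effect allele. The likelihood-based OR of 1.39
per SD recovers the simulated truth (e^0.3 ≈ 1.35) within its CI; the
near-zero Egger intercept, null Q, and null PRESSO global test all say
no pleiotropy — exactly as simulated. The power line says this design
can detect ORs of 1.10 or larger.

A full multi-exposure study (harmonize → all estimators → Bonferroni →
CD/UC heterogeneity → power and plot-data tables) runs through
`run_study()`; `exec/ivmr` wraps it for the shell
(`ivmr run|estimate|power|simulate`).

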