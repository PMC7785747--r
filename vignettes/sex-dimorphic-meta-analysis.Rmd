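---
title: "Sex-dimorphic GWAS meta-analysis: models, tests, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-dimorphic GWAS meta-analysis: models, tests, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexmeta)
```

## The problem

Genome-wide association studies of quantitative glycemic traits — fasting
glucose (FG, mmol/L) and fasting insulin (FI, analyzed as natural-log
pmol/L) — are usually meta-analyzed with men and women pooled. When an
allele's effect differs between the sexes, the pooled analysis averages the
two effects and can miss the signal entirely, most severely when the effect
is confined to one sex. This package implements the statistical machinery of
a sex-stratified alternative: sex-specific fixed-effect meta-analysis,
a 2-degree-of-freedom sex-dimorphic test, a between-sex heterogeneity test,
and the downstream analyses that interpret what those tests find (locus
discovery, approximate conditional analysis, power evaluation, bidirectional
Mendelian randomization, and sex-interaction expression models).

## The core statistics

**Inverse-variance pooling.** Per-study per-sex effect estimates
$(\hat\beta_i, se_i)$ are combined with weights $w_i = 1/se_i^2$:
$\hat\beta = \sum w_i \hat\beta_i / \sum w_i$, $se = 1/\sqrt{\sum w_i}$
(`ivw_meta()`). The model is fixed-effects throughout: the estimand is one
common allelic effect per stratum.

**The 2-df sex-dimorphic test.** With pooled female and male z-statistics
$z_f = \hat\beta_f/se_f$ and $z_m = \hat\beta_m/se_m$, the statistic
$T^2 = z_f^2 + z_m^2$ is chi-square with 2 df under the joint null of no
effect in either sex (`sex_dimorphic_test()`). Its p-value has the closed
form $\exp(-T^2/2)$, which the implementation matches to $10^{-12}$. The
test spends one degree of freedom per sex, so it loses little against the
1-df combined test for concordant effects and gains a lot for discordant
ones.

**Cochran's Q and I².** Between-sex heterogeneity is
$Q = \sum_s w_s (\hat\beta_s - \hat\beta)^2$, which for the two sexes
reduces to $(\hat\beta_f - \hat\beta_m)^2 / (se_f^2 + se_m^2)$, chi-square
with 1 df under homogeneity (`cochran_q()`). The same machinery applies to
paired genetic-correlation estimates. $I^2 = \max(0, (Q - df)/Q) \times 100$
expresses heterogeneity as a percentage independent of the number of
estimates (`i_squared()`).

**The decomposition identity.** For any pair of per-sex estimates,
$z_f^2 + z_m^2 = z_{pooled}^2 + Q$ exactly: the dimorphic statistic splits
algebraically into "shared effect" and "sex difference" components. The test
suite asserts this to $10^{-10}$ over $10^5$ random pairs; it is a sharp
correctness check because it couples three independently coded operations.

**Genomic control.** Residual confounding inflates association statistics
multiplicatively; $\lambda = \mathrm{median}(\chi^2)/0.4549$ estimates the
inflation and $se \to se\sqrt{\lambda}$ corrects it (`genomic_control()`,
`gc_adjust_se()`). Two conventions are baked in: $\lambda < 1$ is never
applied (no deflation — correction can only widen intervals), and
Metabochip-design studies estimate $\lambda$ on a designated null-ish subset
of variants rather than the full chip, which is enriched for true signal.
Because of the no-deflation rule, corrected statistics are *slightly
conservative under an exact null*: with $\lambda$ estimated from $10^4$
variants its sampling noise (SD about 0.02) triggers shrinkage half the
time and never the reverse. Calibration of the pipeline is therefore judged
on the genomic-control $\lambda$ *measured on* the raw pooled statistics,
which is the estimate the correction would act on.

## The meta-analysis pipeline

`meta_pipeline()` runs three strategies over harmonized, QC-passed study
panels: sex-specific pooling, the sex-dimorphic test on the pooled per-sex
estimates, and a sex-combined analysis. Studies of highly related
individuals, analyzed jointly with a sex adjustment, are supplied as
`sex = "combined"` panels and enter only the combined analysis. The combined
column defaults to joint pooling of every contributing study
(`combined_mode = "joint"`); IVW combination of the two sex-level pooled
estimates plus family studies is available as `"pooled_sexes"` — with one
study per sex the two coincide, and the joint form was chosen as default
because it weighs family studies on the same footing as everything else.
Genomic control is applied at the study level before pooling and,
configurably (default on), to the pooled per-sex statistics, mirroring the
two-stage monitoring that sex-differentiated meta-analyses report.

### Harmonization and QC

Allele harmonization (`harmonize()`) tries identity, allele swap
($\beta \to -\beta$, $f \to 1-f$), strand complement, and complement+swap,
in that order. Palindromic pairs (A/T, C/G) are label-ambiguous under strand
flips, so they are aligned by allele frequency, and only when both the
record and the reference frequency are at least 0.08 away from 0.5;
otherwise the record is rejected with a dedicated reason code. The 0.08
margin is a documented package choice (common practice), not something the
underlying study states. Harmonization is idempotent, and a swap followed by
the inverse swap recovers the original record to machine precision.

QC (`qc_filter()`) applies the conventional variant-exclusion rules — call
rate < 0.95, MAF < 0.01, minor allele count < 10, Hardy–Weinberg
p < 1e-4, imputation info < 0.5 (0.7 after summary-statistic imputation), all
strict inequalities — but only where the field is present: study files differ
in which QC columns they deliver, and an absent field never removes a
record. Malformed rows (non-ACGT alleles, nonpositive SE, frequencies
outside [0,1]) are quarantined with reasons at parse time, never silently
dropped.

## Locus discovery and conditional analysis

A variant qualifies as a lead when either the combined or the dimorphic test
reaches $P \le 5\times 10^{-8}$. Lead selection is greedy per chromosome —
lowest qualifying p wins a ±500 kb window; ties break by position, then
marker id (the underlying study states no rule; this one makes the call set
order-independent, which the suite verifies by permuting input rows). A lead
is *novel* when it is more than 500 kb from every established lead for the
trait **and** not in LD with any of them ($r^2 < 0.01$); without an LD
table the distance rule decides alone and the output is flagged. Established
loci are screened for between-sex heterogeneity at the Bonferroni level
$0.05/n_{loci}$ (0.0014 for 36 FG loci, 0.0026 for 19 FI loci).

`approx_conditional()` reconstructs the two-SNP joint regression from
marginal summary statistics: Hardy–Weinberg genotype variances $2f(1-f)$,
their covariance implied by the LD correlation $r$, and the phenotypic
variance recovered from each SNP's own marginal fit. At $r = 0$ the joint
point estimate equals the marginal one exactly; the joint SE differs from
the marginal SE only through the conditioning SNP's explained variance and a
degrees-of-freedom adjustment (the suite allows 1%). $|r| \ge 0.99$ is
refused as singular. Against an individual-level two-covariate OLS oracle on
simulated cohorts ($n = 2000$, $r \in \{0, 0.3, 0.6\}$, CAF
$\in \{0.1, 0.3, 0.5\}$), at least 95% of replicates agree within 2 joint
SEs.

## The power study

`simulate_replicates()` draws per-sex effect estimates directly:
$\hat\beta_s \sim N(\beta_s, se_s^2)$ with $se_s = 1/\sqrt{2 N_s f (1-f)}$
for a unit-variance trait under Hardy–Weinberg genotype frequencies. This
summary-level shortcut is exact up to the $t$-vs-normal distinction at
GWAS sample sizes; a genotype-level mode (dosages $\sim$ Binomial(2, f),
per-sex least squares) is kept as the fidelity oracle and the two agree
within Monte-Carlo error. Residual variance is approximated as 1: a single
SNP with $|\beta| \le 0.1$ SD explains at most 0.5% of trait variance, so
the approximation is negligible at the effect sizes studied.

Four tests are evaluated — sex-combined (1 df), sex-dimorphic (2 df),
female-specific (1 df), and Cochran's Q heterogeneity (1 df) — under three
scenarios: homogeneous ($\beta_m = \beta_f$), dimorphic ($\beta_m$ fixed at
0.05 SD), and single-sex ($\beta_m = 0$). `analytic_power()` provides the
noncentral-chi-square oracle, with noncentrality $(\beta/se)^2$ per stratum
(summed for the 2-df test; $(\beta_f-\beta_m)^2/(se_f^2+se_m^2)$ for Q), and
the empirical estimates must sit within 4 Monte-Carlo SEs of it. The default
conditions are the study's: 70,000 per sex, 10,000 replicates,
$\alpha = 5\times10^{-8}$ for genome-wide grids and $0.05/36$ or $0.05/19$
for the established-loci screens (the heterogeneity-test $\alpha$ is a free
parameter because published usage varies between these levels). Chi-square
thresholds are always derived from $\alpha$, never hard-coded.

## Mendelian randomization

Instruments are genome-wide-significant SNPs pruned greedily to mutual
$r^2 < 0.001$ (1-Mb distance fallback when no LD source exists, flagged).
Per-variant Wald ratios use the first-order delta SE
$se_{out}/|\beta_{exp}|$ by default — the convention of standard two-sample
MR — with the second-order form available by flag. The combined estimate is
the random-effect IVW: the slope of the weighted zero-intercept regression
of outcome on exposure betas (weights $1/se_{out}^2$), with SE inflated by
$\sqrt{\max(1, Q/(k-1))}$ — multiplicative dispersion floored at 1, so
homogeneous instruments reproduce the fixed-effect result exactly. MR-Egger
adds a free intercept after orienting all instruments to
$\beta_{exp} \ge 0$; the intercept estimates directional pleiotropy, the
slope is the pleiotropy-robust causal estimate, SEs use the same floored
dispersion and p-values the $t_{k-2}$ distribution. `mr_bidirectional()`
runs both estimators over the four direction-by-sex cells and judges IVW
significance at $0.05/4 = 0.0125$.

The synthetic MR system (`generate_mr_system()`) follows the generative
model: tabulated exposure betas drawn from a spread distribution, outcomes
$= \text{slope}\cdot\beta_{exp} + \text{pleiotropy} + \text{noise}$. The
exposure betas carry no extra observation noise — they emulate a
biobank-scale exposure GWAS ($N \approx 2\times10^5$; reported
`se_exposure` ≈ 0.003) whose instrument-exposure associations are precise
enough that the no-measurement-error assumption behind the IVW/Egger weights
holds. Violating that regime (exposure-side noise comparable to the weakest
instrument effects) introduces regression-dilution bias that no number of
instruments removes; users simulating weak-instrument settings should
expect the documented attenuation. The headline causal estimate of the
motivating design ($\beta_{IV} = 1.86$, 222 instruments, women only) is
*data-gated*: reproducing it needs the original instrument tables, so the
package instead demonstrates parameter recovery at the same instrument
count.

## Expression models

The eQTL models are, per gene: a common-slope fit
$y = \mu_{sex} + \pi_{plate} + \beta g$ and a sex-specific-slope fit
$y = \mu_{sex} + \pi_{plate} + \beta_{sex} g$. The sex-interaction test is
the 1-df Wald contrast $\beta_f - \beta_m$ from the joint fit, which agrees
with the nested-model F test within 2% at $n \ge 500$ (both are reported).
Rank-deficient designs (e.g. plate confounded with sex) fail loudly, naming
the aliased terms. Sex-differential expression regresses each gene on sex
plus covariates, with male as the reference level so positive coefficients
mean higher expression in women; zero-variance genes are flagged and
excluded from the BH adjustment rather than propagating NaNs. Permutation
p-values (sex-label permutation, configurable count and seed) are available
for both analyses' interaction statistic.

Random effects of the original designs (plate/family/zygosity) are
deliberately approximated by fixed plate effects: the package's scope is
the fixed-effect core, and the approximation is conservative for balanced
plates. A faithful mixed model is out of scope.

One propagation worth knowing: BH adjustment is *not* idempotent — adjusting
an already-adjusted vector changes it again except at fully tied fixed
points — so adjusted p-values must never be re-fed to `bh_adjust()`.

## The synthetic-data layer

`generate_study_sumstats()` emulates the meta-analysis input: per study and
sex, estimates drawn around configurable sex-specific truths with sampling
variance $\lambda_{study}/(2nf(1-f))$, so $\lambda_{study} > 1$ injects
exactly the overdispersion genomic control corrects while the reported SE
column stays at its nominal value. A configurable fraction of rows is
emitted with swapped or strand-complemented alleles (palindromic injection
opt-in) to exercise harmonization; after `harmonize_to_reference()` the
results are bit-identical to a discordance-free run with the same seed.
Every generator demands a seed, is byte-identical under it, and writes its
truth alongside; downstream recovery tests read truth only from there.
`prepare_phenotypes()` encodes the trait conventions: whole-blood FG scaled
by 1.13 to plasma level, exclusion at (corrected) FG ≥ 7 mmol/L or
diagnosed/treated diabetes, FI natural-log transformed with nonpositive
values excluded.

What the generator does *not* emulate: LD structure between variants
(independent draws, except the explicit block structure used by the pruning
tests), covariate-driven confounding, imputation-quality gradients, and
relatedness. Passing tests therefore certify the statistical machinery under
its stated assumptions, not robustness to the full messiness of real
consortium files.

## Numerical choices and problem sizes

- P-values are floored at 1e-300 with the statistic always reported
  alongside, so ranking survives underflow.
- Chi-square tails and quantiles come from R's `pchisq`/`qchisq`; nothing
  distributional is hand-rolled.
- Two-sided tests throughout; no silent 1-df fallback when one sex is
  missing — dimorphic and heterogeneity columns go NA.
- The test suite uses one canonical seed (42) for its stochastic fixtures;
  the simulation sizes it runs at are 10,000 replicates for power cells,
  $10^4$ variants for null calibration, 200 seeds for estimator-coverage
  sweeps, and $10^5$ pairs for the decomposition identity — sizes at which
  every asserted band is comfortably inside Monte-Carlo noise while the
  whole suite runs in well under a minute.
- 2-SE coverage assertions are inherently knife-edge against a 95% bound
  (nominal normal coverage is 95.4%); the conservative SE floors of the
  random-effect IVW and Egger keep the realized coverage above the bound.

## Known limitations

- Fixed-effects only, by design; random-effects across studies and
  trans-ancestry extensions are out of scope.
- Chromosome X is excluded (autosomes 1–22); the sex-stratified analysis of
  X needs dosage-compensation conventions the package does not model.
- The conditional solver handles exactly two SNPs — the reported use case —
  not stepwise multi-SNP selection.
- Consuming real GWAS files requires only the dialect mapping
  (`default_column_map()`), but LD must be supplied externally; the package
  computes nothing from genotypes.
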