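---
title: "Methods: detecting polygenic type 1 diabetes in infants diagnosed before 6 months"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting polygenic type 1 diabetes in infants diagnosed before 6 months}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlyt1d)
```

## The problem

Nearly all diabetes diagnosed before 6 months of age is monogenic, but a
minority of infants carry no pathogenic variant in any known neonatal
diabetes gene. The question this package operationalises is whether part of
that gene-negative group has polygenic (autoimmune, type 1) diabetes, and
how large that part is. Individual-level certainty is impossible — about 5%
of genuinely monogenic individuals carry a high polygenic risk score simply
because common risk alleles are common — so the analysis works at the
cohort level: it measures the *excess* of high-risk-score individuals over
what chance alone would produce, and corroborates it with autoantibody,
C-peptide and birthweight phenotypes.

## The genetic risk score

For individual $j$ with effect-allele dosages $d_{ij} \in \{0,1,2\}$ at $m$
single risk SNPs with per-allele odds ratios $\mathrm{OR}_i$:

$$\mathrm{GRS}_j \;=\; \frac{\sum_{i \in \text{observed}} d_{ij}\,
\log_{10}\mathrm{OR}_i}{2\,m_j},$$

with $m_j$ the number of non-missing SNPs for $j$. Dividing by the allele
count makes the score a per-allele mean, so it is comparable across
individuals with different missingness patterns; that is the default
`reduce-denominator` policy of `compute_grs()`. The alternative
`drop-individual` policy removes individuals above a missingness budget
instead, for analyses that prefer a fixed denominator. An individual with
no observed SNPs has no defined score and is an error, never a zero.

The SNP set and odds ratios are *data*, supplied as a TSV
(`read_weight_table()`), because published score tables are revised,
licensed and assay-dependent. The packaged `synthetic_weights()` table has
the right *shape* for a type 1 diabetes score — one large HLA-class-like
effect (OR 6.8), a couple of intermediate effects, and a tail of small ones
— but its values are synthetic. Scores computed from it are on their own
scale, not the published 0.280-threshold scale.

Additive scoring is used throughout. Some published type 1 diabetes scores
add an HLA DR/DQ genotype-interaction term; nothing in this pipeline
precludes representing such a term as an extra pseudo-SNP row in the weight
table (dosage supplied directly in the dosage matrix), but no interaction
machinery is built in, and the shipped examples are purely additive.

VCF ingestion (`dosages_from_vcf()`) reads GT only and matches sites by ID.
Orientation is resolved by comparing REF/ALT with the weight table's
alleles; under the `flip-unambiguous` policy a strand flip is accepted only
when complementing resolves the mismatch *and* the SNP is not A/T or C/G —
strand-ambiguous SNPs are never silently flipped, they are errors.
Multiallelic sites at scored SNPs are errors, not filtered.

## Threshold, excess, and the polygenic fraction

The classification threshold is a quantile of a control (no type 1
diabetes) score distribution, by default the 95th centile. Quantiles
everywhere in the package — threshold calibration, medians, IQRs — use the
linear-interpolation convention between order statistics (R's type 7),
fixed and pinned by tests, because mixing conventions moves thresholds by
enough to change counts at cohort sizes in the hundreds. Classification is
strict: a score exactly at the threshold is *low*.

With $k$ of $n$ tested individuals above the threshold and null exceedance
probability $\alpha$ (0.05 at the 95th centile):

* expected count $= \alpha n$, reported both raw and rounded
  (half-to-even) to mirror how such counts are quoted;
* excess $= k - \mathrm{round}(\alpha n)$, floored at 0 with a deficit
  flag if negative (an unrounded version is also emitted);
* the excess divided by the *full* referral cohort size is the headline
  polygenic fraction;
* significance is the exact binomial upper tail
  $P(X \ge k),\, X \sim \mathrm{Bin}(n, \alpha)$, summed in log space so
  that tails around $10^{-38}$ neither underflow nor round to 0.

The estimator is a lower bound by construction. If the true polygenic
fraction of the tested set is $\pi$ and the polygenic class exceeds the
threshold with sensitivity $s = P(\mathrm{GRS} > t \mid \text{polygenic})$,
then the expected exceedance fraction is $\pi s + (1-\pi)\alpha$ and the
expected excess fraction over the tested set is $\pi(s-\alpha) \le \pi$.
The acceptance suite verifies exactly this identity against the generator,
with $s$ and $\alpha$ computed analytically (below), and verifies that the
estimate never exceeds $\pi$.

A Wilson score interval for $k/n$, mapped to the excess-fraction scale and
floored at 0, is provided (`excess_confidence_interval()`) as an
uncertainty companion the cohort-level estimate would otherwise lack.

## Biomarker rules

* **Autoantibody positivity** is strict exceedance of a cut-off defined as
  the 99th percentile of healthy controls. Strictness keeps the control
  false-positive rate at or below 1% per analyte; the generator-based test
  confirms the ~1% rate empirically.
* **The panel** is GADA, IA2A, ZnT8A. IAA is summarised separately and
  never enters "any-positive", because in insulin-treated infants
  antibodies to exogenous insulin are indistinguishable from
  autoantibodies; IAA is instead stratified by insulin-treatment duration
  at a 13-week boundary (≈3 months, inclusive on the short side), where
  short-duration positivity is still informative about endogenous
  autoimmunity.
* **Denominators** follow observed measurements: an individual measured for
  a subset of analytes counts toward those analytes and toward the
  any-positive denominator. Every reported proportion carries its
  numerator and denominator (`proportion_report()`, percentages rounded
  half-away-from-zero).
* **C-peptide** below the assay limit of detection (3 pmol/l) is coded
  2.9 pmol/l, including `"<3"` tokens as exported by laboratories; the
  coding is idempotent and applied before any median/IQR. Summaries are
  stratified at 12 months of diabetes duration, and the undetectable
  fraction is the share of coded-2.9 values.

## Birthweight

Z-scores standardise birthweight by the mean and SD for sex and gestational
age from a growth-reference table. The reference is a required input: the
package ships a synthetic reference (clearly labelled, `synthetic_` file
prefix) rather than reproducing any published table, which keeps tests
self-contained and sidesteps licensing and versioning of reference ranges.
Mean and SD are interpolated linearly between tabulated integer weeks; the
mean/SD parameterisation (not LMS skew-adjusted curves) is used; gestational
ages outside the table are errors, never extrapolated. The z-vs-age
regression is ordinary least squares via `lm`, exposed with slope, $r^2$,
and the two-sided slope t-test on $n-2$ df; a constant response is reported
as $r^2 = 0$ with no p-value.

## Comparison statistics

Fisher's exact test is the probability-mass two-sided version: the sum over
the hypergeometric support (margins fixed) of all table probabilities not
exceeding the observed one, with a relative tolerance of $10^{-7}$
absorbing floating-point ties, evaluated in log space. It is pinned against
an independent enumeration oracle on every 2×2 table with total ≤ 30 and
against `stats::fisher.test`. Mann–Whitney U uses midranks; the p-value is
exact (null U distribution) when $nm \le 400$ with no ties, otherwise a
tie-corrected, continuity-corrected normal approximation; exact mode
refuses ties with a message rather than silently approximating.
Kruskal–Wallis uses the tie-corrected H with a $\chi^2_{k-1}$ p-value.
Results are flagged at p < 0.05 and **no multiple-testing correction is
applied** — the report mirrors single-comparison conventions, so readers
should treat borderline p-values across the report's several tests
accordingly.

## The synthetic cohort generator

`simulate_cohort()` emulates the study's data-generating process, not any
real dataset:

* **Genotypes.** Controls: dosage $\sim \mathrm{Bin}(2, f_i)$ per SNP
  (Hardy–Weinberg, linkage equilibrium). Polygenic cases: the logistic
  tilt $P(g \mid \text{case}) \propto \binom{2}{g} f_i^g (1-f_i)^{2-g}
  \mathrm{OR}_i^g$, which reproduces the configured per-allele odds ratios
  exactly in expectation. The cohort mixes
  $\mathrm{round}(\pi \cdot n)$ cases with $(1-\pi)n$ monogenic-like
  controls; truth labels are written to a separate file the pipeline never
  reads.
* **Defaults** mirror the study's shape and are fixed once: $m = 30$ SNPs,
  referral cohort $n = 166$, control reference panel $n = 4862$,
  $\pi = 0.33$ (the excess the printed counts imply, 55/166), optional
  genotype-free comparator groups of 164 (monogenic) and 152 (older-onset
  type 1 diabetes) phenotype rows.
* **Phenotypes.** Per-class antibody positivity probabilities follow the
  reported per-group rates (e.g. polygenic: GADA 0.27, IA2A 0.18, ZnT8A
  0.14, IAA 0.82; monogenic-like: 0.02/0.04/0.01/0.39); negative titres are
  lognormal with their 99th percentile at the cut-off (so assay-noise
  positives occur at ~1%), positive titres sit strictly above the cut-off.
  C-peptide is lognormal per class (monogenic median 64 pmol/l; polygenic
  median ≈1.2 pmol/l, mostly censored at the 3 pmol/l LOD and written as
  `"<3"`). Birthweight z is
  $\mathcal N(\mu_{0,\text{class}} + \beta\,\mathrm{age_w},\ \sigma)$ with
  $\beta = 0.05$ z/week and $\sigma = 0.77$ for the polygenic class —
  values chosen once so that uniform diagnosis ages on (0, 26] weeks give
  $r^2 \approx 0.18$ and a median z near −0.9, the reported scale of the
  birthweight effect. Ages at diagnosis are scaled-Beta on (0, 26] weeks
  per class; birthweights are back-transformed through the shipped
  synthetic growth reference so that recomputed z-scores equal the
  simulated ones.
* **Determinism.** All randomness flows from the single config seed; a
  fixed seed yields byte-identical output files.

What the generator does *not* emulate: linkage disequilibrium (real type 1
diabetes loci include correlated HLA SNPs), population stratification,
assay batch effects, sample-availability missingness (every simulated
individual has every measurement), and loss or gain of autoantibodies over
time. Passing tests on synthetic cohorts therefore demonstrate the
*machinery* — calibration, estimator identities, parameter recovery — not
the field behaviour of the score in any particular population.

## Analytic calibration by exact convolution

Because simulated SNPs are independent, the exact distribution of the score
numerator is the convolution of $m$ three-point distributions.
`grs_distribution()` computes it on an integer grid: weights are rounded to
$10^{-6}$ numerator units, so every partial sum is an exact grid multiple
and atoms merge without accumulated error (worst-case score error
$m \cdot 5\times10^{-7}/(2m) = 2.5\times10^{-7}$, negligible against atom
spacing of interest). This yields the exact control tail $\alpha$ at any
threshold and the exact case sensitivity $s$ — the analytic targets for the
parameter-recovery checks, independent of any Monte-Carlo run.

## Problem sizes and numerical choices

The test and acceptance runs use: every 2×2 table with total ≤ 30 for the
Fisher oracle; 200 random 50×30 dosage matrices (tolerance $10^{-12}$)
for the score oracle; 200 control cohorts of 1000 for null calibration;
100 cohorts of 5000 at $\pi = 0.33$ for excess-fraction recovery; 100
replicates of 48 points for slope recovery. These sizes make Monte-Carlo
standard errors small enough that 3-SE acceptance bands are meaningful
while the whole suite runs in a couple of minutes. Other numerical
decisions, collected: type 7 quantiles throughout; strict `>` at every
threshold and cut-off; round-half-to-even for expected counts,
half-away-from-zero for displayed percentages; log-space summation for
binomial tails and hypergeometric masses; no extrapolation of the growth
reference; deficits floored at zero with a flag.

## Limitations

The excess estimator is deliberately conservative: it cannot attribute
*which* individuals are polygenic, only how many at minimum. Its accuracy
depends on the null exceedance α being correct for the monogenic-like
class, which holds when monogenic risk-allele distributions match the
control population's. The threshold is estimated from a finite reference
panel, so sampling noise in the threshold propagates into counts (the
reference size is data, not a constant, and small panels trigger a
warning). Reported p-values are uncorrected for multiplicity. The shipped
weight table, growth reference and all simulated data are synthetic stand-ins;
analyses of real cohorts must supply the published score table and a real
growth reference.
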