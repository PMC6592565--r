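---
title: "Methods: PRS construction and PheWAS on a coded phenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRS construction and PheWAS on a coded phenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`prsphewas` implements a complete polygenic-risk-score (PRS) analysis chain
for related disease subtypes observed in electronic health records: it
ingests external genome-wide association results, builds PRS four ways
(curated catalog entries, the latest genome-wide-significant scan, LD
clumping with p-value thresholding, and LDpred-style point-normal
reweighting), aggregates ICD9/ICD10 diagnosis events into PheCode
case-control studies, screens each PRS against the phenome with Firth
bias-reduced logistic regression, decomposes subtype PRS into shared and
subtype-unique locus sets, evaluates discrimination and calibration on a
train/test split, and exports a static results catalog. A synthetic-data
generator reproduces the statistical structure every stage assumes, so the
whole pipeline is testable without access to individual-level biobank data.

This vignette records the modeling choices, the defaults and their
rationale, and the limits of what the synthetic experiments demonstrate.

# The synthetic cohort generator

## Genotypes and linkage disequilibrium

Genotypes are hard dosages in $\{0,1,2\}$ organized in equicorrelated LD
blocks. Each block carries one latent haplotype allele per subject per
chromosome copy; every variant in the block copies that allele with
probability $\sqrt{r}$ and otherwise draws a fresh Bernoulli with the
block's allele frequency. Two variants in a block therefore share the
latent allele with probability $r$, and their dosage correlation is exactly
the configured `within_block_r` in expectation — no tetrachoric calibration
is needed, Hardy-Weinberg structure holds by construction, and output is
byte-identical for a fixed seed. The price is that allele frequency is
constant within a block, which is irrelevant for every consumer in this
package (LD estimation, clumping, scoring, reweighting). Blocks span less
than 1 Mb and consecutive blocks sit more than 1 Mb apart, so the clumping
window separates them cleanly. We chose this copy model over thresholding a
Gaussian copula because the copula attenuates the latent correlation
through the genotype thresholds and would need a numerically inverted
calibration per allele frequency to hit the target $r^2$.

## Causal architecture and phenome

Three disease subtypes share `n_shared_causal` loci (default 6, the number
of loci the shared-genetics analysis is designed around) with identical
effects across subtypes, plus `n_unique_causal_per_subtype` loci each
(default 10). Causal variants are drawn from distinct LD blocks so the
shared/unique decomposition has a well-defined truth. Effects are
per-allele log odds ratios $\beta \sim N(0, \texttt{effect\_sd}^2)$ with
`effect_sd = 0.3` by default — large enough that a cohort of a few
thousand subjects carries unambiguous signal, and in the range of the
strongest common pigmentation-locus effects; the generator makes no claim
that real subtype architectures look like this (no external source reports
one), and the default is chosen for testability.

Disease status for subtype $s$ follows
$\mathrm{logit}\, P(Y_s = 1 \mid G) = \alpha_s + \sum_i \beta_{is} G_i$,
with $\alpha_s$ solved by `uniroot` so the realized marginal prevalence
matches the configured target (defaults 4-6%, in the range of common-cancer
prevalences in an enriched clinical cohort). An "overall" code covers
anyone with any subtype via the PheCode hierarchy. Secondary traits are
driven by the standardized shared-locus score (coefficient 0.5 per SD,
baseline prevalence 10%), giving a genetically correlated trait the shared
PRS should detect; "mediated" traits are driven by overall disease status
itself (log-OR 1.5) and carry no direct genetic effect, so their PRS
association must attenuate in the exclusion scan. Null codes are
independent coin flips with prevalences 3-10%.

Every case emits 1 + Poisson(0.5) dated diagnosis events, each randomly
assigned to an ICD9 or ICD10 alias of the trait's PheCode, with dates
uniform over a 10-year window — so both orderings of
secondary-versus-primary first dates occur and the 365-day lag rule is
exercised in both directions. Subjects carry sex, age, a two-level
genotyping-array label, and four standard-normal PCs (no confounding by
default).

## Discovery GWAS and corruption injection

Summary statistics come from an independently drawn cohort of
`discovery_n` subjects (default 20,000) on the same variant panel:
per-variant marginal logistic log odds ratios with Wald SEs, p-values,
effect-allele frequencies and N. Rows are then corrupted at configured
rates to give the QC layer something to find: strand flips (both alleles
complemented; applied only to non-ambiguous variants, where repair is
possible), allele-frequency errors (EAF moved by 0.20-0.35, comfortably
beyond the 0.15 filter), and ambiguous-mismatch rows (a strand-ambiguous
panel variant's alleles replaced by the other ambiguous pair). The
injection log ships with the table so round-trip tests can check recall
exactly.

# Summary-statistic ingestion and QC

Harmonization treats the target panel's alleles as forward-strand truth.
A reported risk allele that matches a panel allele is kept; on a
non-ambiguous variant (not A/T or C/G) a complement match is interpreted as
minus-strand reporting and corrected; an ambiguous variant whose alleles
cannot be matched is excluded, as are entries with missing risk allele,
frequency, or odds ratio, and entries without European ancestry labels.
Note that for single-allele catalog entries on a complete ACGT panel the
"matches nothing" category is geometrically unreachable (every base either
matches or complements a panel allele); it arises only for allele *pairs*
in full summary statistics, which is where the audit reports it.

The risk-allele-frequency check compares the reported frequency against
control subjects of the target cohort on the harmonized effect allele
(females only for chromosome X) and drops entries deviating by more than
0.15 in allele-frequency units — the absolute-difference reading of the
conventional 15% rule used in GWAS meta-analysis quality control,
where it separates concordant from strand-flipped entries on a
reported-versus-observed frequency plot. The RAF check runs before LD
deduplication, so frequency-discordant entries never influence which of a
correlated pair is kept.

Correlated entries ($r^2 > 0.1$ on control dosages within 1 Mb) and
duplicate identifiers are deduplicated keeping the most recent publication
date, ties broken by smaller p-value, then by genomic coordinate for
determinism. The greedy keep-order is verified against brute-force
enumeration in the tests. No p-value threshold applies to catalog entries;
the "latest GWAS" arm instead applies a strict $p < 5\times10^{-8}$ before
the same QC chain.

# Clumping, thresholding, and LDpred reweighting

LD is the signed Pearson correlation of dosage vectors, windowed at 1 Mb
and zero across chromosomes; monomorphic variants get $r = 0$ with a
warning. Clumping is single-pass greedy: take the smallest-p remaining
variant (ties by chromosome and position, so results are platform-stable —
clumping tools rarely document their tie-break),
remove neighbors with $r^2 > 0.1$ within 1 Mb, repeat; candidates require
MAF > 0.5% and $p < 5\times10^{-4}$, all inequalities strict. Six nested
subsets at $5\times10^{-9}\ldots5\times10^{-4}$ become six PRS models with
summary-statistic log odds ratios as weights.

The LDpred arm reweights *all* filtered variants (SNPs only, present in
summary statistics, LD reference and target panel, MAF > 1%,
non-ambiguous) under a point-normal prior with six causal fractions
(100% down to 0.001%) and an LD radius of 2,800 SNPs handled as a sliding
band, matching the "radius" semantics rather than disjoint chunks.
Marginal effects are standardized internally as $z/\sqrt{N}$: for a
unit-variance quantitative trait this equals $\hat\beta\,\mathrm{sd}(G)$,
and unlike the naive $\hat\beta\sqrt{2pq}$ scaling it gives sampling noise
variance exactly $1/N$ for binary-trait log odds ratios too (whose noise
variance is $1/(N \bar\pi(1-\bar\pi) 2pq)$ on the per-allele scale). Output
weights are back-transformed per allele as
$w \cdot \mathrm{SE} \cdot \sqrt{N}$.

The infinitesimal model has the closed form
$w = (M/(Nh^2)\,I + D)^{-1}\hat\beta$ over the banded LD matrix $D$, which
reduces to the scalar shrinkage $Nh^2/(Nh^2+M)$ under identity LD — the
oracle the Gibbs sampler is tested against at causal fraction 1. The
sampler residualizes each variant against its in-radius neighbors,
computes the posterior inclusion probability under the point-normal prior,
samples the effect, and averages post-burn-in sweeps (defaults 100
burn-in / 1,000 kept, chosen so a 500-variant problem runs in seconds;
chain settings are an implementation choice of this package). The inner
sweep is compiled (Rcpp) and draws from R's RNG, so results are
bit-reproducible under a seed. A running sum of squared sampled effects
above $1.5 h^2$ aborts with a diagnostic; this fires when the prior
heritability is materially smaller than the marginal signal, which is the
main practical failure mode of mis-specified $N$ or $h^2$. When `h2 =
"auto"`, an aggregate moment estimator
$\hat h^2 = M(\overline{\chi^2}-1)/(N\bar\ell)$ with windowed LD scores
$\ell$ is used, clamped to $[0.01, 0.99]$ with a warning.

Monte-Carlo agreement between the fraction-1 chain and the closed form is
quantified with the between-chain standard deviation over 5 seeds, used
directly as the per-variant Monte-Carlo SE of a chain (not divided by
$\sqrt{5}$): a per-variant $3\,\mathrm{SD}/\sqrt{5}$ band is a $t_4$
statistic that a perfect sampler would violate for ~4% of 500 variants by
chance, so the conservative band is the one that tests the sampler rather
than the noise of its own error bar. A floor of $5\times10^{-4}$ on the SE
guards coordinates whose chains agree to numerical precision.

# Scoring, loci, and the shared/unique decomposition

A PRS model is a list of (variant, effect allele, weight); scoring is
$\mathrm{PRS}_j = \sum_i \beta_i G_{ij}$ with the dosage flipped to $2-d$
when the model's effect allele is the matrix's other allele, and a hard
error when it matches neither. Model variants missing from the matrix are
skipped and the scored fraction of $\sum_i|\beta_i|$ is reported as
coverage (a strict mode refuses instead). Standardization to mean 0, SD 1
(sample SD, $n-1$) is recomputed on each study's analytical set, never
globally.

Risk SNPs within 1 Mb merge into loci by single-linkage chaining, so a
locus can extend beyond 1 Mb through intermediate SNPs. The shared PRS
takes one representative SNP per locus present in all three subtype
models — the member with the smallest source p-value, ties by
coordinate — oriented to the risk-increasing allele with weight 1 (an
unweighted risk-allele count over shared loci;
one-representative-per-locus is the reading consistent with counting
loci rather than SNPs). Unique models keep a subtype's own SNPs,
with their original weights, in loci no other model touches; loci shared
by exactly two models belong to neither decomposition.

# Phenome construction and matching

ICD events map to PheCodes through a two-vocabulary table; events
propagate to all hierarchical ancestors ("172.11" implies "172.1" and
"172"), and a subject's first date per code is the earliest mapping event.
Controls for a code exclude carriers of the code itself and of its
ancestors and descendants (the standard PheWAS exclusion range,
configurable off). Studies require strictly more than `min_cases` cases
(default 50).

Matching draws, per case in ascending subject-ID order, up to 10 controls
without replacement from pool members equal on sex and genotyping array
and within 0.25 SD on *each* standardized matching covariate (age and
PC1-4), nearest first by Mahalanobis distance; cases with no eligible
control are dropped and logged. The per-covariate caliper is the
interpretable, exactly testable reading of a "0.25 SD caliper"; its
consequence is worth stating plainly: with five diffuse covariates the
probability that a random control clears all five calipers is about
$5\times10^{-5}$, so population-style pools produce achieved ratios near
zero, and ratios near 10 require pools genuinely rich near the cases
(near-duplicate covariates). The matching contract is therefore
demonstrated on such rich pools, while the replicate-heavy phenome-wide
experiments below run in unmatched mode — the same sensitivity
configuration the package exposes for real analyses — where the synthetic covariates are independent of case
status by construction and matching would only subtract sample. With a
scalar propensity-type caliper, achieved ratios near 9-10 become
reachable on diffuse pools, but that is a different algorithm than the
per-covariate one implemented here.

# Association and evaluation

The Firth fit maximizes the Jeffreys-penalized likelihood
$\ell(\beta) + \tfrac12 \log\det X^TWX$ by modified-score Newton steps
with step-halving, converging on a vanishing step or on a stationary
penalized likelihood with an already-tiny step (near-optimal two-cycles at
machine precision otherwise keep the raw step criterion from firing).
Estimates are finite under complete separation; on a saturated 2×2 design
the slope equals the half-cell-corrected log odds ratio
$\ln\frac{(a+\frac12)(d+\frac12)}{(b+\frac12)(c+\frac12)}$, which the
tests verify on the exhaustive grid of cell counts 1-20 (run with step
tolerance $10^{-6}$, giving slope accuracy around $10^{-7}$). Wald
p-values are the default; penalized-likelihood-ratio p-values (profiling
with the full-design penalty, the convention of the standard R Firth
implementation) are available by flag.

Each PheWAS study fits case status on the study-standardized PRS plus age,
sex, array and PC1-4, dropping degenerate covariate columns (e.g. sex in a
single-sex phenotype) with a log message; covariates enter unstandardized
since matching, where used, already balances them. Significance is
controlled phenome-wide by Bonferroni over the studies actually tested.
The exclusion scan removes carriers of the primary code and its hierarchy
family from every study before refitting. The lagged secondary-diagnosis
model codes its predictor 1 for subjects whose secondary diagnosis
precedes the primary by at least 365 days or who never receive the
primary, 0 for subjects without the secondary code, and excludes
subjects whose primary follows the secondary too closely (or precedes it).

Evaluation fits an unpenalized logistic model of status on the PRS alone
(Firth as fallback under separation) on a case-stratified random third of the
study and computes, on the remaining two thirds: Mann-Whitney AUC with the
DeLong 95% CI (via pROC, cross-checked against pair counting),
Hosmer-Lemeshow $\chi^2$ over deciles of predicted risk with $g-2$ degrees
of freedom (empty or degenerate deciles merge with a message; the $g-2$
convention presumes the two logistic parameters were estimated on the
data, which is how the calibration null is simulated), the Brier score,
and Nagelkerke's pseudo-$R^2$.

# Problem sizes and what the experiments show

The test-suite experiments use cohorts of 1,200-10,000 subjects, 20-500
variants, and 10-200 replicates; the phenome-wide specificity and type-I
experiments use the generator's default cohort size (5,000) with 100 null
codes, and the Gibbs/closed-form comparison uses 500 variants at GWAS
N = 10,000 with 1,000 kept sweeps. These sizes are the package's chosen
desk-scale study conditions. What passing shows: the algorithmic cores
equal their closed-form or brute-force oracles; the scan controls size on
truly null codes and ranks each subtype's own study first among subtype
studies when given that subtype's true-weight PRS; the shared PRS detects
a shared-score-driven secondary trait at phenome-wide significance; QC
repairs exactly the corruptions injected. What passing does not show:
performance on real imputed genotypes (dosage uncertainty, realistic LD
decay, relatedness, population structure and ancestry confounding are all
absent), calibration of the aggregate $h^2$ estimator on traits with
LD-architecture coupling, or that any real cohort's odds ratios
and AUCs are reproduced — those depend on data this package deliberately
does not require.

# Known limitations

* The generator's LD is blockwise-equicorrelated with block-constant
  allele frequency; there is no LD decay within blocks and no cross-block
  LD.
* Ambiguous-variant handling discards rather than attempts frequency-based
  strand inference — the conservative convention — losing ~1/3 of
  ambiguous-SNP information in the synthetic panel.
* The per-covariate matching caliper makes diffuse-pool matching
  infeasible by design (discussed above).
* `estimate_h2_aggregate` is a moment estimator assuming effects
  independent of LD; it is provided so an "auto" mode exists, and fixed
  $h^2$ is accepted everywhere for controlled experiments.
* The catalog renderer emits static SVG and JSON only; interactive
  regional plots are out of scope.
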