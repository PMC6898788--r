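---
title: "Methods: integrative modeling of intrinsic resistance to anti-PD1 blockade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative modeling of intrinsic resistance to anti-PD1 blockade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbResist)
```

## Scope and design

`icbResist` implements an end-to-end analysis for discovering and modeling
predictors of intrinsic resistance to anti-PD1 immune-checkpoint blockade
(ICB) in metastatic melanoma. The unit of analysis is a *cohort bundle*: a
per-patient clinical table (best RECIST response, prior-ipilimumab status,
LDH, lymph-node metastasis, survival), a somatic mutation table with cancer
cell fractions (CCF), allelic copy-number segments, sample-level genomics
(purity, ploidy, coverage histogram, callable bases) and, optionally, a
gene x sample TPM matrix with biotype annotation. The package consumes the
*outputs* of upstream variant-calling and purity/ploidy inference; it does
not realign reads, call variants, or infer purity itself.

Two response contrasts are used throughout: responders (CR/PR) versus
progressors (PD), for feature discovery; and PD versus non-PD (CR, PR, SD,
MR), for predictive modeling — the latter better reflects the clinical
question of identifying intrinsic resistance among all possible outcomes.

## Detection-power quality control

Low-purity, low-coverage tumors can masquerade as mutation-poor. The QC
stage estimates, per sample, the power to detect a *clonal heterozygous*
mutation and excludes underpowered samples:

1. draw a locus depth $N$ from the sample's empirical coverage histogram;
2. draw tumor-derived reads $T \sim \mathrm{Bin}(N, \text{purity})$;
3. draw mutant reads $M \sim \mathrm{Bin}(T, 1/2)$ (heterozygous, no
   copy-number alteration);
4. score detection with the log10 odds of the mutant model at
   $\hat f = M/N$ against the no-mutation model, with per-read likelihoods
   $P(\text{alt}\mid f) = f(1-e) + (1-f)e/3$ and
   $P(\text{ref}\mid f) = f e/3 + (1-f)(1-e)$; a mutation is detected when
   the LOD reaches 6.3, the conventional somatic-caller threshold.

Power is the detected fraction over `n_sim = 1000` simulated mutations.
Parameters: `error_rate = 0.001` (Q30; the simulation draws read counts,
not per-base qualities, so a single fixed error rate is used) and
`min_power = 0.80`. The exclusion threshold is a conventional power level,
exposed in `power_config()` because no canonical value exists for it. The
test suite checks the Monte-Carlo estimate against exact enumeration of
$(T, M)$ outcomes for point-mass coverage distributions and verifies
monotonicity in purity and coverage.

## Whole-exome scalar features

* **TMB**: count of nonsynonymous mutations; `log_tmb` is
  $\log_{10}(\text{count} + 1)$. The log base is a convention choice
  (burden is conventionally plotted in log10) and the pseudocount keeps
  zero-mutation tumors finite. Mutations per megabase divides the count by
  callable megabases.
* **Heterogeneity**: the fraction of mutations with CCF below 0.8.
  CCF $\ge 0.8$ defines clonal — a deliberately conservative,
  high-specificity rule. Mutations with missing CCF are excluded from both
  numerator and denominator (the alternative — counting them subclonal —
  would conflate missingness with biology).
* **Aneuploidy fraction**: length-weighted share of the profiled genome in
  segments flagged as allelic amplification or deletion. Copy-neutral LOH
  counts toward the denominator only, since the definition is specifically
  about allelic amplification/deletion.
* Purity and ploidy are consumed as provided (they come from upstream
  purity/ploidy inference, which is out of scope).

Gene-level event calls (e.g. B2M LOH, biallelic CDKN2A) are consumed as
boolean inputs where needed; their calling criteria live upstream.

## Transcriptome preprocessing and enrichment

snoRNA genes are removed before analysis (in degraded FFPE RNA they can
dominate the library) and each sample is renormalized to a transcriptome
sum of $10^6$ (TPM closure). Genes must have TPM > 0 in at least 25% of
samples (inclusive) to be analyzed. External FPKM cohorts are converted by
per-sample closure, which is invariant to any per-sample rescaling.

**ssGSEA.** Per sample, genes are ranked by expression (average ranks for
ties; ordering ties broken deterministically by gene name), ranks
normalized to $(0, 1]$, and the score is the sum over list positions of
the difference between the weighted in-set empirical CDF (weights
$\text{rank}^{0.25}$) and the unweighted out-of-set CDF. The exponent 0.25
is the published single-sample default; the score depends on expression
only through ranks, hence is invariant to monotone transforms — the
property that makes it robust across normalization pipelines.

**Cohort GSEA.** Genes are ranked by the signal-to-noise ratio (difference
of group means over the sum of group SDs, zero-guarded for constant
genes); the enrichment score is the signed maximum deviation of the
weighted running sum (weight exponent 1). On an exact magnitude tie
between the positive and negative extreme, the negative extreme is
returned (the reference implementation's convention; ties are detected
with a 1e-10 tolerance because the two extremes are accumulated along
different floating-point paths). The null is **gene-set permutation**:
random same-size gene sets drawn from the ranked list — not phenotype
permutation — because sample sizes per subgroup here are small. NES
divides ES by the mean same-sign null ES; FDR q follows the standard
pooled-NES procedure.

**Gene families.** Per-gene two-sided Mann-Whitney-Wilcoxon tests are
reported unadjusted (discovery-oriented; a Benjamini-Hochberg flag exists
downstream of `gene_wise_mww()` via `p.adjust`). A family of genes (e.g.
the 13 MHC-II HLA genes) is tested for directional concordance with a
two-sided exact binomial test on the count of positive median differences,
zeros dropped: 13/13 concordant gives $2 \cdot 0.5^{13} = 0.000244$.

## Association and survival statistics

2x2 association uses the sample cross-product odds ratio and the two-sided
Fisher exact p (point-probability definition: sum of all tables as or less
probable). The *adjusted* OR adds one to both exposure-positive cells — a
conservative repair for empty cells. Confidence intervals are Woolf
(normal on the log OR); this combination reproduces every published
interval in the motivating analysis to printed precision. Median splits
label strictly-above-median as high (ties at the median go low; the
convention is configurable in spirit — it is a documented tie rule, not a
tuned choice). Interaction tests expand stratified 2x2 counts to
per-subject rows and fit the saturated logistic model; the exponentiated
interaction coefficient then equals the cross-ratio of stratum odds
ratios, which the tests verify algebraically. Survival uses Kaplan-Meier
product-limit curves and log-rank tests (via the `survival` package), with
the median defined as the earliest time survival drops to 0.5 or below
("unreached" medians are reported missing).

## Predictive modeling

Models are maximum-likelihood logistic regressions of PD versus non-PD,
fitted separately in the ipilimumab-experienced and ipilimumab-naive
subgroups. Forward selection adds, at each step, the candidate whose Wald
p-value upon addition is below 0.05 and which maximizes the combined
model's in-sample AUC, stopping when no candidate passes. The
non-algorithmic "manual review" of candidates in the original workflow is
realized as an optional ordered whitelist so runs are reproducible. The
default candidate pool: log TMB, purity, ploidy, heterogeneity, aneuploidy
fraction, MHC-I and MHC-II ssGSEA scores, LDH dichotomized at 247 U/l (the
anchored cohort median), and the lymph-node-metastasis flag.

Generalization is estimated by stratified k-fold cross-validation with
*fixed* features (feature selection is deliberately not nested — matching
the original design, where selection included manual review; the reported
CV AUC therefore estimates coefficient stability, not selection
stability). Statistical support is summarized by AIC/BIC ledgers,
likelihood-ratio tests for added features (the TMB-addition check), and a
label-permutation empiric p-value with the add-one correction
$(1+b)/(1+B)$, which cannot return zero. Phenotype (not predictor)
permutation preserves the inter-predictor correlation structure. Survival
stratification splits fitted probabilities at their median and compares
halves by log-rank.

## Subgroup-specific enrichment permutation test

To ask whether a pathway's enrichment is specific to one subgroup, the
subgroup labels are permuted *within response classes*, preserving exactly
both subgroup sizes and per-subgroup responder/progressor counts, and the
per-subgroup GSEA is rerun on each permutation. A permutation is at least
as extreme as the observation when both (i) its difference in log q
between subgroups reaches the observed difference and (ii) its q in the
subgroup of interest is at most the observed q ("equal to or more extreme"
is read as smaller-or-equal, per FDR-q semantics). q-values are floored at
the GSEA permutation resolution before taking logs. The default runtime
profile is 100 outer x 200 inner permutations — a scaled-down profile with
full-scale flags (`n_perm`, `n_perm_gsea`), since the full-resolution
version of this nested resampling is cluster-scale by construction.

## The synthetic cohort generator

`simulate_cohort()` exists so that every downstream stage is testable
without access to the controlled-access study data. Its defaults *are* the
study conditions: subtype frequencies 0.729/0.132/0.069/0.07
(cutaneous/occult/acral/mucosal), prior-ipilimumab probability 0.417,
subtype-conditional response distributions giving a ~38% overall response
rate and ~45% PD, nonsynonymous burden lognormal with subtype-group
medians anchored at 297.5 (cutaneous/occult) versus 58 (acral/mucosal) and
dispersions chosen to approximate the published interquartile range,
purity Beta(2.2, 1.2) (median 0.68, IQR ~0.48-0.84), ploidy a
diploid/genome-doubled normal mixture with 38% doubled (median ~2.15),
heterogeneity Beta(4, 18) (median ~0.17), LDH lognormal with median 247
U/l shifted upward by 0.25 log units in progressors, and exponential
survival with response-dependent rates under administrative censoring.
Where the motivating analysis prints only medians or IQRs, the remaining
distribution parameters were chosen once to be realistic and are not
revisited.

Planted structure follows the analysis's own hypotheses: burden depends on
subtype only (so the TMB-by-subtype confounding is reproducible); CCFs mix
clonal U(0.8, 1) and subclonal U(0.05, 0.8) components so the expected
subclonal fraction equals the patient's heterogeneity parameter; and the
13 MHC-II HLA gene TPMs are multiplied by `2^mhc2_effect_size` only in
ipilimumab-experienced responders. No effect size in natural units is
published for the MHC-II difference, so the default log2 shift of 1 is an
explicit free parameter of the generator. Expression background is
lognormal with per-gene baselines and a logistic-in-baseline dropout,
column-rescaled to TPM closure — the simplest model satisfying closure.
All draws come from a single seeded stream in a fixed order, so bundles
are byte-reproducible given `(config, seed)`.

What the generator does *not* emulate: linkage and trinucleotide context,
mutational signatures, gene-gene expression correlation, realistic
immune-infiltrate covariation, or informative censoring. Passing
recovery tests on these synthetic cohorts therefore demonstrates that the
statistical machinery detects the planted structure at realistic sample
sizes — not that the biological effects themselves replicate in real
cohorts.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero alt reads give LOD 0;
constant genes get rank-sum p 1; empty CCF vectors yield missing
heterogeneity with a warning; complete separation in logistic fits is
flagged rather than fatal; all-censored groups report unreached medians;
leave-one-out cross-validation falls back to a pooled holdout AUC when
single-subject folds cannot support per-fold AUCs.

The shipped tests run the recovery experiments at reduced but honest
sizes, chosen as the package's own verification scale: planted-effect
model selection on 50 cohorts of 150 patients with 2000 genes;
permutation-null calibration on 30 cohorts; subgroup-enrichment recovery
on 20 cohorts of 60 expression samples at the 100 x 200 scaled permutation
profile; power enumeration up to depth 100. The acceptance script
recomputes the deterministic published statistics (for example the
stratified interaction odds ratio) from their printed counts at run time.

## Known limitations

The enrichment null uses gene-set permutation only; phenotype-permutation
GSEA is out of scope. Cox models are not provided (the motivating analysis
used only log-rank comparisons). Immune deconvolution, neoantigen
prediction, HLA typing and mutational-signature decomposition are consumed
as upstream scalars where needed, never recomputed. Gene symbols are
matched case-sensitively without alias resolution.
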