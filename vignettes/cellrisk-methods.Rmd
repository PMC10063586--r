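---
title: "Models and methods behind cellrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cellrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cellrisk` connects GWAS summary statistics to candidate cell types and
genes in three stages — regulatory-annotation enrichment, chromatin-
interaction-aware gene mapping, and cell-specific polygenic scoring —
and ships a synthetic-data generator with fully recorded planted truth
so that each stage can be validated end to end.  This vignette explains
the underlying models, the parameters that matter, the numerical
choices, and what the synthetic validation does and does not establish
about real data.

## The synthetic genome and its planted truth

The generator is deliberately simple where simplicity keeps oracles
tractable, and explicit about everything it plants.

**LD model.**  Variants live in disjoint blocks; correlation is zero
across blocks and follows either an exchangeable or an AR-1
("decaying") profile within a block, parameterised by the within-block
r².  Each variant carries a random sign, so signed correlations take
both signs while r² follows the profile; all downstream logic (pruning,
clumping, proxies, the gene test) consumes r² only.  Block-diagonal LD
makes the greedy pruning oracle and the gene-test null exactly
computable, and mirrors the locus-level structure that pruning and
clumping semantics rely on.  It does not reproduce coalescent
haplotype structure, long-range LD, or allele-frequency-dependent LD;
no sex chromosomes or imputation error are simulated.

**Summary statistics.**  Z-scores are drawn per block from a
multivariate normal with the signed LD as correlation and the
LD-propagated non-centrality as mean: for variant *i*,
`mean_i = sum_j r_ij * beta_j * sqrt(2 maf_j (1 - maf_j) n_eff)`.  A
ridge of 1e-6 is added to every block diagonal before the Cholesky
factorisation — applied unconditionally so near-singular blocks never
fail silently, at a bias far below sampling noise.  p-values are
two-sided normal tails, floored at the smallest positive double so the
p ∈ (0, 1] contract holds even for extreme signals.

**Genotypes and liability.**  Cohort dosages come from a Gaussian
copula: a latent normal vector with the block correlation is
thresholded at the Hardy–Weinberg cut points for each variant's allele
frequency.  This controls MAF exactly and r² approximately (thresholding
attenuates the genotype correlation slightly below the latent r; the
test suite asserts the sign and a 0.6–1.0 attenuation band rather than
equality).  Disease liability is the weighted standardized-dosage sum
plus `N(0, 1 - h2)` noise; an individual is a case iff liability
exceeds `qnorm(1 - K)`.  Case–control ascertainment simulates candidate
chunks until both strata fill and errors out, with a suggestion, when
the prevalence makes the requested counts unreachable within the
candidate cap.  The default prevalence recorded in `synthetic_truth()`
is K = 0.00127, the multiple-sclerosis prevalence used for
liability-scale corrections; pipeline demonstrations use a larger K so
that ascertainment stays cheap, and record the K they used.

**Planted annotations and loops.**  Peak sets either follow a
configurable sharing profile (each consensus peak drawn into a known
number of cell types — the truth table records the count), or are
variant-anchored with a planted logistic model: for the enriched cell
type, `P(covered) = plogis(qlogis(base_rate) + log_or * 1{p < T})`, so
the planted log-odds of overlap for significant variants is exactly
`log_or`.  Peak widths stay below the variant spacing so anchored peaks
never merge.  Loops connect an isoform promoter anchor to a distal
anchor centred on a variant; by default the distal anchor avoids every
exon and promoter, as enhancer anchors typically do — this also keeps
planted causal signal from leaking into non-causal genes through a
randomly placed anchor, which matters for interpreting recovery tests.

## Enrichment with matched confounders

Greedy pruning visits variants in ascending p order and keeps a variant
iff no already-kept variant within the window has r² above threshold
(defaults r² 0.01 / 500 kb; clumping for scores uses 0.1 / 250 kb).
Ascending-p order keeps the most significant representative of each
locus, which is the intent of threshold-based enrichment; the output is
maximal under the rule, and the suite checks it against an independent
quadratic-time greedy oracle.

The enrichment model is a logistic regression of `y = 1{p < T}` on the
annotation indicator plus dummy-coded quantile bins of three matched
confounders: MAF, distance to the nearest isoform TSS, and the number
of LD proxies at r² > 0.8.  Five bins per feature balance matching
against stability and are configurable; features with fewer distinct
values collapse with a warning.  Annotation overlap uses half-open
interval tests and, by default, also counts a variant as annotated when
any of its r² > 0.8 proxies overlaps — both modes are exposed because
published pipelines are ambiguous on this point.

Numerical edge cases are explicit: a cell with zero (or all)
significant variants or a constant annotation column is flagged
`untestable` and kept in the grid (grid completeness matters for
plotting and for honest reporting); separation — judged on the
annotation coefficient only, since nuisance bin dummies routinely
diverge when a significant stratum is empty without invalidating the
annotation Wald estimate — falls back to a Firth-penalized fit, flagged
`penalized`.  Multiple testing uses Bonferroni at the effective number
of independent annotations, defined as the count of eigenvalues of the
annotation correlation matrix needed to reach 99.5% of total variance
(duplicated annotations therefore cost nothing); BH over the testable
grid is available as an alternative.

One estimand subtlety is worth recording.  The regression reports a
*conditional* (covariate-adjusted) odds ratio, and odds ratios are not
collapsible: when the planted causal variants sit inside exons, TSS
distance strongly predicts significance and the conditional OR exceeds
the planted marginal log-odds.  The recovery checks therefore scatter
causal signal uniformly, making the marginal and conditional estimands
coincide; with exonic planting the direction of the shift is expected,
not a defect.

## Gene mapping and the LD-aware gene test

Variants map to genes by location — any exon of any isoform, or the
strand-aware 2-kb window strictly upstream of any isoform TSS (for `+`
isoforms positions `[tss - 2000, tss)`; for `-` isoforms upstream means
increasing coordinates, `(tss, tss + 2000]`) — and by interaction: for
each cis loop, if one anchor overlaps a gene's exon or promoter, every
variant in the partner anchor is assigned to that gene, symmetrically.
The variant-side anchor needs no exon/promoter overlap of its own.
Location- and interaction-based assignments merge as a set union with
route tags preserved.  All overlap logic is 0-based half-open
throughout the package; GTF input is converted on ingest, which removes
the usual off-by-one class entirely (the boundary tests pin 2000 in /
2001 out, end coordinate excluded).

The gene statistic is the SNP-wise mean: `S_g = sum_i z_i^2` with
`z_i = qnorm(1 - p_i / 2)`.  Under the null and joint normality, S_g is
a weighted sum of independent 1-df chi-squares whose weights are the
eigenvalues of the gene's LD correlation matrix (ridge 1e-6).  The
default evaluates this null exactly by Imhof numerical integration.  A
two-moment scaled chi-square (Brown's method, matching `E[S] = k` and
`Var[S] = 2k + 4 sum_{i<j} r_ij^2`) is available as `method = "brown"`
and serves two roles in the default path: the deep tail (Brown p below
1e-4) is evaluated by the Brown tail, because the oscillatory Imhof
integral becomes unreliable exactly where the two-moment tail is
accurate and monotone; and any failed integral falls back to it.  The
choice is driven by calibration: under strong exchangeable within-block
LD the two-moment approximation is systematically miscalibrated at the
2000-gene scale, while the exact null passes KS uniformity comfortably
— the test suite checks both the no-LD and the r² = 0.5 cases.
Both reductions hold exactly: a one-SNP gene returns the SNP's own
p-value, and independent SNPs return the chi-square(k) tail.

FDR control is BH over all tested genes, per cell type (a pooled
universe across cell types is a flag away; per-cell-type matches how
per-cell-type risk sets are compared downstream), and the risk set is
restricted to protein-coding genes at q < 0.05.  Set comparison reports
the intersection of all cell types, each cell type's unique set
(set minus the union of the others), and pairwise overlaps.

## Cell-specific scores

QC applies the conventional biobank thresholds — INFO < 0.6, MAF < 1%,
missingness > 10%, Hardy–Weinberg p < 1e-6 (1-df chi-square on rounded
dosage genotype counts), kinship > 0.0844 with the lower-completeness
member of each pair removed (ties by id order) — and reports per-rule
counts.  Scoring universes come from the gene-SNP annotation: `all`
variants annotated in a cell type, `unique` after subtracting every
other cell type's set (unique universes of different cell types are
disjoint by construction, asserted exactly), or one `combined` score
over the union — a single score rather than a sum of per-cell-type
scores, which is the natural reading of a "combined" model and keeps
the evaluation machinery identical; a per-cell-type sum can be built
from the parts if wanted.

Scores are weighted effect-allele dosage sums.  Allele handling is
strict: a panel that counts the other allele is reconciled by
reflecting dosages (2 − d), anything irreconcilable is an error listing
the variants, and missing dosages are mean-imputed to 2·MAF.  Threshold
optimization walks the standard 13-point p-threshold grid, scores the
validation cohort at each threshold, and maximises the incremental
Nagelkerke R² over the covariates-only model; ties break to the
smaller (sparser) threshold.

**Evaluation.**  The observed R² is the incremental Nagelkerke R².
The liability-scale R² uses the Lee transformation for ascertained
case–control samples, `R2_liab = C R2 / (1 + C theta R2)` with
`C = K^2 (1 - K)^2 / (z^2 P (1 - P))` and the ascertainment term
`theta = a (a - t)`, `a = (z / K)(P - K)/(1 - K)`, applied to the
observed-scale *linear* incremental R² — the scale on which the
transformation is derived.  This combination was selected by a
latent-liability simulation oracle (a score explaining a known fraction
of liability variance under 50/50 ascertainment at K = 0.01): the
constant alone slightly under-recovers, applying it to Nagelkerke
over-recovers, and the full transformation on the linear scale lands on
the planted value; the oracle is part of the test suite, so the choice
is continuously re-validated.  AUC is the exact Mann–Whitney statistic
of the score alone (cross-checked against an independent ROC
implementation).  Stratified odds ratios cut the score into quantile
bands — bottom 5%, 15/20/20/20/15%, top 5% by default, configurable —
and regress status on the stratum factor plus covariates with the
median-containing stratum as reference; when 0.5 is itself a break the
lower stratum is the reference.  Empty strata are dropped with a
warning.  The extended MHC filter removes chr6:25–35 Mb (GRCh37,
half-open, configurable).

Phenotype associations standardize score and phenotype before fitting,
so the reported β is a standardized coefficient (the raw-scale slope is
also emitted); the incremental R² over covariates equals the squared
partial correlation scaled by `1 − R²_covariates`.  Binary outcomes use
logistic regression with the same Firth fallback under separation.
BH flags the phenotype × universe grid; Bonferroni is a flag.

## Problem sizes and what the validation shows

The test suite runs oracle comparisons on hundreds of randomized small
fixtures (tens of variants each); null calibration on a 10⁴-cell
enrichment grid (4000 pruned variants, 1000 annotations × 10
thresholds) and 2000-gene scans with and without within-block LD at
r² = 0.5; recovery of a planted log 2 enrichment on a 2·10⁴-variant
pruned set with a 100-replicate ranking check; causal-gene recovery on
a 20000-variant, 500-gene genome; liability-R² recovery at planted
0.03; and full-pipeline byte determinism.  These sizes were chosen so
the complete suite exercises every code path at meaningful statistical
resolution while staying convenient to run routinely.

Passing them shows that the implementations compute what they claim on
data whose generative model is known exactly.  It does not show that
the block-LD model captures real haplotype structure, that planted
logistic peak coverage mimics real scATAC peak biology, or that
liability-threshold case–control sampling reproduces biobank
ascertainment quirks (self-report misclassification, relatedness
structure, population stratification beyond simulated PCs).  Results on
real cohorts inherit all the usual caveats of the underlying methods.

## Known limitations

* LD is block-diagonal; pruning windows that straddle real long-range
  LD are untested territory.
* The gene test assumes the summary statistics and the LD reference
  describe the same population; mismatch inflates or deflates the
  variance correction, as it does for any LD-aware gene statistic.
* No shrinkage-based score weighting (PRS-CS-style) — clumping +
  thresholding only, by design.
* Firth fallbacks report Wald-type SEs from the penalized information;
  profile-likelihood intervals are not implemented.
* GO/pathway interpretation of gene sets is out of scope; exports are
  plain tibbles precisely so such tools can consume them.
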