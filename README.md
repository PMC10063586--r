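# cellrisk

Linking GWAS risk variants to the cell types and genes they act through
is one of the central problems of complex-disease genetics: most risk
variants are non-coding, sit in cell-type-restricted regulatory DNA, and
reach their target genes through chromatin loops.  `cellrisk` implements
the three analytical stages of that integration as a tested, reusable R
pipeline, together with a synthetic-data generator whose planted truth
makes every stage verifiable without access to consortium or biobank
data:

1. **Regulatory enrichment** — are trait associations concentrated in a
   cell type's open-chromatin peaks?  Variants are greedily LD-pruned
   (keep a variant iff no already-kept variant within a window has
   r² above threshold), dichotomized at a GWAS threshold *T*, and the
   annotation effect is estimated by logistic regression of
   `1{p < T}` on the 0/1 overlap indicator plus quantile-binned matched
   confounders (MAF, distance to nearest TSS, number of LD proxies at
   r² > 0.8), reported as an odds ratio over an annotation × threshold
   grid with Bonferroni control at the effective number of independent
   annotations.

2. **Gene mapping** — variants are assigned to genes through exons,
   strand-aware 2-kb isoform promoters, and chromatin-interaction
   anchors (a variant in one loop anchor is assigned to any gene whose
   exon/promoter overlaps the partner anchor).  The gene statistic is
   the SNP-wise mean, S_g = Σᵢ zᵢ² with zᵢ = Φ⁻¹(1 − pᵢ/2), whose null
   under LD is a weighted sum of 1-df chi-squares with weights equal to
   the eigenvalues of the gene's LD matrix, evaluated exactly (Imhof
   integration; two-moment Brown tail far out).  Risk genes are
   protein-coding genes at Benjamini–Hochberg FDR < 0.05; per-cell-type
   risk sets are partitioned into shared and unique genes.

3. **Cell-specific polygenic risk scores (CPRS)** — after variant and
   kinship QC, variants restricted to a cell type's gene annotation are
   LD-clumped (r² 0.1, 250 kb), the selection p-threshold is optimized
   on a validation cohort, and the score Σᵢ wᵢ dᵢⱼ is evaluated by
   incremental Nagelkerke R², the liability-scale R² (Lee
   transformation with prevalence *K*, default 0.00127), AUC, and
   odds ratios across score quantile strata (top 5% vs the median
   stratum); associations of scores with quantitative phenotypes and
   binary outcomes are covariate-adjusted regressions with BH control.

Everything is tibble-first and pipe-friendly; fitted results have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate a genome with 20,000 variants in LD blocks, plant 50 causal
genes and a cell type whose peaks are enriched (log-OR = log 2) at
significant variants, then run all three stages:

```r
library(cellrisk)
library(dplyr)

genome <- generate_genome(n_variants = 20000, block_size = 5,
                          n_genes = 500, seed = 42)
ld     <- ld_from_genome(genome)
truth  <- plant_truth(genome, n_causal_genes = 50, beta_per_variant = 0.05,
                      h2 = 0.3, K = 0.05, seed = 43)
stats  <- generate_gwas(genome, truth, n_eff = 5e4, seed = 44)

# 1. enrichment scan over three cell types (ct01 planted)
peaks <- generate_enriched_annotations(stats, n_cell_types = 3,
                                       enriched_cell_type = "ct01",
                                       log_or = log(2), base_rate = 0.25,
                                       seed = 45)
scan <- run_enrichment_scan(stats, peaks$peaks, ld, genome$genes,
                            thresholds = c(1e-3, 1e-5))
as_tibble(scan) |> filter(threshold == 1e-5) |>
  select(annotation, or, p, n_significant, significant_after_correction)
#> # A tibble: 3 × 5
#>   annotation    or      p n_significant significant_after_correction
#>   <chr>      <dbl>  <dbl>         <int> <lgl>
#> 1 ct01       1.57  0.0363           102 FALSE
#> 2 ct02       0.977 0.921            102 FALSE
#> 3 ct03       0.992 0.973            102 FALSE

# 2. gene mapping: exons + promoters + loops, LD-aware gene test, FDR
loops <- generate_loops(genome, n_loops = 30,
                        target_genes = truth$causal_genes, seed = 46)
ann <- merge_annotations(
  build_location_annotation(stats, genome$genes),
  build_interaction_annotation(stats, genome$genes, loops))
genes <- fdr_filter(gene_level_test(stats, ann, ld, genome$genes))
sum(genes$risk)                                        #> 52 risk genes of 500
mean(truth$causal_genes %in% genes$gene_id[genes$risk]) #> sensitivity 1

# 3. cell-specific score on an ascertained cohort
cohort   <- generate_cohort(genome, truth,
                            sampling = c(n_cases = 400, n_controls = 1600),
                            seed = 47)
universe <- restrict_universe(list(ct01 = ann), "ct01", "all")
clumped  <- clump_variants(filter(stats, variant_id %in% universe), ld)
opt <- optimize_threshold(clumped, cohort, covariates = paste0("pc", 1:4))
prs <- compute_prs(cohort, opt$model)
evaluate_scores(prs, cohort$samples$status,
                cohort$samples[paste0("pc", 1:4)], K = 0.05)
#> <cprs_result> n = 2000 (400 cases)  R2_obs = 0.2448  R2_liab = 0.2253
#>               AUC = 0.782  p = 1.45e-57
```

The enriched cell type carries the largest odds ratio; the 52 flagged
risk genes contain all 50 planted causal genes; and the cell-specific
score separates the ascertained cases from controls (AUC 0.78), with
the prevalence-corrected liability-scale R² alongside the observed
(Nagelkerke) R².  `run_pipeline(out_dir, seed)` chains all of the above
— including writing and re-reading every input in its standard on-disk
format (summary-stats TSV, BED, BEDPE, GTF, dosage TSV/VCF, truth JSON)
— deterministically for a fixed seed.

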