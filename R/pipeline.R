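#' Run the full synthetic pipeline end to end
#'
#' Simulates a genome, planted truth, GWAS summary statistics, per-cell-
#' type peaks, loops and an ascertained cohort; writes every input in its
#' standard on-disk format (TSV summary stats, BED peaks, BEDPE loops,
#' GTF gene models, dosage TSV, phenotype TSV, truth JSON); reads them
#' back through the package readers; and runs every analysis stage:
#' cell-specific peak derivation, the enrichment scan, gene mapping with
#' the LD-aware gene test and FDR filtering, per-cell-type score building
#' with threshold optimization and evaluation, score stratification, and
#' phenotype association.  All stage outputs are written under
#' `out_dir/results`.  Every random draw derives from `seed`, so a fixed
#' seed reproduces all files byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_variants,block_size,n_genes Genome size parameters.
#' @param n_cell_types Number of simulated cell types.
#' @param n_causal_genes,beta_per_variant Planted causal architecture.
#' @param enrich_log_or Planted enrichment log-odds for cell type
#'   `"ct01"`.
#' @param n_eff GWAS effective sample size.
#' @param h2 Liability heritability.
#' @param K Population prevalence used for the cohort simulation (the
#'   demo keeps it large enough that case ascertainment stays cheap; the
#'   liability correction still takes any K).
#' @param n_cases,n_controls Ascertained cohort sizes.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         n_variants = 2000, block_size = 5, n_genes = 60,
                         n_cell_types = 3, n_causal_genes = 6,
                         beta_per_variant = 0.04, enrich_log_or = log(2),
                         n_eff = 5e4, h2 = 0.3, K = 0.05,
                         n_cases = 300, n_controls = 700,
                         quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  in_dir <- file.path(out_dir, "inputs")
  res_dir <- file.path(out_dir, "results")
  dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

  ## --- simulate -----------------------------------------------------
  say("simulating genome / truth / GWAS / cohort")
  genome <- generate_genome(n_variants, block_size = block_size,
                            n_genes = n_genes, seed = derive_seed(seed, 1))
  truth <- plant_truth(genome, n_causal_genes, beta_per_variant,
                       h2 = h2, K = K,
                       phenotype_effects = c(wmv = -0.13),
                       enriched_annotations = setNames(enrich_log_or, "ct01"),
                       seed = derive_seed(seed, 2))
  stats <- generate_gwas(genome, truth, n_eff = n_eff,
                         seed = derive_seed(seed, 3))
  anns <- generate_enriched_annotations(
    stats, n_cell_types, enriched_cell_type = "ct01",
    log_or = enrich_log_or, seed = derive_seed(seed, 4))
  cell_types <- names(anns$peaks)
  loops <- lapply(seq_along(cell_types), function(i) {
    generate_loops(genome, n_loops = 40,
                   target_genes = truth$causal_genes,
                   seed = derive_seed(seed, 10 + i))
  })
  names(loops) <- cell_types
  cohort <- generate_cohort(genome, truth,
                            sampling = c(n_cases = n_cases,
                                         n_controls = n_controls),
                            seed = derive_seed(seed, 5))

  ## --- write inputs, read them back (round trip is part of the run) --
  write_summary_stats(stats, file.path(in_dir, "gwas.tsv"))
  write_gtf(genome$genes, file.path(in_dir, "genes.gtf"))
  for (ct in cell_types) {
    write_bed(anns$peaks[[ct]], file.path(in_dir, paste0("peaks_", ct, ".bed")))
    write_bedpe(loops[[ct]], file.path(in_dir, paste0("loops_", ct, ".bedpe")))
  }
  write_dosages_tsv(cohort$dosages, cohort$variants,
                    file.path(in_dir, "dosages.tsv"))
  readr::write_tsv(cohort$samples, file.path(in_dir, "samples.tsv"))
  write_truth_json(truth, file.path(in_dir, "truth.json"))

  stats <- read_summary_stats(file.path(in_dir, "gwas.tsv"))
  genes <- read_gene_models(file.path(in_dir, "genes.gtf"), "gtf")
  peaksets <- lapply(cell_types, function(ct) {
    read_bed(file.path(in_dir, paste0("peaks_", ct, ".bed")))
  })
  names(peaksets) <- cell_types
  loops <- lapply(cell_types, function(ct) {
    read_bedpe(file.path(in_dir, paste0("loops_", ct, ".bedpe")))
  })
  names(loops) <- cell_types
  dos <- read_dosages_tsv(file.path(in_dir, "dosages.tsv"))
  samples <- read_table_tsv(file.path(in_dir, "samples.tsv"))
  cohort <- list(dosages = dos$dosages,
                 variants = left_join(dos$variants,
                                      select(stats, "variant_id", "maf"),
                                      by = "variant_id"),
                 samples = samples)
  ld <- ld_from_genome(genome)

  ## --- peaks + enrichment -------------------------------------------
  say("deriving specific peaks and running the enrichment scan")
  specific <- derive_cell_specific_peaks(peaksets)
  scan <- run_enrichment_scan(stats, specific, ld, genes,
                              thresholds = c(0.05, 1e-3, 1e-5, 1e-8))
  readr::write_tsv(as_tibble(scan), file.path(res_dir, "enrichment.tsv"))

  ## --- gene mapping --------------------------------------------------
  say("gene mapping and gene-level tests")
  loc <- build_location_annotation(stats, genes)
  gene_res <- list(); risk_sets <- list(); merged_ann <- list()
  for (ct in cell_types) {
    ia <- build_interaction_annotation(stats, genes, loops[[ct]])
    merged <- merge_annotations(loc, ia)
    merged_ann[[ct]] <- merged
    res <- fdr_filter(gene_level_test(stats, merged, ld, genes))
    gene_res[[ct]] <- res
    risk_sets[[ct]] <- res$gene_id[res$risk]
    readr::write_tsv(res, file.path(res_dir, paste0("genes_", ct, ".tsv")))
  }
  partition <- compare_gene_sets(risk_sets)
  jsonlite::write_json(partition[c("shared", "unique")],
                       file.path(res_dir, "gene_partition.json"),
                       auto_unbox = FALSE, digits = NA)

  ## --- scoring -------------------------------------------------------
  say("building and evaluating cell-specific scores")
  qc <- qc_filter(stats, cohort)
  covars <- grep("^pc", names(samples), value = TRUE)
  score_eval <- list(); scores_tbl <- list()
  for (ct in cell_types) {
    universe <- restrict_universe(merged_ann, ct, "all")
    st_u <- filter(qc$stats, .data$variant_id %in% universe)
    clumped <- clump_variants(st_u, ld)
    opt <- optimize_threshold(clumped, qc$cohort, covariates = covars,
                              cell_type = ct, universe = "all_cell_snps")
    sc <- compute_prs(qc$cohort, opt$model)
    ev <- evaluate_scores(sc, qc$cohort$samples$status,
                          qc$cohort$samples[covars], K = K)
    score_eval[[ct]] <- ev
    scores_tbl[[ct]] <- mutate(sc, cell_type = ct)
  }
  readr::write_tsv(bind_rows(scores_tbl), file.path(res_dir, "scores.tsv"))
  jsonlite::write_json(lapply(score_eval, function(e) glance(e)),
                       file.path(res_dir, "cprs_eval.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  strata <- stratify_or(filter(bind_rows(scores_tbl),
                               .data$cell_type == "ct01")$score,
                        qc$cohort$samples$status)
  readr::write_tsv(as_tibble(strata), file.path(res_dir, "strata.tsv"))

  ## --- phenotype association ----------------------------------------
  say("phenotype association")
  covar_df <- qc$cohort$samples[, c("age", "gender", "disease_duration")]
  sc1 <- filter(bind_rows(scores_tbl), .data$cell_type == "ct01")$score
  relapse <- simulate_binary_outcome(qc$cohort$samples$genetic_score, 0.29,
                                     seed = derive_seed(seed, 30))
  assoc <- bind_rows(
    assoc_linear(sc1, qc$cohort$samples$wmv, covar_df,
                 phenotype_name = "wmv", label = "ct01"),
    select(assoc_binary(sc1, relapse, covar_df,
                        outcome_name = "relapse", label = "ct01"),
           -"or", -"status")
  )
  assoc <- multiple_testing(assoc)
  readr::write_tsv(assoc, file.path(res_dir, "phenotype_assoc.tsv"))

  invisible(list(
    genome = genome, truth = truth, stats = stats, scan = scan,
    gene_results = gene_res, partition = partition,
    score_eval = score_eval, strata = strata, assoc = assoc
  ))
}
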