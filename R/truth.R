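#' Planted-truth container for synthetic data
#'
#' Records every planted quantity a downstream recovery test needs:
#' per-annotation enrichment log-odds, causal genes, per-variant liability
#' effect sizes, heritability, prevalence, and planted phenotype effects.
#'
#' @param causal_variants Named numeric vector: per-variant effect size
#'   `beta` on the liability scale (standardized-dosage units).  May be
#'   empty.
#' @param causal_genes Character vector of causal gene ids.
#' @param enriched_annotations Named numeric vector: annotation (cell type)
#'   id -> planted log-odds of overlap for significant variants.
#' @param h2 Heritability of liability in \[0, 1).
#' @param K Population prevalence in (0, 1).  Defaults to 0.00127, the
#'   multiple-sclerosis prevalence used for liability-scale corrections.
#' @param phenotype_effects Named numeric vector: quantitative phenotype ->
#'   planted standardized beta on the true genetic score.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(causal_variants = numeric(),
                            causal_genes = character(),
                            enriched_annotations = numeric(),
                            h2 = 0,
                            K = 0.00127,
                            phenotype_effects = numeric()) {
  check_scalar_number(h2, "h2", lower = 0, upper = 1 - 1e-12)
  check_scalar_number(K, "K", lower = 1e-12, upper = 1 - 1e-12)
  if (length(causal_variants) && is.null(names(causal_variants))) {
    abort("`causal_variants` must be a named numeric vector (variant id -> beta).")
  }
  structure(
    list(
      causal_variants = causal_variants,
      causal_genes = causal_genes,
      enriched_annotations = enriched_annotations,
      h2 = h2,
      K = K,
      phenotype_effects = phenotype_effects
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d causal variants, %d causal genes, h2 = %.3g, K = %.3g\n",
    length(x$causal_variants), length(x$causal_genes), x$h2, x$K
  ))
  invisible(x)
}

#' Plant causal genes and variants into a genome model
#'
#' Picks `n_causal_genes` protein-coding genes, then places causal variants
#' inside their exons (variants whose position falls in an exon interval of
#' the gene), each with liability effect `beta_per_variant`.  All planted
#' quantities are recorded in the returned [synthetic_truth()].
#'
#' @param genome A [generate_genome()] result with genes.
#' @param n_causal_genes Number of causal genes to plant.
#' @param beta_per_variant Liability-scale effect per causal variant
#'   (standardized-dosage units).
#' @param h2,K,phenotype_effects,enriched_annotations Passed to
#'   [synthetic_truth()].
#' @param seed Integer seed for the gene draw.
#' @return A [synthetic_truth()].
#' @export
plant_truth <- function(genome, n_causal_genes, beta_per_variant,
                        h2 = 0.2, K = 0.00127,
                        phenotype_effects = numeric(),
                        enriched_annotations = numeric(),
                        seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(genome$genes)) abort("Genome has no gene models; regenerate with `n_genes > 0`.")
  set.seed(as.integer(seed))
  pc <- filter(genome$genes$genes, .data$biotype == "protein_coding")
  if (nrow(pc) < n_causal_genes) abort("Not enough protein-coding genes to plant.")
  causal_genes <- sort(sample(pc$gene_id, n_causal_genes))

  ex <- filter(genome$genes$exons, .data$gene_id %in% causal_genes)
  hits <- variants_in_intervals(genome$variants, ex)
  causal_ids <- unique(genome$variants$variant_id[hits])
  if (!length(causal_ids)) abort("No variants fall in exons of the chosen genes.")
  causal <- setNames(rep(beta_per_variant, length(causal_ids)), causal_ids)

  synthetic_truth(
    causal_variants = causal,
    causal_genes = causal_genes,
    enriched_annotations = enriched_annotations,
    h2 = h2, K = K,
    phenotype_effects = phenotype_effects
  )
}

# Logical index of variants whose position lies in any half-open interval.
variants_in_intervals <- function(variants, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, nrow(variants)))
  q <- points_to_granges(variants$chrom, variants$pos)
  s <- peaks_to_granges(intervals)
  suppressWarnings(IRanges::overlapsAny(q, s))
}
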