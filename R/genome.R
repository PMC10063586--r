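#' Synthetic genome model with LD blocks and gene models
#'
#' A `genome_model` bundles a variant table, a block-diagonal signed LD
#' structure, and isoform-resolved gene models.  It is the substrate every
#' other generator draws on: GWAS summary statistics are simulated per LD
#' block, cohort dosages come from a Gaussian copula over the same blocks,
#' and peaks/loops are placed relative to the variant grid.
#'
#' LD is block-diagonal by construction: correlation is zero across blocks
#' and follows either an exchangeable or a distance-decaying (AR-1) profile
#' within a block.  Each variant carries a random sign so that signed
#' correlations `r` take both signs while `r^2` follows the chosen profile;
#' pruning, clumping and proxy logic only ever consume `r^2`.
#'
#' @param n_variants Number of variants to simulate (>= 1).
#' @param block_size LD block size; a scalar or a vector of sizes that is
#'   recycled/truncated to cover all variants.  Size 1 everywhere gives an
#'   identity LD matrix.
#' @param chrom Chromosome label for all variants.
#' @param spacing_bp Mean spacing between adjacent variants in bp; actual
#'   gaps are drawn uniformly in `[0.2, 1.8] * spacing_bp`.
#' @param maf_range Range of minor allele frequencies, within (0, 0.5].
#' @param r2_profile `"decaying"` for an AR-1 profile (`r2_within` between
#'   adjacent variants, decaying with distance in index), `"exchangeable"`
#'   for constant within-block `r^2`, or `"none"`.
#' @param r2_within Within-block r-squared parameter of the profile, in \[0, 1).
#' @param n_genes Number of genes laid over the variant grid (0 for none).
#' @param gene_span_variants Number of consecutive variants in each gene's
#'   territory; exons are placed to cover a subset of them.
#' @param prop_protein_coding Fraction of genes with biotype
#'   `protein_coding` (the rest are `other`).
#' @param seed Integer seed; the same seed and parameters reproduce the
#'   model exactly.
#'
#' @return An object of class `genome_model`: a list with `variants`
#'   (tibble: `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `maf`, `block`), `block_r` (list of signed correlation matrices, one
#'   per block, dimnames = variant ids) and `genes` (a [gene_models()]
#'   object, or `NULL`).
#' @export
#' @examples
#' g <- generate_genome(n_variants = 100, block_size = 5, seed = 1)
#' g$variants
generate_genome <- function(n_variants,
                            block_size = 10,
                            chrom = "chr1",
                            spacing_bp = 1000,
                            maf_range = c(0.05, 0.5),
                            r2_profile = c("decaying", "exchangeable", "none"),
                            r2_within = 0.5,
                            n_genes = 0,
                            gene_span_variants = 8,
                            prop_protein_coding = 0.8,
                            seed = 1L) {
  r2_profile <- match.arg(r2_profile)
  check_scalar_number(n_variants, "n_variants", lower = 1)
  check_scalar_number(r2_within, "r2_within", lower = 0, upper = 1 - 1e-12)
  check_scalar_number(spacing_bp, "spacing_bp", lower = 1)
  if (any(block_size < 1)) abort("All `block_size` values must be >= 1.")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  n_variants <- as.integer(n_variants)
  set.seed(as.integer(seed))

  # Block assignment: recycle block sizes until all variants are covered.
  sizes <- as.integer(block_size)
  sizes <- rep_len(sizes, ceiling(n_variants / min(sizes)) + n_variants)
  block <- rep.int(seq_along(sizes), sizes)[seq_len(n_variants)]
  block <- match(block, unique(block))

  gaps <- as.integer(round(runif(n_variants, 0.2, 1.8) * spacing_bp))
  gaps <- pmax(gaps, 1L)
  pos <- cumsum(gaps) + 10000L

  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n_variants, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))

  variants <- tibble(
    variant_id = sprintf("rs%06d", seq_len(n_variants)),
    chrom = chrom,
    pos = pos,
    effect_allele = ea,
    other_allele = unname(oa),
    maf = runif(n_variants, maf_range[1], maf_range[2]),
    block = block
  )

  r_within <- sqrt(r2_within)
  block_r <- lapply(split(seq_len(n_variants), block), function(idx) {
    k <- length(idx)
    R <- switch(r2_profile,
      none = diag(k),
      exchangeable = {
        M <- matrix(r_within, k, k); diag(M) <- 1; M
      },
      decaying = r_within^abs(outer(seq_len(k), seq_len(k), "-"))
    )
    s <- sample(c(-1, 1), k, replace = TRUE)
    R <- R * tcrossprod(s)
    diag(R) <- 1
    dimnames(R) <- list(variants$variant_id[idx], variants$variant_id[idx])
    R
  })
  names(block_r) <- as.character(seq_along(block_r))

  genes <- NULL
  if (n_genes > 0) {
    genes <- .layout_genes(variants, n_genes, gene_span_variants,
                           prop_protein_coding)
  }

  structure(
    list(variants = variants, block_r = block_r, genes = genes),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %d variants in %d LD blocks%s\n",
    nrow(x$variants), length(x$block_r),
    if (is.null(x$genes)) "" else sprintf(", %d genes", nrow(x$genes$genes))
  ))
  invisible(x)
}

# Lay non-overlapping gene territories over the variant grid.  Exons are
# placed to contain known variants so that causal variants can be planted
# inside exons of chosen genes.
.layout_genes <- function(variants, n_genes, span, prop_pc) {
  n_variants <- nrow(variants)
  if (n_genes * (span + 2) > n_variants) {
    abort("Too many genes for the variant grid; reduce `n_genes` or `gene_span_variants`.")
  }
  starts <- floor(seq(1, n_variants - span, length.out = n_genes))
  genes_l <- vector("list", n_genes)
  iso_l <- vector("list", n_genes)
  exon_l <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    idx <- starts[g]:(starts[g] + span - 1)
    vpos <- variants$pos[idx]
    gid <- sprintf("GENE%04d", g)
    strand <- sample(c("+", "-"), 1)
    biotype <- if (runif(1) < prop_pc) "protein_coding" else "other"
    chromg <- variants$chrom[idx[1]]
    region_start <- min(vpos) - 200L
    region_end <- max(vpos) + 200L

    # Exons: split the span variants into 2-3 groups, each becoming one
    # exon interval padded by 50 bp on both sides.
    n_exon <- sample(2:3, 1)
    grp <- sort(rep_len(seq_len(n_exon), span))
    exons <- tibble(
      gene_id = gid,
      transcript_id = paste0(gid, ".1"),
      chrom = chromg,
      start = as.integer(tapply(vpos, grp, min)) - 50L,
      end = as.integer(tapply(vpos, grp, max)) + 50L
    )

    n_iso <- sample(1:2, 1)
    tss <- if (strand == "+") {
      region_start + as.integer(runif(n_iso, 0, 100))
    } else {
      region_end - as.integer(runif(n_iso, 0, 100))
    }
    iso <- tibble(
      gene_id = gid,
      transcript_id = paste0(gid, ".", seq_len(n_iso)),
      chrom = chromg,
      strand = strand,
      tss = as.integer(tss)
    )
    if (n_iso > 1) {
      exons <- bind_rows(exons, mutate(exons, transcript_id = paste0(gid, ".2")))
    }
    genes_l[[g]] <- tibble(gene_id = gid, chrom = chromg, strand = strand,
                           biotype = biotype,
                           start = region_start, end = region_end)
    iso_l[[g]] <- iso
    exon_l[[g]] <- exons
  }
  gene_models(bind_rows(genes_l), bind_rows(iso_l), bind_rows(exon_l))
}

#' Gene model container
#'
#' Bundles gene-, isoform- and exon-level tables with the 0-based half-open
#' coordinate convention used throughout the package.  `tss` is the 0-based
#' position of the first transcribed base: for `+` strand isoforms the
#' smallest transcript coordinate, for `-` strand the largest.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `strand`, `biotype` (and
#'   optionally `start`, `end`).
#' @param isoforms Tibble with `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `tss`.
#' @param exons Tibble with `gene_id`, `transcript_id`, `chrom`, `start`,
#'   `end` (half-open).
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, isoforms, exons) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(sprintf("`%s` is missing column(s): %s", what,
                    paste(miss, collapse = ", ")))
    }
  }
  need(genes, c("gene_id", "chrom", "strand", "biotype"), "genes")
  need(isoforms, c("gene_id", "transcript_id", "chrom", "strand", "tss"),
       "isoforms")
  need(exons, c("gene_id", "transcript_id", "chrom", "start", "end"), "exons")
  if (any(exons$end < exons$start)) abort("Exon intervals must have end >= start.")
  structure(
    list(genes = as_tibble(genes), isoforms = as_tibble(isoforms),
         exons = as_tibble(exons)),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d isoforms, %d exons\n",
              nrow(x$genes), nrow(x$isoforms), nrow(x$exons)))
  invisible(x)
}
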