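#' Read gene models from GTF or BED12
#'
#' GTF coordinates (1-based, end-inclusive) are converted to the internal
#' 0-based half-open convention on ingest; BED12 is already half-open.
#' Isoform-level TSSs are derived strand-aware: the smallest transcript
#' coordinate on `+`, the largest on `-`.
#'
#' For the BED12 dialect the `name` field must encode
#' `gene_id|transcript_id|biotype` and blocks are taken as exons.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @param chr_prefix As in [read_bed()].
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, dialect = c("gtf", "bed12"),
                             chr_prefix = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (dialect == "gtf") .read_gtf(path, chr_prefix) else .read_bed12(path, chr_prefix)
}

.read_gtf <- function(path, chr_prefix) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) abort("GTF parse error: missing `gene_id` attribute.")
  biotype <- md$gene_biotype %||% md$gene_type
  if (is.null(biotype)) {
    abort("GTF parse error: missing `gene_biotype`/`gene_type` attribute.")
  }
  df <- tibble(
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr)), chr_prefix),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    biotype = as.character(biotype)
  )
  if (any(is.na(df$gene_id)) || any(is.na(df$biotype))) {
    abort("GTF parse error: record without gene_id/biotype.")
  }
  tx <- filter(df, .data$type == "transcript")
  ex <- filter(df, .data$type == "exon")
  if (!nrow(tx)) {
    # Fall back to exon extents per transcript when no transcript lines.
    tx <- summarise(group_by(ex, .data$gene_id, .data$transcript_id,
                             .data$chrom, .data$strand, .data$biotype),
                    start = min(.data$start), end = max(.data$end),
                    .groups = "drop")
  }
  isoforms <- mutate(
    tx,
    tss = if_else(.data$strand == "+", .data$start, .data$end - 1L)
  )
  genes <- distinct(select(isoforms, "gene_id", "chrom", "strand", "biotype"))
  gene_models(
    genes = genes,
    isoforms = select(isoforms, "gene_id", "transcript_id", "chrom",
                      "strand", "tss"),
    exons = select(ex, "gene_id", "transcript_id", "chrom", "start", "end")
  )
}

.read_bed12 <- function(path, chr_prefix) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    abort(sprintf("BED12 parse error at line %d: fewer than 12 columns.",
                  which(nf < 12)[1]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  name <- strsplit(col(4), "|", fixed = TRUE)
  if (any(lengths(name) < 3)) {
    abort("BED12 parse error: `name` must encode gene_id|transcript_id|biotype.")
  }
  chrom <- normalize_chrom(col(1), chr_prefix)
  start <- as.integer(col(2)); end <- as.integer(col(3))
  strand <- col(6)
  gene_id <- vapply(name, `[[`, character(1), 1)
  transcript_id <- vapply(name, `[[`, character(1), 2)
  biotype <- vapply(name, `[[`, character(1), 3)
  isoforms <- tibble(
    gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
    strand = strand,
    tss = if_else(strand == "+", start, end - 1L)
  )
  exons <- purrr::pmap_dfr(
    list(seq_along(fields), start, gene_id, transcript_id, chrom),
    function(i, st, g, t, ch) {
      sizes <- as.integer(strsplit(col(11)[i], ",")[[1]])
      offs <- as.integer(strsplit(col(12)[i], ",")[[1]])
      tibble(gene_id = g, transcript_id = t, chrom = ch,
             start = st + offs, end = st + offs + sizes)
    }
  )
  gene_models(
    genes = distinct(tibble(gene_id = gene_id, chrom = chrom,
                            strand = strand, biotype = biotype)),
    isoforms = isoforms,
    exons = exons
  )
}

#' Write gene models as GTF
#'
#' Emits one `transcript` and per-exon `exon` line per isoform, converting
#' the internal 0-based half-open coordinates back to GTF's 1-based
#' inclusive convention.  `read_gene_models(..., dialect = "gtf")` on the
#' output reproduces the input object.
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  iso <- left_join(models$isoforms,
                   select(models$genes, "gene_id", "biotype"),
                   by = "gene_id")
  ex_by_tx <- split(models$exons, models$exons$transcript_id)
  lines <- character(0)
  for (i in seq_len(nrow(iso))) {
    r <- iso[i, ]
    ex <- ex_by_tx[[r$transcript_id]]
    if (is.null(ex)) next
    # Transcript extent: TSS to the far exon end, strand-aware.
    if (r$strand == "+") {
      tx_start1 <- r$tss + 1L
      tx_end1 <- max(ex$end)
    } else {
      tx_start1 <- min(ex$start) + 1L
      tx_end1 <- r$tss + 1L
    }
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     r$gene_id, r$transcript_id, r$biotype)
    lines <- c(lines,
               paste(r$chrom, "cellrisk", "transcript", tx_start1, tx_end1,
                     ".", r$strand, ".", attrs, sep = "\t"),
               paste(ex$chrom, "cellrisk", "exon", ex$start + 1L, ex$end,
                     ".", r$strand, ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
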