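#' Read GWAS summary statistics from a delimited file
#'
#' @param path Path to a tab-delimited file with a header.
#' @param column_map Optional named character vector mapping internal
#'   column names (`variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `p`, `maf`, `info`) to the file's
#'   column names.  Unmapped internal names are looked up verbatim.
#' @param chr_prefix As in [read_bed()].
#' @return A summary-statistics tibble with the internal column names.
#'   `p = 0` is rejected with a pointer to the smallest positive double;
#'   duplicate variant ids are rejected.
#' @export
read_summary_stats <- function(path, column_map = NULL, chr_prefix = TRUE) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  internal <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "p", "maf", "info")
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "p", "maf")
  map <- setNames(internal, internal)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  missing <- required[!map[required] %in% names(raw)]
  if (length(missing)) {
    abort(sprintf("Summary-stats file is missing required column(s): %s",
                  paste(map[missing], collapse = ", ")))
  }
  present <- intersect(internal, internal[map %in% names(raw)])
  out <- as_tibble(setNames(raw[map[present]], present))
  if (!"info" %in% names(out)) out$info <- 1
  out$chrom <- normalize_chrom(as.character(out$chrom), chr_prefix)
  out$pos <- as.integer(out$pos)
  for (col in c("beta", "se", "p", "maf", "info")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  if (anyDuplicated(out$variant_id)) {
    abort(sprintf("Duplicate variant id(s): %s",
                  paste(utils::head(unique(out$variant_id[duplicated(out$variant_id)]), 3),
                        collapse = ", ")))
  }
  if (any(out$p <= 0, na.rm = TRUE)) {
    abort(paste("p = 0 is not representable on (0, 1]; replace zero p-values",
                "with the smallest positive double (about 4.9e-324) upstream."))
  }
  if (any(out$p > 1, na.rm = TRUE)) abort("p-values must lie in (0, 1].")
  if (any(out$maf <= 0 | out$maf > 0.5, na.rm = TRUE)) {
    abort("MAF must lie in (0, 0.5].")
  }
  out
}

#' Write summary statistics to TSV
#'
#' @param stats Summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  cols <- intersect(c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "beta", "se", "p", "maf", "info"),
                    names(stats))
  readr::write_tsv(stats[cols], path)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Thin wrapper over tab-delimited reading, kept so every pipeline input
#' goes through one audited entry point.
#'
#' @param path Path to a tab-delimited file with a header.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read a dosage matrix as TSV
#'
#' The TSV layout is one row per variant: `variant_id`, `effect_allele`,
#' `other_allele`, then one column per sample holding the effect-allele
#' dosage in \[0, 2\].
#'
#' @param dosages Individuals x variants numeric matrix with dimnames.
#' @param variants Tibble with `variant_id`, `effect_allele`,
#'   `other_allele` covering the matrix columns.
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, a list with
#'   `dosages` (individuals x variants matrix) and `variants`.
#' @export
write_dosages_tsv <- function(dosages, variants, path) {
  stopifnot(!is.null(colnames(dosages)), !is.null(rownames(dosages)))
  v <- variants[match(colnames(dosages), variants$variant_id),
                c("variant_id", "effect_allele", "other_allele")]
  out <- dplyr::bind_cols(v, as_tibble(t(dosages)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_dosages_tsv
#' @export
read_dosages_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- c("variant_id", "effect_allele", "other_allele")
  miss <- setdiff(meta, names(raw))
  if (length(miss)) {
    abort(sprintf("Dosage TSV missing column(s): %s", paste(miss, collapse = ", ")))
  }
  sample_cols <- setdiff(names(raw), meta)
  D <- t(as.matrix(raw[sample_cols]))
  dimnames(D) <- list(sample_cols, raw$variant_id)
  if (any(D < 0 | D > 2, na.rm = TRUE)) abort("Dosages must lie in [0, 2].")
  list(dosages = D, variants = raw[meta])
}

#' Write / read dosages as a minimal VCF with a DS genotype field
#'
#' The writer emits a sites-plus-genotypes VCF 4.2 with a single `DS`
#' FORMAT field (effect-allele dosage as ALT allele dosage); the reader
#' accepts exactly that dialect.
#'
#' @inheritParams write_dosages_tsv
#' @param chrom,pos Per-variant coordinates for the VCF columns.
#' @return As in [write_dosages_tsv()].
#' @export
write_dosages_vcf <- function(dosages, variants, path) {
  v <- variants[match(colnames(dosages), variants$variant_id), ]
  samples <- rownames(dosages)
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Effect (ALT) allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$other_allele[i],
            v$effect_allele[i], ".", "PASS", ".", "DS",
            format(dosages[, i], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_dosages_vcf
#' @export
read_dosages_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1) abort("VCF parse error: missing #CHROM header line.")
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(list(dosages = matrix(numeric(), 0, 0),
                variants = tibble(variant_id = character())))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  fmt <- vapply(fields, `[[`, character(1), 9L)
  ds_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("DS", f), integer(1))
  if (any(is.na(ds_idx))) {
    abort(sprintf("VCF parse error at record %d: no DS field in FORMAT.",
                  which(is.na(ds_idx))[1]))
  }
  D <- vapply(seq_along(fields), function(i) {
    g <- fields[[i]][-(1:9)]
    as.numeric(vapply(strsplit(g, ":", fixed = TRUE), `[[`, character(1),
                      ds_idx[i]))
  }, numeric(length(samples)))
  if (is.null(dim(D))) D <- matrix(D, nrow = length(samples))
  variants <- tibble(
    variant_id = vapply(fields, `[[`, character(1), 3L),
    chrom = vapply(fields, `[[`, character(1), 1L),
    pos = as.integer(vapply(fields, `[[`, character(1), 2L)),
    other_allele = vapply(fields, `[[`, character(1), 4L),
    effect_allele = vapply(fields, `[[`, character(1), 5L)
  )
  dimnames(D) <- list(samples, variants$variant_id)
  if (any(D < 0 | D > 2, na.rm = TRUE)) abort("Dosages must lie in [0, 2].")
  list(dosages = D, variants = variants)
}

#' Serialize / restore planted truth as JSON
#'
#' @param truth A [synthetic_truth()].
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, the truth
#'   object.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  payload <- unclass(truth)
  # named numeric vectors must become JSON objects, not bare arrays
  for (f in c("causal_variants", "enriched_annotations", "phenotype_effects")) {
    payload[[f]] <- as.list(payload[[f]])
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_truth(
    causal_variants = unlist(x$causal_variants) %||% numeric(),
    causal_genes = as.character(x$causal_genes %||% character()),
    enriched_annotations = unlist(x$enriched_annotations) %||% numeric(),
    h2 = x$h2, K = x$K,
    phenotype_effects = unlist(x$phenotype_effects) %||% numeric()
  )
}
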