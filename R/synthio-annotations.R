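#' Simulate per-cell-type peak sets with a known sharing profile
#'
#' Places non-overlapping candidate peaks along the chromosome, draws each
#' peak's sharing count (how many cell types contain it) from the requested
#' profile, and assigns it to that many randomly chosen cell types.  The
#' per-peak membership count is recorded so specificity-rule tests can
#' check recovery exactly.
#'
#' @param genome A [generate_genome()] result (peaks are placed over its
#'   coordinate span).
#' @param n_cell_types Number of cell types (>= 2).
#' @param sharing `"unique"` (every peak in exactly one cell type),
#'   `"ubiquitous"` (every peak in all), or a numeric probability vector of
#'   length `n_cell_types` over sharing counts 1..n_cell_types.
#' @param n_peaks Number of candidate peaks.
#' @param peak_width Peak width in bp.
#' @param seed Integer seed.
#' @return An object of class `annotation_sets`: list with `peaks` (named
#'   list of half-open interval tibbles, one per cell type) and `truth`
#'   (tibble: `chrom`, `start`, `end`, `n_shared`, `cell_types`).
#' @export
generate_annotations <- function(genome, n_cell_types, sharing = "unique",
                                 n_peaks = 500, peak_width = 200,
                                 seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (n_cell_types < 2) abort("`n_cell_types` must be >= 2.")
  if (is.character(sharing)) {
    sharing <- match.arg(sharing, c("unique", "ubiquitous"))
    profile <- rep(0, n_cell_types)
    profile[if (sharing == "unique") 1 else n_cell_types] <- 1
  } else {
    if (length(sharing) != n_cell_types || any(sharing < 0) || sum(sharing) <= 0) {
      abort("Numeric `sharing` must be a non-negative profile of length `n_cell_types`.")
    }
    profile <- sharing / sum(sharing)
  }
  set.seed(as.integer(seed))

  span <- range(genome$variants$pos)
  grid <- seq(span[1], span[2], by = 2L * as.integer(peak_width))
  if (length(grid) < n_peaks) {
    abort("Genome span too small for `n_peaks` non-overlapping peaks.")
  }
  centers <- sort(sample(grid, n_peaks))
  chrom <- genome$variants$chrom[1]
  half <- as.integer(peak_width) %/% 2L
  start <- as.integer(centers) - half
  end <- start + as.integer(peak_width)

  cell_types <- sprintf("ct%02d", seq_len(n_cell_types))
  k <- sample.int(n_cell_types, n_peaks, replace = TRUE, prob = profile)
  members <- lapply(k, function(ki) sort(sample(cell_types, ki)))

  peaks <- lapply(cell_types, function(ct) {
    keep <- vapply(members, function(m) ct %in% m, logical(1))
    tibble(chrom = chrom, start = start[keep], end = end[keep])
  })
  names(peaks) <- cell_types

  structure(
    list(
      peaks = peaks,
      truth = tibble(chrom = chrom, start = start, end = end, n_shared = k,
                     cell_types = members)
    ),
    class = "annotation_sets"
  )
}

#' Simulate peak sets with planted enrichment at significant variants
#'
#' Builds variant-anchored peaks: each variant gets, per cell type, an
#' independent chance of being covered by a peak centred on it.  For the
#' enriched cell type the coverage probability follows a logistic model in
#' the variant's significance indicator,
#' `P(covered) = plogis(qlogis(base_rate) + log_or * 1\{p < sig_threshold\})`,
#' so the planted log-odds of overlap for significant variants is exactly
#' `log_or`.  Other cell types cover variants at `base_rate` throughout.
#'
#' @param stats Summary-statistics tibble (from [generate_gwas()]).
#' @param n_cell_types Number of cell types (>= 2).
#' @param enriched_cell_type Cell type label receiving the planted
#'   enrichment (one of `"ct01"`.. by default naming).
#' @param log_or Planted log-odds of overlap for significant variants.
#' @param base_rate Baseline coverage probability in (0, 1).
#' @param sig_threshold GWAS p-value threshold defining "significant" for
#'   the plant.
#' @param peak_width Peak width in bp (kept below the variant spacing so
#'   peaks never merge across variants).
#' @param seed Integer seed.
#' @return An `annotation_sets` object (see [generate_annotations()]);
#'   `truth` additionally carries the planted `log_or` as an attribute.
#' @export
generate_enriched_annotations <- function(stats, n_cell_types,
                                          enriched_cell_type = "ct01",
                                          log_or = log(2),
                                          base_rate = 0.1,
                                          sig_threshold = 1e-5,
                                          peak_width = 100,
                                          seed = 1L) {
  if (n_cell_types < 2) abort("`n_cell_types` must be >= 2.")
  check_scalar_number(base_rate, "base_rate", lower = 1e-9, upper = 1 - 1e-9)
  cell_types <- sprintf("ct%02d", seq_len(n_cell_types))
  if (!enriched_cell_type %in% cell_types) {
    abort("`enriched_cell_type` must be one of the generated cell-type labels.")
  }
  set.seed(as.integer(seed))
  sig <- stats$p < sig_threshold
  half <- as.integer(peak_width) %/% 2L
  start <- as.integer(stats$pos) - half
  end <- start + as.integer(peak_width)

  member <- matrix(FALSE, nrow(stats), n_cell_types,
                   dimnames = list(NULL, cell_types))
  for (ct in cell_types) {
    pr <- if (ct == enriched_cell_type) {
      stats::plogis(stats::qlogis(base_rate) + log_or * sig)
    } else {
      rep(base_rate, nrow(stats))
    }
    member[, ct] <- runif(nrow(stats)) < pr
  }

  peaks <- lapply(cell_types, function(ct) {
    keep <- member[, ct]
    tibble(chrom = stats$chrom[keep], start = start[keep], end = end[keep])
  })
  names(peaks) <- cell_types

  truth <- tibble(chrom = stats$chrom, start = start, end = end,
                  n_shared = rowSums(member),
                  cell_types = apply(member, 1, function(m) cell_types[m],
                                     simplify = FALSE))
  truth <- truth[truth$n_shared > 0, ]
  attr(truth, "planted_log_or") <- setNames(log_or, enriched_cell_type)
  structure(list(peaks = peaks, truth = truth), class = "annotation_sets")
}

#' @export
print.annotation_sets <- function(x, ...) {
  cat(sprintf("<annotation_sets> %d cell types, %d consensus peaks\n",
              length(x$peaks), nrow(x$truth)))
  invisible(x)
}
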