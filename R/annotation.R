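#' Derive cell-type-specific peaks from per-cell-type peak sets
#'
#' Overlapping intervals across all cell types are merged into consensus
#' units (>= 1 bp overlap joins).  A consensus unit is cell-type-specific
#' iff its membership count -- the number of cell types with at least one
#' peak overlapping it -- is at most `max_sharing_fraction` of the number
#' of cell types, with the comparison inclusive at exactly half ("half or
#' less").  Each specific unit is emitted into the specific set of every
#' cell type that contains it.
#'
#' @param peaksets Named list of peak tibbles (`chrom`, `start`, `end`),
#'   one per cell type; >= 2 cell types.
#' @param max_sharing_fraction Maximum membership fraction for a unit to
#'   count as specific (default 0.5).
#' @return Named list (same cell-type names) of specific-peak tibbles with
#'   an extra `n_shared` column giving the unit's membership count.
#' @export
#' @examples
#' ps <- list(a = tibble::tibble(chrom = "chr1", start = 0, end = 100),
#'            b = tibble::tibble(chrom = "chr1", start = 500, end = 600))
#' derive_cell_specific_peaks(ps)
derive_cell_specific_peaks <- function(peaksets, max_sharing_fraction = 0.5) {
  if (length(peaksets) < 2) abort("Need peak sets for at least 2 cell types.")
  if (is.null(names(peaksets)) || any(!nzchar(names(peaksets)))) {
    abort("`peaksets` must be a named list (one name per cell type).")
  }
  n_ct <- length(peaksets)
  empty <- vapply(peaksets, function(p) nrow(p) == 0, logical(1))
  if (all(empty)) {
    warn("All peak sets are empty; returning empty specific sets.")
    return(lapply(peaksets, function(p) mutate(p[0, ], n_shared = integer())))
  }
  grl <- lapply(peaksets, peaks_to_granges)
  consensus <- GenomicRanges::reduce(do.call(c, unname(grl)))
  membership <- vapply(grl, function(g) {
    suppressWarnings(IRanges::overlapsAny(consensus, g))
  }, logical(length(consensus)))
  if (is.null(dim(membership))) membership <- matrix(membership, nrow = 1)
  count <- rowSums(membership)
  specific <- count <= max_sharing_fraction * n_ct + 1e-9
  units <- granges_to_peaks(consensus)
  units$n_shared <- as.integer(count)
  out <- lapply(seq_len(n_ct), function(j) {
    keep <- specific & membership[, j]
    arrange(units[keep, ], .data$chrom, .data$start)
  })
  names(out) <- names(peaksets)
  out
}

#' Annotate variants with a regulatory annotation (0/1), optionally via LD proxies
#'
#' The indicator is 1 iff the variant's position -- or the position of any
#' supplied LD proxy -- falls inside an annotation interval under the
#' half-open test (`start <= pos < end`).  Variants on chromosomes absent
#' from the annotation get 0.
#'
#' @param stats Summary-statistics tibble (needs `variant_id`, `chrom`,
#'   `pos`).
#' @param annotation Peak tibble (`chrom`, `start`, `end`).
#' @param proxies Optional named list: variant id -> character vector of
#'   proxy variant ids (r^2 > 0.8 partners); proxies must be present in
#'   `stats` to contribute a position.
#' @return Integer 0/1 vector aligned with `stats` rows.
#' @export
annotate_variants <- function(stats, annotation, proxies = NULL) {
  if (!nrow(annotation)) return(integer(nrow(stats)))
  direct <- variants_in_intervals(stats, annotation)
  hit <- direct
  if (!is.null(proxies) && length(proxies)) {
    hit_ids <- stats$variant_id[direct]
    # A variant is also annotated when any of its proxies overlaps.
    prox_hit <- vapply(stats$variant_id, function(id) {
      pr <- proxies[[id]]
      !is.null(pr) && any(pr %in% hit_ids)
    }, logical(1))
    hit <- hit | prox_hit
  }
  as.integer(hit)
}

#' Build an annotation matrix over several annotations
#'
#' @param stats Summary-statistics tibble.
#' @param annotations Named list of peak tibbles.
#' @param proxies As in [annotate_variants()].
#' @return Tibble: `variant_id` plus one 0/1 column per annotation, column
#'   order following `annotations`.
#' @export
build_annotation_matrix <- function(stats, annotations, proxies = NULL) {
  cols <- lapply(annotations, function(a) annotate_variants(stats, a, proxies))
  dplyr::bind_cols(tibble(variant_id = stats$variant_id), as_tibble(cols))
}

#' Count LD proxies of each variant
#'
#' The number of distinct other variants with `r^2 > threshold`, one of
#' the matched confounders in the enrichment model.
#'
#' @param ld An [ld_ref()].
#' @param threshold r-squared threshold (default 0.8, strict inequality).
#' @param variant_ids Variants to report (default: all in `ld`).
#' @return Named integer vector of proxy counts.
#' @export
count_ld_proxies <- function(ld, threshold = 0.8, variant_ids = NULL) {
  stopifnot(inherits(ld, "ld_ref"))
  ids <- variant_ids %||% ld$variant_id
  adj <- ld_adjacency(ld, threshold)
  counts <- vapply(adj, function(x) length(unique(x)), integer(1))
  out <- setNames(integer(length(ids)), ids)
  common <- intersect(ids, names(counts))
  out[common] <- counts[common]
  out
}

#' LD-proxy map at a threshold
#'
#' @inheritParams count_ld_proxies
#' @return Named list: variant id -> character vector of proxies with
#'   `r^2 > threshold`.
#' @export
ld_proxy_map <- function(ld, threshold = 0.8) {
  stopifnot(inherits(ld, "ld_ref"))
  ld_adjacency(ld, threshold)
}
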