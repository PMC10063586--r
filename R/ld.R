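#' Sparse pairwise LD reference
#'
#' The package represents LD as a sparse list of signed pairwise
#' correlations: pairs absent from the table are treated as r = 0.  This
#' matches both the block-diagonal synthetic LD and the small hand-set
#' matrices used in fixtures.  Pruning, clumping and proxy counting consume
#' `r^2`; the gene-level statistic consumes `r^2` as well, so the stored
#' sign only matters for simulation.
#'
#' @param pairs Tibble with columns `id1`, `id2`, `r` (signed correlation);
#'   each unordered pair at most once, self-pairs ignored.
#' @param variant_ids Character vector fixing the variant universe/order.
#' @return An object of class `ld_ref`.
#' @export
ld_ref <- function(pairs, variant_ids) {
  pairs <- as_tibble(pairs)
  need <- setdiff(c("id1", "id2", "r"), names(pairs))
  if (length(need)) abort(paste("`pairs` missing column(s):", paste(need, collapse = ", ")))
  pairs <- filter(pairs, .data$id1 != .data$id2)
  if (any(abs(pairs$r) > 1 + 1e-9)) abort("LD correlations must lie in [-1, 1].")
  bad <- setdiff(c(pairs$id1, pairs$id2), variant_ids)
  if (length(bad)) {
    abort(sprintf("LD pairs reference unknown variants: %s",
                  paste(utils::head(bad, 3), collapse = ", ")))
  }
  # Canonical order within pair, dedup keeping the first occurrence.
  swap <- match(pairs$id1, variant_ids) > match(pairs$id2, variant_ids)
  tmp <- pairs$id1[swap]
  pairs$id1[swap] <- pairs$id2[swap]
  pairs$id2[swap] <- tmp
  pairs <- distinct(pairs, .data$id1, .data$id2, .keep_all = TRUE)
  structure(list(variant_id = variant_ids, pairs = pairs), class = "ld_ref")
}

#' @export
print.ld_ref <- function(x, ...) {
  cat(sprintf("<ld_ref> %d variants, %d non-zero pairs\n",
              length(x$variant_id), nrow(x$pairs)))
  invisible(x)
}

#' Flatten a genome model's block LD into an `ld_ref`
#'
#' @param genome A [generate_genome()] result.
#' @return An [ld_ref()] with one row per non-zero within-block pair.
#' @export
ld_from_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  id1 <- vector("list", length(genome$block_r))
  id2 <- vector("list", length(genome$block_r))
  rr <- vector("list", length(genome$block_r))
  for (b in seq_along(genome$block_r)) {
    R <- genome$block_r[[b]]
    k <- nrow(R)
    if (k < 2) next
    ut <- upper.tri(R) & R != 0
    if (!any(ut)) next
    rows <- row(R)[ut]; cols <- col(R)[ut]
    id1[[b]] <- rownames(R)[rows]
    id2[[b]] <- colnames(R)[cols]
    rr[[b]] <- R[ut]
  }
  pairs <- tibble(id1 = unlist(id1) %||% character(),
                  id2 = unlist(id2) %||% character(),
                  r = unlist(rr) %||% numeric())
  ld_ref(pairs, genome$variants$variant_id)
}

#' Build an `ld_ref` from a dense signed correlation matrix
#'
#' @param R Square matrix with dimnames giving variant ids.
#' @return An [ld_ref()].
#' @export
ld_from_matrix <- function(R) {
  if (is.null(rownames(R))) abort("`R` needs variant ids as dimnames.")
  ut <- which(upper.tri(R) & R != 0, arr.ind = TRUE)
  pairs <- tibble(id1 = rownames(R)[ut[, 1]], id2 = colnames(R)[ut[, 2]],
                  r = R[ut])
  ld_ref(pairs, rownames(R))
}

# Adjacency list over pairs with r^2 > r2_min: named list variant -> character
# vector of partners.  Variants with no qualifying partner are absent.
ld_adjacency <- function(ld, r2_min) {
  keep <- ld$pairs$r^2 > r2_min
  if (!any(keep)) return(list())
  p <- ld$pairs[keep, ]
  ids <- c(p$id1, p$id2)
  partners <- c(p$id2, p$id1)
  split(partners, ids)
}

# Dense signed correlation submatrix for the given variant ids (absent
# pairs are 0, diagonal 1).
ld_submatrix <- function(ld, ids) {
  k <- length(ids)
  R <- diag(k)
  dimnames(R) <- list(ids, ids)
  p <- filter(ld$pairs, .data$id1 %in% ids & .data$id2 %in% ids)
  if (nrow(p)) {
    i <- match(p$id1, ids); j <- match(p$id2, ids)
    R[cbind(i, j)] <- p$r
    R[cbind(j, i)] <- p$r
  }
  R
}
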