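# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join inner_join anti_join distinct pull n row_number
#'   rename relocate across if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm qnorm dnorm rnorm runif rbinom pchisq quantile
#'   glm glm.fit lm binomial coef vcov sd var cor complete.cases
#'   logLik model.matrix p.adjust setNames ks.test cor.test
NULL

# Half-open [start, end) interval tibbles are the package-wide convention
# (0-based, BED-style).  A point at bp `pos` hits [start, end) iff
# start <= pos < end.
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# Points (0-based bp) as width-1 IRanges for overlap queries.
points_iranges0 <- function(pos) {
  IRanges::IRanges(start = pos + 1L, width = 1L)
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = as_iranges0(peaks$start, peaks$end)
  )
}

points_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom, ranges = points_iranges0(pos))
}

granges_to_peaks <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Standardize to mean 0, sd 1; errors on zero variance when strict.
standardize <- function(x, what = "variable") {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort(sprintf("Cannot standardize zero-variance %s.", what))
  }
  (x - mean(x)) / s
}

# Quantile bins with collapsing when there are fewer distinct cut points
# than requested bins; ties share a bin.
quantile_bin <- function(x, n_bins, label = "feature") {
  stopifnot(n_bins >= 1)
  brk <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                         names = FALSE, type = 7))
  if (length(brk) - 1 < n_bins) {
    warn(sprintf("Fewer distinct values than bins for %s; bins collapsed to %d.",
                 label, max(1L, length(brk) - 1L)))
  }
  if (length(brk) < 2) {
    return(rep.int(1L, length(x)))
  }
  as.integer(cut(x, breaks = brk, include.lowest = TRUE, labels = FALSE))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Deterministic child seeds below 2^31 derived from a user seed.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}
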