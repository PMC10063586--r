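#' Read a BED3+ peak file
#'
#' Intervals are kept in the package-wide 0-based half-open convention,
#' exactly as BED stores them.  Output is sorted by chromosome then start.
#'
#' @param path Path to a tab-delimited BED file with >= 3 columns.
#' @param chr_prefix Normalize chromosome names to carry a `"chr"` prefix
#'   (default TRUE; set FALSE to strip it instead).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path, chr_prefix = TRUE) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED parse error at line %d: fewer than 3 columns.",
                  which(nf < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad)) {
    abort(sprintf("BED parse error at line %d: non-numeric coordinates.", bad[1]))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    abort(sprintf("BED parse error at line %d: start >= end.", bad[1]))
  }
  out <- tibble(chrom = normalize_chrom(chrom, chr_prefix),
                start = as.integer(start), end = as.integer(end))
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write a peak tibble as BED3
#'
#' @param peaks Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  readr::write_tsv(peaks[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a BEDPE loop file
#'
#' Each record has two anchors; both are 0-based half-open intervals.  A
#' seventh column, when present, is kept as the loop score.
#'
#' @param path Path to a tab-delimited BEDPE file with >= 6 columns.
#' @param allow_trans Keep records whose anchors sit on different
#'   chromosomes (default FALSE: such records raise an error naming the
#'   record number).
#' @param chr_prefix As in [read_bed()].
#' @return Tibble with `chrom1`, `start1`, `end1`, `chrom2`, `start2`,
#'   `end2`, `score`.
#' @export
read_bedpe <- function(path, allow_trans = FALSE, chr_prefix = TRUE) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble(chrom1 = character(), start1 = integer(), end1 = integer(),
                  chrom2 = character(), start2 = integer(), end2 = integer(),
                  score = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(sprintf("BEDPE parse error at record %d: fewer than 6 columns.",
                  which(nf < 6)[1]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(col(i)))
    bad <- which(!is.finite(x))
    if (length(bad)) {
      abort(sprintf("BEDPE parse error at record %d: non-numeric %s.", bad[1], what))
    }
    x
  }
  out <- tibble(
    chrom1 = normalize_chrom(col(1), chr_prefix),
    start1 = as.integer(num(2, "start1")), end1 = as.integer(num(3, "end1")),
    chrom2 = normalize_chrom(col(4), chr_prefix),
    start2 = as.integer(num(5, "start2")), end2 = as.integer(num(6, "end2")),
    score = if (all(nf >= 7)) suppressWarnings(as.numeric(col(7))) else NA_real_
  )
  bad <- which(out$start1 >= out$end1 | out$start2 >= out$end2)
  if (length(bad)) {
    abort(sprintf("BEDPE parse error at record %d: start >= end.", bad[1]))
  }
  if (!allow_trans) {
    tr <- which(out$chrom1 != out$chrom2)
    if (length(tr)) {
      abort(sprintf(
        "Trans interaction at record %d; pass `allow_trans = TRUE` to keep trans records.",
        tr[1]))
    }
  }
  out
}

#' Write loops as BEDPE
#'
#' @param loops Tibble as returned by [read_bedpe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  out <- loops[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")]
  if ("score" %in% names(loops) && !all(is.na(loops$score))) {
    out$score <- loops$score
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

normalize_chrom <- function(chrom, chr_prefix = TRUE) {
  bare <- sub("^chr", "", chrom)
  if (chr_prefix) paste0("chr", bare) else bare
}
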