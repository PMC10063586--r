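#' Simulate enhancer-promoter chromatin loops
#'
#' Each loop connects a promoter-side anchor (an interval spanning a
#' randomly chosen isoform TSS and its promoter window) to a distal
#' anchor centred on a randomly chosen variant elsewhere on the same
#' chromosome, emulating promoter-capture interaction records.  Loops are
#' cis by construction.
#'
#' @param genome A [generate_genome()] result with genes.
#' @param n_loops Number of loops.
#' @param anchor_width Width of each anchor in bp.
#' @param target_genes Optional gene ids to bias loop targets toward (all
#'   loops use these genes when supplied).
#' @param distal `"intergenic"` (default) centres the distal anchor on
#'   variants outside every exon and promoter, the typical location of an
#'   enhancer anchor; `"any"` allows any variant.
#' @param seed Integer seed.
#' @return A loop tibble (`chrom1`, `start1`, `end1`, `chrom2`, `start2`,
#'   `end2`, `score`).
#' @export
generate_loops <- function(genome, n_loops, anchor_width = 2000,
                           target_genes = NULL,
                           distal = c("intergenic", "any"), seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  distal <- match.arg(distal)
  if (is.null(genome$genes)) abort("Genome has no gene models.")
  set.seed(as.integer(seed))
  iso <- genome$genes$isoforms
  if (!is.null(target_genes)) {
    iso <- filter(iso, .data$gene_id %in% target_genes)
    if (!nrow(iso)) abort("No isoforms for the requested target genes.")
  }
  half <- as.integer(anchor_width) %/% 2L
  pick_iso <- iso[sample.int(nrow(iso), n_loops, replace = TRUE), ]
  v <- genome$variants
  ok_distal <- rep(TRUE, nrow(v))
  if (distal == "intergenic") {
    # keep the distal anchor clear of every exon/promoter so its variants
    # are genic only through the loop being simulated
    feats <- bind_rows(
      select(genome$genes$exons, "chrom", "start", "end"),
      select(promoter_windows(genome$genes), "chrom", "start", "end")
    )
    feats <- mutate(feats, start = .data$start - as.integer(half),
                    end = .data$end + as.integer(half))
    ok_distal <- !variants_in_intervals(v, feats)
    if (!any(ok_distal)) ok_distal <- rep(TRUE, nrow(v))
  }
  rows <- purrr::map_dfr(seq_len(n_loops), function(i) {
    tss <- pick_iso$tss[i]
    ch <- pick_iso$chrom[i]
    a1 <- c(max(tss - half, 0L), tss + half)
    cand <- which(v$chrom == ch & abs(v$pos - tss) > anchor_width * 2 &
                    ok_distal)
    if (!length(cand)) cand <- which(v$chrom == ch)
    vp <- v$pos[sample(cand, 1)]
    a2 <- c(max(vp - half, 0L), vp + half)
    tibble(chrom1 = ch, start1 = as.integer(a1[1]), end1 = as.integer(a1[2]),
           chrom2 = ch, start2 = as.integer(a2[1]), end2 = as.integer(a2[2]),
           score = round(runif(1, 1, 100), 2))
  })
  rows
}

#' Simulate a binary outcome driven by a score
#'
#' Bernoulli outcome with `logit P = qlogis(base_rate) +
#' log_odds_per_sd * standardized score`, used to plant relapse-style
#' outcomes.
#'
#' @param score Numeric vector.
#' @param log_odds_per_sd Planted log-odds per SD of score.
#' @param base_rate Outcome probability at the mean score.
#' @param seed Integer seed.
#' @return Integer 0/1 vector.
#' @export
simulate_binary_outcome <- function(score, log_odds_per_sd, base_rate = 0.3,
                                    seed = 1L) {
  check_scalar_number(base_rate, "base_rate", lower = 1e-9, upper = 1 - 1e-9)
  set.seed(as.integer(seed))
  s <- standardize(score, "score")
  rbinom(length(s), 1, stats::plogis(stats::qlogis(base_rate) +
                                       log_odds_per_sd * s))
}
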