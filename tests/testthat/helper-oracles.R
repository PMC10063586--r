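# Independent brute-force oracles.  Each one re-derives the quantity a
# package function computes, by the most literal method available, and is
# deliberately kept free of package internals.

# Does a point hit any half-open interval?  Plain double loop.
oracle_point_in_intervals <- function(chrom, pos, intervals) {
  hit <- logical(length(pos))
  for (i in seq_along(pos)) {
    for (j in seq_len(nrow(intervals))) {
      if (chrom[i] == intervals$chrom[j] &&
          pos[i] >= intervals$start[j] && pos[i] < intervals$end[j]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

# Greedy pruning in ascending p order, quadratic scan.
oracle_greedy_prune <- function(p, pos, chrom, R2, r2_thr, window_bp) {
  n <- length(p)
  ord <- order(p, seq_len(n))
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (j in kept) {
      if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= window_bp &&
          R2[i, j] > r2_thr) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) kept <- c(kept, i)
  }
  sort(kept)
}

# Benjamini-Hochberg step-up q-values from first principles.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  q[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  pmin(q, 1)
}

# Closed-form 2x2 odds ratio from counts (a = exposed cases etc.).
oracle_or_2x2 <- function(n11, n10, n01, n00) {
  (n11 * n00) / (n10 * n01)
}

# Weighted-dosage score by explicit double loop.
oracle_prs <- function(D, w) {
  n <- nrow(D)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(ncol(D))) s <- s + w[j] * D[i, j]
    out[i] <- s
  }
  out
}

# OLS coefficients from the normal equations.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# A small random genome + LD fixture used across oracle tests.
random_small_fixture <- function(n = 30, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(5e5, n))
  R <- diag(n)
  # sprinkle random LD among nearby variants
  for (k in seq_len(3 * n)) {
    ij <- sort(sample.int(n, 2))
    if (abs(pos[ij[1]] - pos[ij[2]]) < 2e5) {
      r <- runif(1, -1, 1)
      R[ij[1], ij[2]] <- r
      R[ij[2], ij[1]] <- r
    }
  }
  ids <- sprintf("v%03d", seq_len(n))
  dimnames(R) <- list(ids, ids)
  stats <- tibble::tibble(
    variant_id = ids, chrom = "chr1", pos = pos,
    effect_allele = "A", other_allele = "G",
    beta = rnorm(n, 0, 0.05), se = 0.05,
    p = runif(n), maf = runif(n, 0.05, 0.5), info = 1
  )
  list(stats = stats, R = R, ld = cellrisk::ld_from_matrix(R))
}

# Small gene models fixture with known promoter/exon geometry.
toy_genes <- function() {
  gene_models(
    genes = tibble::tibble(
      gene_id = c("Gp", "Gm", "Gnc"), chrom = "chr1",
      strand = c("+", "-", "+"),
      biotype = c("protein_coding", "protein_coding", "other")
    ),
    isoforms = tibble::tibble(
      gene_id = c("Gp", "Gm", "Gnc"),
      transcript_id = c("Gp.1", "Gm.1", "Gnc.1"),
      chrom = "chr1", strand = c("+", "-", "+"),
      tss = c(10000L, 50000L, 90000L)
    ),
    exons = tibble::tibble(
      gene_id = c("Gp", "Gm", "Gnc"),
      transcript_id = c("Gp.1", "Gm.1", "Gnc.1"),
      chrom = "chr1",
      start = c(10000L, 48000L, 90000L),
      end = c(11000L, 50001L, 90500L)
    )
  )
}

# Plant equal-effect causal variants (one per LD block, or a sample of
# them) scaled so the genetic liability variance is h2 under independent
# standardized dosages.
plant_truth_on_variants <- function(genome, h2, K,
                                    phenotype_effects = numeric(),
                                    n_causal = NULL, seed = 1) {
  set.seed(seed)
  v <- genome$variants
  picks <- vapply(split(seq_len(nrow(v)), v$block), function(ix) ix[1],
                  integer(1))
  if (!is.null(n_causal)) picks <- sample(picks, min(n_causal, length(picks)))
  b <- sqrt(h2 / length(picks))
  synthetic_truth(
    causal_variants = stats::setNames(rep(b, length(picks)),
                                      v$variant_id[picks]),
    h2 = h2, K = K, phenotype_effects = phenotype_effects
  )
}
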