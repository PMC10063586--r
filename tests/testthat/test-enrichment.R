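test_that("greedy pruning matches the independent greedy oracle", {
  # trivial: no LD keeps everything
  fx <- random_small_fixture(n = 20, seed = 1)
  ld0 <- ld_ref(tibble::tibble(id1 = character(), id2 = character(),
                               r = numeric()), fx$stats$variant_id)
  expect_equal(prune_variants(fx$stats, ld0)$variant_id,
               fx$stats$variant_id)

  # two perfect proxies: only the smaller-p one kept
  st <- tibble::tibble(variant_id = c("a", "b"), chrom = "chr1",
                       pos = c(100L, 200L), p = c(0.2, 0.01))
  R <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(prune_variants(st, ld_from_matrix(R))$variant_id, "b")

  # hand-set 5-variant fixture
  st5 <- tibble::tibble(
    variant_id = letters[1:5], chrom = "chr1",
    pos = c(100L, 500L, 900L, 700000L, 700100L),
    p = c(0.5, 0.01, 0.3, 0.2, 0.05)
  )
  R5 <- diag(5)
  R5[1, 2] <- R5[2, 1] <- 0.6   # a-b conflict
  R5[2, 3] <- R5[3, 2] <- 0.05  # b-c below default threshold? (0.0025 r2)
  R5[4, 5] <- R5[5, 4] <- 0.9   # d-e conflict
  R5[1, 4] <- R5[4, 1] <- 0.9   # a-d: far apart (window blocks it)
  dimnames(R5) <- list(st5$variant_id, st5$variant_id)
  got <- prune_variants(st5, ld_from_matrix(R5), 0.01, 500)
  want <- oracle_greedy_prune(st5$p, st5$pos, st5$chrom, R5^2, 0.01, 5e5)
  expect_equal(got$variant_id, st5$variant_id[want])

  # randomized fixtures, both parameter sets (prune and clump defaults)
  for (seed in 1:25) {
    fx <- random_small_fixture(n = 30, seed = seed)
    for (par in list(c(0.01, 500), c(0.1, 250))) {
      got <- prune_variants(fx$stats, fx$ld, par[1], par[2])
      want <- oracle_greedy_prune(fx$stats$p, fx$stats$pos, fx$stats$chrom,
                                  fx$R^2, par[1], par[2] * 1000)
      expect_equal(got$variant_id, fx$stats$variant_id[want])
    }
  }
})

test_that("pruned sets are maximal under the conflict rule", {
  for (seed in 1:5) {
    fx <- random_small_fixture(n = 30, seed = seed)
    kept <- prune_variants(fx$stats, fx$ld)$variant_id
    dropped <- setdiff(fx$stats$variant_id, kept)
    idx <- match(kept, fx$stats$variant_id)
    for (d in dropped) {
      i <- match(d, fx$stats$variant_id)
      conf <- any(fx$R[i, idx]^2 > 0.01 &
                    abs(fx$stats$pos[idx] - fx$stats$pos[i]) <= 5e5)
      expect_true(conf)
    }
  }
})

test_that("confounder binning produces quantile bins with tie collapsing", {
  g <- generate_genome(100, block_size = 1, seed = 2)
  s <- generate_gwas(g, synthetic_truth(), 1e4, seed = 3)
  genes <- toy_genes()
  ld <- ld_from_genome(g)

  # 100 distinct uniform MAFs -> 20 per bin
  s$maf <- seq(0.05, 0.5, length.out = 100)
  suppressWarnings(bins <- bin_confounders(s, genes, ld, n_bins = 5))
  expect_equal(unname(table(bins$maf_bin)), rep(20L, 5),
               ignore_attr = TRUE)

  # all MAFs identical -> single bin, with a warning
  s$maf <- rep(0.2, 100)
  w <- capture_warnings(bins <- bin_confounders(s, genes, ld, n_bins = 5))
  expect_true(any(grepl("MAF", w)))
  expect_equal(unique(bins$maf_bin), 1L)

  # a variant exactly at a TSS has distance 0 and the lowest bin
  s2 <- s
  s2$pos[1] <- 10000L  # TSS of Gp
  suppressWarnings(b2 <- bin_confounders(s2, genes, ld))
  expect_equal(b2$tss_distance[1], 0)
  expect_equal(b2$tss_bin[1], min(b2$tss_bin))
})

test_that("enrichment regression reduces to the closed-form 2x2 odds ratio", {
  # counts: sig&annot 30, sig&not 70, nonsig&annot 10, nonsig&not 90
  y <- c(rep(1, 100), rep(0, 100))
  annot <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  pr <- tibble::tibble(p = ifelse(y == 1, 1e-6, 0.5))
  r <- test_enrichment(pr, annot, threshold = 1e-5)
  expect_equal(r$or, oracle_or_2x2(30, 70, 10, 90), tolerance = 1e-6)
  expect_equal(r$or, 270 / 70, tolerance = 1e-6)
  expect_equal(r$status, "ok")
  expect_equal(r$n_significant, 100)
  expect_equal(r$n_annotated, 40)

  # randomized 2x2 fixtures to >= 6 significant digits
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(40:80, 4, replace = TRUE)  # n11 n10 n01 n00
    y <- c(rep(1, n[1] + n[2]), rep(0, n[3] + n[4]))
    annot <- c(rep(1, n[1]), rep(0, n[2]), rep(1, n[3]), rep(0, n[4]))
    pr <- tibble::tibble(p = ifelse(y == 1, 1e-6, 0.5))
    r <- test_enrichment(pr, annot, 1e-5)
    expect_equal(r$or, oracle_or_2x2(n[1], n[2], n[3], n[4]),
                 tolerance = 1e-6)
    # with single-level bins the estimate must be unchanged
    bins1 <- tibble::tibble(maf_bin = 1, tss_bin = 1, ldprox_bin = 1)
    bins1 <- bins1[rep(1, length(y)), ]
    r1 <- test_enrichment(pr, annot, 1e-5, bins1)
    expect_equal(r1$or, r$or, tolerance = 1e-6)
  }
})

test_that("enrichment estimate is invariant to confounder bin relabeling", {
  set.seed(11)
  n <- 400
  pr <- tibble::tibble(p = runif(n))
  annot <- rbinom(n, 1, 0.3)
  bins <- tibble::tibble(
    maf_bin = sample(1:4, n, TRUE),
    tss_bin = sample(1:4, n, TRUE),
    ldprox_bin = sample(1:2, n, TRUE)
  )
  r1 <- test_enrichment(pr, annot, 0.1, bins)
  relab <- dplyr::mutate(bins, maf_bin = 5 - maf_bin,
                         tss_bin = c(9, 2, 7, 4)[tss_bin])
  r2 <- test_enrichment(pr, annot, 0.1, relab)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
  expect_equal(r1$se, r2$se, tolerance = 1e-8)
})

test_that("degenerate enrichment cells are flagged rather than estimated", {
  pr <- tibble::tibble(p = runif(50, 0.2, 1))
  annot <- rbinom(50, 1, 0.5)
  r <- test_enrichment(pr, annot, 1e-5)   # no significant variants
  expect_equal(r$status, "untestable")
  expect_true(is.na(r$estimate))

  # complete separation: all significant variants annotated, none outside
  y_sig <- c(rep(1, 10), rep(0, 40))
  annot2 <- c(rep(1, 10), rep(0, 40))
  pr2 <- tibble::tibble(p = ifelse(y_sig == 1, 1e-8, 0.6))
  r2 <- test_enrichment(pr2, annot2, 1e-5)
  expect_equal(r2$status, "penalized")
  expect_true(is.finite(r2$estimate) && is.finite(r2$se))
})

test_that("independent annotation gives a near-zero estimate", {
  set.seed(3)
  n <- 5000
  pr <- tibble::tibble(p = runif(n))
  annot <- rbinom(n, 1, 0.3)
  r <- test_enrichment(pr, annot, 0.05)
  expect_lt(abs(r$estimate), 3 * r$se)
})

test_that("effective annotation number collapses duplicate columns", {
  set.seed(4)
  base <- rbinom(300, 1, 0.4)
  M <- cbind(a = base, b = base, c = base, d = base, e = base)
  expect_equal(effective_n_annotations(M), 1L)
  M2 <- cbind(M, f = rbinom(300, 1, 0.4), g = rbinom(300, 1, 0.4))
  n_eff <- effective_n_annotations(M2)
  expect_gte(n_eff, 3L)
  expect_lte(n_eff, 3L)
})

test_that("the scan grid is complete and correction behaves at the edges", {
  g <- generate_genome(600, block_size = 3, n_genes = 20, seed = 6)
  ld <- ld_from_genome(g)
  s <- generate_gwas(g, synthetic_truth(), 1e4, seed = 7)
  a <- generate_annotations(g, 3, sharing = "unique", n_peaks = 150, seed = 8)
  suppressWarnings(
    scan <- run_enrichment_scan(s, a$peaks, ld, g$genes,
                                thresholds = c(0.05, 1e-3, 1e-8))
  )
  expect_equal(nrow(scan), 3 * 3)
  expect_true(all(scan$n_significant <= scan$n_pruned))
  # at T = 1e-8 a null scan has no significant variants -> untestable
  expect_true(all(scan$status[scan$threshold == 1e-8] == "untestable"))

  # one annotation, one threshold: correction is the identity on p
  suppressWarnings(
    scan1 <- run_enrichment_scan(s, a$peaks[1], ld, g$genes,
                                 thresholds = 0.05)
  )
  expect_equal(attr(scan1, "n_eff"), 1L)
  expect_equal(scan1$significant_after_correction, scan1$p < 0.05)
})
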