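make_cohort_fixture <- function(n = 40, m = 12, seed = 1) {
  g <- generate_genome(m, block_size = 3, seed = seed)
  tr <- plant_truth_on_variants(g, h2 = 0.3, K = 0.2, seed = seed + 1)
  co <- generate_cohort(g, tr, n_individuals = n, seed = seed + 2)
  list(genome = g, truth = tr, cohort = co,
       stats = generate_gwas(g, tr, 1e4, seed = seed + 3))
}

test_that("variant QC applies the published thresholds exactly", {
  fx <- make_cohort_fixture()
  st <- fx$stats
  st$info <- 1; st$maf <- pmax(st$maf, 0.05)
  st$info[1] <- 0.5       # INFO < 0.6 -> removed
  st$info[2] <- 0.6       # boundary: kept
  st$maf[3] <- 0.005      # MAF < 1% -> removed
  co <- fx$cohort
  co$dosages[1:20, st$variant_id[4]] <- NA  # 50% missing -> removed
  # force an HWE failure: all heterozygotes
  co$dosages[, st$variant_id[5]] <- 1
  qc <- qc_filter(st, co)
  gone <- setdiff(st$variant_id, qc$stats$variant_id)
  expect_setequal(gone, st$variant_id[c(1, 3, 4, 5)])
  expect_true(st$variant_id[2] %in% qc$stats$variant_id)
  expect_false(any(gone %in% colnames(qc$cohort$dosages)))
})

test_that("kinship filtering removes exactly one of each related pair", {
  fx <- make_cohort_fixture(n = 10)
  ids <- rownames(fx$cohort$dosages)
  kin <- tibble::tibble(id1 = ids[c(1, 3)], id2 = ids[c(2, 4)],
                        kinship = c(0.09, 0.05))
  qc <- qc_filter(fx$stats, fx$cohort, kinship = kin)
  kept <- rownames(qc$cohort$dosages)
  # pair above 0.0844 loses one member; pair below keeps both
  expect_equal(sum(ids[1:2] %in% kept), 1)
  expect_true(all(ids[3:4] %in% kept))
  # ties in completeness resolve by id order (first kept)
  expect_true(ids[1] %in% kept)
})

test_that("scoring universes follow the set algebra of annotations", {
  anns <- list(
    b = tibble::tibble(gene_id = "G", variant_id = c("a", "b", "c"),
                       route = "exonic"),
    m = tibble::tibble(gene_id = "G", variant_id = c("b", "c", "d"),
                       route = "exonic"),
    g = tibble::tibble(gene_id = "G", variant_id = c("e"), route = "exonic")
  )
  expect_setequal(restrict_universe(anns, "b", "all"), c("a", "b", "c"))
  expect_setequal(restrict_universe(anns, "b", "unique"), "a")
  expect_setequal(restrict_universe(anns, mode = "combined"),
                  c("a", "b", "c", "d", "e"))
  # identical annotations -> empty unique set errors out explicitly
  same <- list(b = anns$b, m = anns$b)
  expect_error(restrict_universe(same, "b", "unique"), "Empty")
  # disjoint annotations -> unique equals all
  disj <- list(b = anns$b, g = anns$g)
  expect_setequal(restrict_universe(disj, "g", "unique"),
                  restrict_universe(disj, "g", "all"))
  # unique universes of different cell types are always disjoint
  for (seed in 1:5) {
    set.seed(seed)
    rnd <- lapply(1:3, function(i) {
      tibble::tibble(gene_id = "G", route = "exonic",
                     variant_id = sample(letters, sample(8:15, 1)))
    })
    names(rnd) <- c("b", "m", "g")
    uniqs <- lapply(names(rnd), function(ct) {
      tryCatch(restrict_universe(rnd, ct, "unique"), error = function(e) character())
    })
    expect_equal(length(intersect(uniqs[[1]], uniqs[[2]])), 0)
    expect_equal(length(intersect(uniqs[[1]], uniqs[[3]])), 0)
  }
})

test_that("clumping keeps independent effects at the scoring defaults", {
  st <- tibble::tibble(variant_id = c("a", "b"), chrom = "chr1",
                       pos = c(100L, 200L), p = c(0.3, 0.01))
  R <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(clump_variants(st, ld_from_matrix(R))$variant_id, "b")
  # 8-variant fixture against the greedy oracle at r2 = 0.1 / 250 kb
  for (seed in 1:10) {
    fx <- random_small_fixture(n = 8, seed = seed + 50)
    got <- clump_variants(fx$stats, fx$ld)
    want <- oracle_greedy_prune(fx$stats$p, fx$stats$pos, fx$stats$chrom,
                                fx$R^2, 0.1, 2.5e5)
    expect_equal(got$variant_id, fx$stats$variant_id[want])
  }
})

test_that("PRS computation is the exact weighted dosage sum", {
  # direct arithmetic: weights (0.2, -0.1), dosages (2, 1) -> 0.3
  co <- list(
    dosages = matrix(c(2, 1), 1, 2,
                     dimnames = list("i1", c("v1", "v2"))),
    variants = tibble::tibble(variant_id = c("v1", "v2"),
                              effect_allele = c("A", "C"),
                              other_allele = c("G", "T"))
  )
  m <- score_model(tibble::tibble(
    variant_id = c("v1", "v2"), effect_allele = c("A", "C"),
    other_allele = c("G", "T"), beta = c(0.2, -0.1), maf = c(0.1, 0.2)
  ))
  expect_equal(compute_prs(co, m)$score, 0.3)

  # zero weights -> zero scores
  m0 <- score_model(dplyr::mutate(m$variants, beta = 0))
  expect_equal(compute_prs(co, m0)$score, 0)

  # random 50 x 20 matrix equals the double-loop oracle; linearity holds
  set.seed(8)
  D <- matrix(sample(0:2, 1000, TRUE), 50, 20,
              dimnames = list(sprintf("i%02d", 1:50), sprintf("v%02d", 1:20)))
  vars <- tibble::tibble(variant_id = colnames(D), effect_allele = "A",
                         other_allele = "G")
  w1 <- rnorm(20); w2 <- rnorm(20)
  mk <- function(w) score_model(dplyr::mutate(vars, beta = w, maf = 0.2))
  co2 <- list(dosages = D, variants = vars)
  s1 <- compute_prs(co2, mk(w1))$score
  expect_equal(s1, oracle_prs(D, w1))
  s12 <- compute_prs(co2, mk(w1 + w2))$score
  expect_equal(s12, s1 + compute_prs(co2, mk(w2))$score, tolerance = 1e-12)
})

test_that("allele flips and missing dosages are handled as documented", {
  set.seed(9)
  D <- matrix(sample(0:2, 60, TRUE), 10, 6,
              dimnames = list(sprintf("i%d", 1:10), sprintf("v%d", 1:6)))
  vars <- tibble::tibble(variant_id = colnames(D),
                         effect_allele = c("A", "C", "G", "T", "A", "C"),
                         other_allele = c("G", "T", "A", "C", "G", "T"))
  co <- list(dosages = D, variants = vars)
  w <- rnorm(6)
  m <- score_model(dplyr::mutate(vars, beta = w, maf = 0.2))
  base <- compute_prs(co, m)$score

  # a panel that counts the other allele (dosages reflected, alleles
  # swapped) yields exactly the same scores under the same model
  panel_swap <- vars
  panel_swap$effect_allele <- vars$other_allele
  panel_swap$other_allele <- vars$effect_allele
  co_swap <- list(dosages = 2 - D, variants = panel_swap)
  expect_equal(compute_prs(co_swap, m)$score, base, tolerance = 1e-12)

  # swapping the model's alleles with sign-flipped weight shifts every
  # score by the same constant (w*d vs -w*(2-d) differ by 2w per variant)
  flip <- vars
  flip$effect_allele[2] <- vars$other_allele[2]
  flip$other_allele[2] <- vars$effect_allele[2]
  mflip <- score_model(dplyr::mutate(flip, beta = w * c(1, -1, 1, 1, 1, 1),
                                     maf = 0.2))
  flipped <- compute_prs(co, mflip)$score
  expect_equal(flipped - base, rep(-2 * w[2], 10), tolerance = 1e-12)

  # irreconcilable alleles raise a named error
  bad <- vars; bad$effect_allele[3] <- "T"; bad$other_allele[3] <- "C"
  mbad <- score_model(dplyr::mutate(bad, beta = w, maf = 0.2))
  expect_error(compute_prs(co, mbad), "v3")

  # missing dosages impute to 2 * MAF
  D2 <- D; D2[1, 1] <- NA
  co2 <- list(dosages = D2, variants = vars)
  m2 <- score_model(dplyr::mutate(vars, beta = w, maf = 0.25))
  got <- compute_prs(co2, m2)$score
  want <- compute_prs(list(dosages = `[<-`(D, 1, 1, 0.5), variants = vars),
                      m2)$score
  expect_equal(got, want)
})

test_that("threshold optimization picks planted signal and breaks ties low", {
  # identical performance at all thresholds (no variants between cuts)
  st <- tibble::tibble(variant_id = c("v1", "v2"), chrom = "chr1",
                       pos = c(1L, 2L), effect_allele = "A",
                       other_allele = "G", beta = c(0.5, 0.2),
                       se = 0.1, p = c(1e-10, 1e-9), maf = 0.3, info = 1)
  set.seed(10)
  D <- matrix(sample(0:2, 400, TRUE), 200, 2,
              dimnames = list(sprintf("i%03d", 1:200), c("v1", "v2")))
  co <- list(dosages = D,
             variants = tibble::tibble(variant_id = c("v1", "v2"),
                                       effect_allele = "A",
                                       other_allele = "G"),
             samples = tibble::tibble(status = rbinom(200, 1, 0.3)))
  opt <- optimize_threshold(st, co, thresholds = c(5e-8, 0.05, 1))
  # all thresholds select both variants -> identical r2 -> smallest returned
  expect_equal(opt$model$p_threshold, 5e-8)
  expect_equal(nrow(opt$path), 3)

  # single threshold supplied -> returned trivially
  opt1 <- optimize_threshold(st, co, thresholds = 0.5)
  expect_equal(opt1$model$p_threshold, 0.5)

  # thresholds selecting nothing are skipped with a warning
  st2 <- dplyr::mutate(st, p = c(0.04, 0.3))
  expect_warning(opt2 <- optimize_threshold(st2, co,
                                            thresholds = c(5e-8, 0.05, 1)),
                 "skipped")
  expect_true(opt2$model$p_threshold %in% c(0.05, 1))
})

test_that("score evaluation behaves at the null and separating extremes", {
  set.seed(11)
  status <- rbinom(10000, 1, 0.5)
  score <- rnorm(10000)
  ev <- evaluate_scores(score, status, K = 0.01)
  expect_lt(abs(ev$auc - 0.5), 0.02)
  expect_lt(ev$r2_liab, 0.005)

  # perfectly separating score
  sep_score <- status + runif(10000, 0, 0.5)
  expect_equal(evaluate_scores(sep_score, status, K = 0.01)$auc, 1)

  # AUC agrees with pROC as an independent implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    s <- rnorm(500); y <- rbinom(500, 1, plogis(s))
    ev2 <- evaluate_scores(s, y, K = 0.1)
    expect_equal(ev2$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-10)
  }

  expect_error(evaluate_scores(rnorm(10), rep(1, 10)), "classes")
})

test_that("the liability transformation is monotone, zero at zero, and validated", {
  expect_equal(liability_r2(0, K = 0.01, P = 0.5), 0)
  r2s <- seq(0, 0.3, by = 0.01)
  out <- vapply(r2s, liability_r2, numeric(1), K = 0.01, P = 0.5)
  expect_true(all(diff(out) > 0))

  # latent-liability oracle: planted 3% of liability variance, K = 0.01,
  # ascertained 50/50 -> recovered within ±0.01 (averaged over replicates)
  est <- vapply(1:5, function(i) {
    d <- simulate_liability_scores(4000, 4000, r2_liab = 0.03, K = 0.01,
                                   seed = 700 + i)
    evaluate_scores(d$score, d$status, K = 0.01)$r2_liab
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.03), 0.01)
})

test_that("stratum odds ratios match the 2x2 closed form and flag reference", {
  # covariate-free two-stratum case: (20, 80) vs reference (10, 90)
  status <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  score <- c(runif(100, 10, 11), runif(100, 1, 2))  # top vs bottom half
  out <- stratify_or(score, status, breaks = c(0, 0.5, 1))
  top <- out[!out$reference, ]
  expect_equal(top$or, oracle_or_2x2(20, 80, 10, 90), tolerance = 1e-6)
  expect_equal(top$or, 2.25, tolerance = 1e-6)
  expect_equal(out$n, c(100L, 100L))
  expect_equal(out$n_cases[out$reference], 10L)

  # null score: all ORs within 3 SE of 1
  set.seed(13)
  status <- rbinom(20000, 1, 0.3)
  score <- rnorm(20000)
  nulls <- stratify_or(score, status)
  est <- nulls[!nulls$reference, ]
  expect_true(all(abs(est$estimate) < 3 * est$se))
  expect_equal(sum(nulls$reference), 1)
  expect_equal(nulls$q_lo[nulls$reference], 0.4)
})

test_that("MHC exclusion respects its half-open bounds", {
  st <- tibble::tibble(
    variant_id = sprintf("v%d", 1:5),
    chrom = c("chr6", "chr6", "chr6", "chr6", "chr7"),
    pos = c(30e6, 10e6, 25e6, 35e6, 30e6)
  )
  out <- exclude_mhc(st)
  expect_setequal(out$variant_id, c("v2", "v4", "v5"))  # 35 Mb boundary kept
  expect_false("v3" %in% out$variant_id)                # 25 Mb boundary removed
})
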