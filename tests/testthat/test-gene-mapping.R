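test_that("promoter windows are strand-aware with exact 2-kb boundaries", {
  genes <- toy_genes()
  st <- tibble::tibble(
    variant_id = sprintf("v%d", 1:6), chrom = "chr1",
    # + strand TSS 10000: 9999 in, 8000 in (edge), 7999 out, 10000 not promoter
    # - strand TSS 50000: 50500 in, 52001 out
    pos = c(9999L, 8000L, 7999L, 10000L, 50500L, 52001L)
  )
  ann <- build_location_annotation(st, genes)
  prom <- ann[ann$route == "promoter", ]
  expect_setequal(prom$variant_id[prom$gene_id == "Gp"], c("v1", "v2"))
  expect_false("v3" %in% prom$variant_id)
  expect_false("v4" %in% prom$variant_id)   # at the TSS itself (exonic instead)
  expect_true("v4" %in% ann$variant_id[ann$route == "exonic"])
  # - strand: upstream means increasing coordinates
  gm_prom <- prom$variant_id[prom$gene_id == "Gm"]
  expect_true("v5" %in% gm_prom)
  expect_false("v6" %in% gm_prom)
  # independent strand-flip arithmetic oracle over a position grid
  tss <- 50000L
  grid <- tibble::tibble(variant_id = sprintf("g%d", 1:200), chrom = "chr1",
                         pos = seq(tss - 100L, by = 11L, length.out = 200))
  got <- build_location_annotation(grid, genes)
  got_gm <- sort(got$variant_id[got$gene_id == "Gm" & got$route == "promoter"])
  want <- sort(grid$variant_id[grid$pos - tss >= 1 & grid$pos - tss <= 2000])
  expect_equal(got_gm, want)
})

test_that("interaction annotation equals the brute-force triple loop", {
  genes <- toy_genes()
  # variant in anchor2, anchor1 overlapping Gp's promoter
  st <- tibble::tibble(variant_id = c("a", "b"), chrom = "chr1",
                       pos = c(200000L, 300000L))
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = c(9500L, 70000L), end1 = c(9800L, 71000L),
    chrom2 = "chr1", start2 = c(199900L, 299900L), end2 = c(200100L, 300100L),
    score = NA_real_
  )
  ia <- build_interaction_annotation(st, genes, loops)
  expect_equal(ia$variant_id[ia$gene_id == "Gp"], "a")
  # partner anchor of loop 2 overlaps no exon/promoter -> no assignment
  expect_false("b" %in% ia$variant_id)

  # randomized triple-loop oracle
  for (seed in 1:10) {
    set.seed(seed)
    g <- generate_genome(200, block_size = 2, n_genes = 12, seed = seed)
    st <- generate_gwas(g, synthetic_truth(), 1e4, seed = seed + 100)
    loops <- generate_loops(g, n_loops = 15, seed = seed + 200)
    got <- build_interaction_annotation(st, g$genes, loops)
    feats <- dplyr::bind_rows(
      dplyr::select(g$genes$exons, gene_id, chrom, start, end),
      cellrisk:::promoter_windows(g$genes)
    )
    want <- list()
    for (li in seq_len(nrow(loops))) {
      for (fi in seq_len(nrow(feats))) {
        for (vi in seq_len(nrow(st))) {
          a1f <- loops$start1[li] < feats$end[fi] &&
            feats$start[fi] < loops$end1[li]
          a2f <- loops$start2[li] < feats$end[fi] &&
            feats$start[fi] < loops$end2[li]
          v1 <- st$pos[vi] >= loops$start1[li] && st$pos[vi] < loops$end1[li]
          v2 <- st$pos[vi] >= loops$start2[li] && st$pos[vi] < loops$end2[li]
          if ((a1f && v2) || (a2f && v1)) {
            want[[length(want) + 1]] <- paste(feats$gene_id[fi],
                                              st$variant_id[vi])
          }
        }
      }
    }
    expect_setequal(paste(got$gene_id, got$variant_id), unique(unlist(want)))
  }
})

test_that("annotation merging is a route-tagged set union", {
  loc <- tibble::tibble(gene_id = c("G1", "G1", "G2"),
                        variant_id = c("a", "b", "c"),
                        route = c("exonic", "promoter", "exonic"))
  ia <- tibble::tibble(gene_id = c("G1", "G3"), variant_id = c("b", "d"),
                       route = "interaction")
  m <- merge_annotations(loc, ia)
  # disjoint gene-variant pairs add; duplicates collapse per route
  pairs <- unique(paste(m$gene_id, m$variant_id))
  expect_equal(length(pairs), 4)
  expect_setequal(m$route[m$gene_id == "G1" & m$variant_id == "b"],
                  c("promoter", "interaction"))
  # idempotence
  expect_equal(merge_annotations(loc, loc), loc)
  # inclusion-exclusion on random sets
  for (seed in 1:10) {
    set.seed(seed)
    A <- tibble::tibble(gene_id = "G", route = "exonic",
                        variant_id = sample(letters, 10))
    B <- tibble::tibble(gene_id = "G", route = "exonic",
                        variant_id = sample(letters, 12))
    m <- merge_annotations(A, B)
    expect_equal(nrow(m), length(union(A$variant_id, B$variant_id)))
    expect_equal(nrow(m),
                 nrow(A) + nrow(B) -
                   length(intersect(A$variant_id, B$variant_id)))
  }
})

test_that("gene statistic reduces to closed forms for k = 1 and independence", {
  st <- tibble::tibble(variant_id = c("a", "b", "c"), chrom = "chr1",
                       pos = c(1L, 2L, 3L), p = c(0.02, 0.4, 0.9))
  ld0 <- ld_ref(tibble::tibble(id1 = character(), id2 = character(),
                               r = numeric()), st$variant_id)
  # one-SNP gene: gene p equals the SNP p
  ann1 <- tibble::tibble(gene_id = "G1", variant_id = "a", route = "exonic")
  r1 <- gene_level_test(st, ann1, ld0)
  expect_equal(r1$p, 0.02, tolerance = 1e-12)

  # k independent SNPs: exact chi-square(k) survival of sum z^2
  annk <- tibble::tibble(gene_id = "Gk", variant_id = c("a", "b", "c"),
                         route = "exonic")
  rk <- gene_level_test(st, annk, ld0)
  z2 <- qnorm(1 - st$p / 2)^2
  expect_equal(rk$p, pchisq(sum(z2), df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(rk$statistic, sum(z2))

  # exact and Brown nulls agree closely for moderate LD
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.4
  dimnames(R) <- list(st$variant_id, st$variant_id)
  ld <- ld_from_matrix(R)
  re <- gene_level_test(st, annk, ld, method = "exact")
  rb <- gene_level_test(st, annk, ld, method = "brown")
  expect_equal(re$p, rb$p, tolerance = 0.05)
})

test_that("gene p-values are null-uniform without and with LD", {
  # without LD
  g0 <- generate_genome(4000, block_size = 1, n_genes = 400, seed = 21)
  s0 <- generate_gwas(g0, synthetic_truth(), 5e4, seed = 22)
  r0 <- gene_level_test(s0, build_location_annotation(s0, g0$genes),
                        ld_from_genome(g0), g0$genes)
  expect_gt(ks.test(r0$p, "punif")$p.value, 0.01)

  # with strong exchangeable within-block LD (r2 = 0.5)
  g1 <- generate_genome(4000, block_size = 5, r2_profile = "exchangeable",
                        r2_within = 0.5, n_genes = 400, seed = 23)
  s1 <- generate_gwas(g1, synthetic_truth(), 5e4, seed = 24)
  r1 <- gene_level_test(s1, build_location_annotation(s1, g1$genes),
                        ld_from_genome(g1), g1$genes)
  expect_gt(ks.test(r1$p, "punif")$p.value, 0.01)
})

test_that("interaction assignments lower the p of a causal gene on average", {
  # paired simulation: the same stats scored with and without a loop that
  # routes causal variants into the gene
  g <- generate_genome(300, block_size = 3, n_genes = 10, seed = 31)
  ld <- ld_from_genome(g)
  target <- g$genes$genes$gene_id[1]
  # a loop connecting the target's promoter to a causal anchor far away
  iso <- g$genes$isoforms[g$genes$isoforms$gene_id == target, ][1, ]
  anchor_var <- g$variants[250, ]
  loops <- tibble::tibble(
    chrom1 = iso$chrom, start1 = iso$tss - 500L, end1 = iso$tss + 500L,
    chrom2 = anchor_var$chrom, start2 = anchor_var$pos - 500L,
    end2 = anchor_var$pos + 500L, score = NA_real_
  )
  tr <- synthetic_truth(
    causal_variants = setNames(0.15, anchor_var$variant_id), h2 = 0.1)
  diffs <- vapply(1:20, function(i) {
    s <- generate_gwas(g, tr, 5e4, seed = 400 + i)
    loc <- build_location_annotation(s, g$genes)
    p0 <- gene_level_test(s, loc, ld, g$genes)
    p1 <- gene_level_test(s, merge_annotations(
      loc, build_interaction_annotation(s, g$genes, loops)), ld, g$genes)
    log(p1$p[p1$gene_id == target]) - log(p0$p[p0$gene_id == target])
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})

test_that("FDR filtering follows hand-computed BH and the biotype rule", {
  res <- tibble::tibble(
    gene_id = c("G1", "G2", "G3"),
    biotype = "protein_coding",
    n_snps = 1L, statistic = 1, p = c(0.001, 0.2, 0.3),
    null_method = "chisq"
  )
  out <- fdr_filter(res)
  expect_equal(out$q, c(0.003, 0.3, 0.3))
  expect_equal(sum(out$risk), 1)
  expect_equal(out$gene_id[out$risk], "G1")

  # all p = 1 -> empty risk set
  res$p <- 1
  expect_equal(sum(fdr_filter(res)$risk), 0)

  # non-protein-coding gene with tiny p is excluded from the risk set
  res2 <- res
  res2$p <- c(1e-10, 0.5, 0.5)
  res2$biotype <- c("other", "protein_coding", "protein_coding")
  out2 <- fdr_filter(res2)
  expect_false(out2$risk[1])
  expect_true(out2$gene_id[1] %in% out2$gene_id)  # still reported

  # random vectors against the oracle
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(50)
    res3 <- tibble::tibble(gene_id = sprintf("g%02d", 1:50),
                           biotype = "protein_coding", n_snps = 1L,
                           statistic = 1, p = p, null_method = "chisq")
    expect_equal(fdr_filter(res3)$q, oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("gene-set comparison partitions match inclusion-exclusion", {
  sets <- list(b = c("x", "y", "z"), m = c("x", "y", "z"),
               g = c("x", "y", "z"))
  cmp <- compare_gene_sets(sets)
  expect_equal(cmp$shared, c("x", "y", "z"))
  expect_true(all(lengths(cmp$unique) == 0))

  sets2 <- list(b = c("a", "b"), m = c("c"), g = c("d", "e"))
  cmp2 <- compare_gene_sets(sets2)
  expect_equal(length(cmp2$shared), 0)
  expect_equal(cmp2$unique$b, c("a", "b"))
  expect_equal(cmp2$unique$g, c("d", "e"))

  for (seed in 1:10) {
    set.seed(seed)
    sets3 <- list(b = sample(letters, 12), m = sample(letters, 10),
                  g = sample(letters, 14))
    cmp3 <- compare_gene_sets(sets3)
    expect_setequal(cmp3$shared,
                    intersect(intersect(sets3$b, sets3$m), sets3$g))
    expect_setequal(cmp3$unique$m, setdiff(sets3$m, union(sets3$b, sets3$g)))
    ov <- cmp3$pairwise
    expect_equal(ov$n_overlap[ov$set1 == "b" & ov$set2 == "m"],
                 length(intersect(sets3$b, sets3$m)))
  }
})
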