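#' Variant and individual quality control for scoring
#'
#' Variant rules: imputation `info < info_min`, `maf < maf_min`, dosage
#' missingness above `missing_max`, Hardy-Weinberg deviation below
#' `hwe_p_min` (1-df chi-square on genotype counts from rounded dosages).
#' Individual rule: for each related pair with kinship above
#' `kinship_max`, the member with lower genotyping completeness is
#' removed (ties broken by id sort order, keeping the first).
#'
#' @param stats Summary-statistics tibble (`info`, `maf` used).
#' @param cohort A [generate_cohort()] result (or compatible list).
#' @param kinship Optional tibble `id1`, `id2`, `kinship` of related pairs.
#' @param info_min,maf_min,missing_max,hwe_p_min,kinship_max Thresholds;
#'   defaults 0.6, 0.01, 0.1, 1e-6, 0.0844.
#' @return List: `stats` (filtered), `cohort` (filtered), `removed` (tibble
#'   of per-rule removal counts).
#' @export
qc_filter <- function(stats, cohort, kinship = NULL,
                      info_min = 0.6, maf_min = 0.01, missing_max = 0.1,
                      hwe_p_min = 1e-6, kinship_max = 0.0844) {
  D <- cohort$dosages
  in_matrix <- stats$variant_id %in% colnames(D)

  fail_info <- stats$info < info_min
  fail_maf <- stats$maf < maf_min
  miss_frac <- rep(0, nrow(stats))
  hwe_p <- rep(1, nrow(stats))
  if (any(in_matrix)) {
    cols <- match(stats$variant_id[in_matrix], colnames(D))
    miss_frac[in_matrix] <- colMeans(is.na(D[, cols, drop = FALSE]))
    hwe_p[in_matrix] <- apply(D[, cols, drop = FALSE], 2, hwe_test_p)
  }
  fail_miss <- miss_frac > missing_max
  fail_hwe <- hwe_p < hwe_p_min
  keep_var <- !(fail_info | fail_maf | fail_miss | fail_hwe)

  drop_ind <- character(0)
  if (!is.null(kinship) && nrow(kinship)) {
    completeness <- 1 - rowMeans(is.na(D))
    rel <- filter(kinship, .data$kinship > kinship_max)
    present <- rownames(D)
    for (i in seq_len(nrow(rel))) {
      a <- rel$id1[i]; b <- rel$id2[i]
      if (a %in% drop_ind || b %in% drop_ind) next
      if (!(a %in% present) || !(b %in% present)) next
      ca <- completeness[[a]]; cb <- completeness[[b]]
      victim <- if (ca > cb) b else if (cb > ca) a else sort(c(a, b))[2]
      drop_ind <- c(drop_ind, victim)
    }
  }

  keep_ind <- !(rownames(D) %in% drop_ind)
  keep_cols <- colnames(D) %in% stats$variant_id[keep_var]
  cohort_out <- cohort
  cohort_out$dosages <- D[keep_ind, keep_cols, drop = FALSE]
  cohort_out$samples <- cohort$samples[keep_ind, ]

  list(
    stats = stats[keep_var, ],
    cohort = cohort_out,
    removed = tibble(
      rule = c("info", "maf", "missingness", "hwe", "kinship"),
      n_removed = c(sum(fail_info), sum(fail_maf & !fail_info),
                    sum(fail_miss & !fail_info & !fail_maf),
                    sum(fail_hwe & !fail_info & !fail_maf & !fail_miss),
                    length(drop_ind))
    )
  )
}

# 1-df Hardy-Weinberg chi-square on genotype counts (dosages rounded to
# the nearest genotype); returns the upper-tail p.
hwe_test_p <- function(d) {
  g <- round(d[!is.na(d)])
  n <- length(g)
  if (n == 0) return(1)
  n2 <- sum(g == 2); n1 <- sum(g == 1); n0 <- n - n1 - n2
  p <- (n1 + 2 * n2) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((c(n0, n1, n2) - e)^2 / e)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Restrict the scoring universe to a cell type's annotated variants
#'
#' @param annotations Named list of gene-SNP annotation tibbles, one per
#'   cell type.
#' @param cell_type Cell type for modes `"all"`/`"unique"`.
#' @param mode `"all"` (every variant annotated to any gene in the cell
#'   type), `"unique"` (that set minus the union of all other cell
#'   types'), or `"combined"` (union over all cell types).
#' @return Character vector of variant ids.
#' @export
restrict_universe <- function(annotations, cell_type = NULL,
                              mode = c("all", "unique", "combined")) {
  mode <- match.arg(mode)
  if (is.null(names(annotations))) abort("`annotations` must be named by cell type.")
  var_sets <- lapply(annotations, function(a) unique(a$variant_id))
  out <- switch(mode,
    combined = Reduce(union, var_sets),
    all = {
      if (is.null(cell_type)) abort("`cell_type` required for mode 'all'.")
      var_sets[[cell_type]]
    },
    unique = {
      if (is.null(cell_type)) abort("`cell_type` required for mode 'unique'.")
      others <- var_sets[setdiff(names(var_sets), cell_type)]
      setdiff(var_sets[[cell_type]], Reduce(union, others))
    }
  )
  if (!length(out)) {
    abort(sprintf("Empty variant universe for cell type '%s' (mode '%s').",
                  cell_type %||% "<combined>", mode))
  }
  sort(out)
}

#' LD clumping for score construction
#'
#' Identical greedy contract to [prune_variants()] with the scoring
#' defaults: `r^2` 0.1 within a 250-kb window, keeping the most
#' significant representative of each clump.
#'
#' @inheritParams prune_variants
#' @export
clump_variants <- function(stats, ld, r2_threshold = 0.1, window_kb = 250) {
  prune_variants(stats, ld, r2_threshold = r2_threshold,
                 window_kb = window_kb)
}

#' Build a polygenic score model from selected variants
#'
#' @param stats Summary statistics restricted to the selected (clumped)
#'   variants; weights are the per-variant effect sizes for the effect
#'   allele.
#' @param p_threshold Selection p-value threshold recorded on the model.
#' @param cell_type,universe,mhc_excluded Metadata labels.
#' @return An object of class `score_model`.
#' @export
score_model <- function(stats, p_threshold = 1, cell_type = NA_character_,
                        universe = c("all_cell_snps", "unique_cell_snps",
                                     "combined"),
                        mhc_excluded = FALSE) {
  universe <- match.arg(universe)
  if (!all(is.finite(stats$beta))) abort("Score weights must be finite.")
  structure(
    list(
      variants = select(stats, "variant_id", "effect_allele", "other_allele",
                        "beta", "maf"),
      p_threshold = p_threshold,
      cell_type = cell_type, universe = universe,
      mhc_excluded = mhc_excluded
    ),
    class = "score_model"
  )
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model> %d variants, p < %g, cell type %s (%s)%s\n",
              nrow(x$variants), x$p_threshold, x$cell_type, x$universe,
              if (x$mhc_excluded) ", MHC excluded" else ""))
  invisible(x)
}

#' Compute polygenic scores as a weighted effect-allele dosage sum
#'
#' `score_j = sum_i w_i * d_ij` over the model variants.  When a model
#' variant's effect/other alleles are swapped relative to the dosage
#' panel, the dosage is reflected (`2 - d`) so the score is unchanged;
#' irreconcilable alleles raise an error listing the variants.  Missing
#' dosages are mean-imputed to `2 * MAF` from the model's allele
#' frequency.
#'
#' @param cohort A [generate_cohort()] result or any list with `dosages`
#'   (individuals x variants) and `variants` (tibble with `variant_id`,
#'   `effect_allele`, `other_allele`).
#' @param model A [score_model()].
#' @return Tibble: `sample_id`, `score`.
#' @export
compute_prs <- function(cohort, model) {
  stopifnot(inherits(model, "score_model"))
  D <- cohort$dosages
  panel <- cohort$variants
  mv <- model$variants
  missing_var <- setdiff(mv$variant_id, colnames(D))
  if (length(missing_var)) {
    abort(sprintf("Model variants absent from dosage matrix: %s",
                  paste(utils::head(missing_var, 5), collapse = ", ")))
  }
  pv <- panel[match(mv$variant_id, panel$variant_id), ]
  same <- pv$effect_allele == mv$effect_allele &
    pv$other_allele == mv$other_allele
  swapped <- pv$effect_allele == mv$other_allele &
    pv$other_allele == mv$effect_allele
  bad <- !(same | swapped)
  if (any(bad)) {
    abort(sprintf("Allele mismatch for variant(s): %s",
                  paste(utils::head(mv$variant_id[bad], 5), collapse = ", ")))
  }
  Dm <- D[, mv$variant_id, drop = FALSE]
  if (anyNA(Dm)) {
    imput <- rep(2 * mv$maf, each = nrow(Dm))
    Dm[is.na(Dm)] <- imput[is.na(Dm)]
  }
  if (any(swapped)) {
    Dm[, swapped] <- 2 - Dm[, swapped, drop = FALSE]
  }
  tibble(sample_id = rownames(D), score = unname(drop(Dm %*% mv$beta)))
}

#' Optimize the score p-value threshold on a validation cohort
#'
#' For each threshold, builds a score from the clumped variants with
#' `p < threshold`, computes scores on the validation cohort and records
#' the incremental Nagelkerke R^2 of `status ~ covariates + score` over
#' the covariates-only model.  Returns the best model; ties go to the
#' smaller threshold.  Thresholds that select no variants are skipped
#' with a warning.
#'
#' @param clumped Clumped summary-statistics tibble
#'   ([clump_variants()] output restricted to the scoring universe).
#' @param cohort Validation cohort with binary `status` in
#'   `cohort$samples`.
#' @param covariates Character vector of covariate column names in
#'   `cohort$samples` (e.g. ancestry PCs).
#' @param thresholds Candidate p-value thresholds (default the standard
#'   13-point grid 5e-8 ... 1).
#' @param ... Metadata passed to [score_model()].
#' @return List: `model` (best [score_model()]), `path` (tibble:
#'   `threshold`, `n_snps`, `r2_obs`).
#' @export
optimize_threshold <- function(clumped, cohort, covariates = character(),
                               thresholds = c(5e-08, 5e-07, 5e-06, 5e-05,
                                              0.0005, 0.005, 0.05, 0.1, 0.2,
                                              0.3, 0.4, 0.5, 1),
                               ...) {
  thresholds <- sort(thresholds)
  status <- cohort$samples$status
  covar <- as.data.frame(cohort$samples[, covariates, drop = FALSE])
  best <- NULL; best_r2 <- -Inf
  path <- list()
  for (T in thresholds) {
    sel <- filter(clumped, .data$p < T)
    if (!nrow(sel)) {
      warn(sprintf("No variants at threshold %g; skipped.", T))
      next
    }
    m <- score_model(sel, p_threshold = T, ...)
    sc <- compute_prs(cohort, m)$score
    r2 <- incremental_nagelkerke(status, covar, sc)
    path[[length(path) + 1L]] <- tibble(threshold = T, n_snps = nrow(sel),
                                        r2_obs = r2)
    if (r2 > best_r2) {   # strict: ties keep the earlier, smaller threshold
      best_r2 <- r2; best <- m
    }
  }
  if (is.null(best)) abort("No threshold selected any variants.")
  list(model = best, path = bind_rows(path))
}

# Incremental Nagelkerke R^2 of adding `score` to a covariates-only
# logistic model (each Nagelkerke measured against the intercept-only
# model, PRS-tool convention).
incremental_nagelkerke <- function(status, covar, score = NULL) {
  df <- data.frame(status = status, covar)
  ll_null <- as.numeric(logLik(glm(status ~ 1, data = df, family = binomial())))
  # separation in the full model is legitimate at evaluation extremes

  n <- length(status)
  nag <- function(fit) {
    ll <- as.numeric(logLik(fit))
    cs <- 1 - exp(2 * (ll_null - ll) / n)
    cs / (1 - exp(2 * ll_null / n))
  }
  f0 <- if (ncol(covar)) {
    suppressWarnings(glm(status ~ ., data = df, family = binomial()))
  } else {
    glm(status ~ 1, data = df, family = binomial())
  }
  if (is.null(score)) return(nag(f0))
  df$score <- score
  f1 <- suppressWarnings(glm(status ~ ., data = df, family = binomial()))
  nag(f1) - nag(f0)
}

# Incremental linear (observed 0/1 scale) R^2 -- the scale on which the
# liability transformation is derived.
incremental_linear_r2 <- function(status, covar, score) {
  df <- data.frame(status = status, covar)
  r2_0 <- if (ncol(covar)) summary(lm(status ~ ., data = df))$r.squared else 0
  df$score <- score
  r2_1 <- summary(lm(status ~ ., data = df))$r.squared
  max(r2_1 - r2_0, 0)
}

#' Transform an observed-scale R^2 to the liability scale
#'
#' Lee-style transformation for an ascertained case-control sample with
#' sample case proportion `P` and population prevalence `K`:
#' `R2_liab = C * R2_obs / (1 + C * theta * R2_obs)` where
#' `C = K^2 (1-K)^2 / (z^2 P (1-P))` with `z` the standard-normal
#' density at the prevalence quantile `t = qnorm(1 - K)`, and
#' `theta = a * (a - t)` with `a = (z / K) * (P - K) / (1 - K)` the
#' ascertainment correction.  `R2_obs` is the observed-scale (linear,
#' 0/1 outcome) incremental R^2.  The map is monotone increasing in
#' `R2_obs` and 0 at 0; it is validated against the latent-liability
#' simulation oracle in the test suite.
#'
#' @param r2_obs Observed-scale incremental R^2.
#' @param K Population prevalence.
#' @param P Sample case proportion.
#' @return Liability-scale R^2.
#' @export
liability_r2 <- function(r2_obs, K, P) {
  check_scalar_number(K, "K", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar_number(P, "P", lower = 1e-12, upper = 1 - 1e-12)
  t <- qnorm(1 - K)
  z <- dnorm(t)
  C <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  a <- (z / K) * (P - K) / (1 - K)
  theta <- a * (a - t)
  max(C * r2_obs / (1 + C * theta * r2_obs), 0)
}

#' Evaluate a polygenic score against case/control status
#'
#' Reports the incremental Nagelkerke R^2 of
#' `status ~ covariates + score` over covariates-only (the observed R^2),
#' the liability-scale R^2 (prevalence-corrected via [liability_r2()]
#' applied to the observed-scale linear R^2), the score-only AUC
#' (Mann-Whitney), and the two-sided Wald p of the score coefficient.
#'
#' @param scores Tibble from [compute_prs()] (or numeric vector).
#' @param status Binary 0/1 vector, both classes present.
#' @param covariates Optional data frame of covariates.
#' @param K Population prevalence for the liability correction (default
#'   0.00127).
#' @return An object of class `cprs_result`.
#' @export
evaluate_scores <- function(scores, status, covariates = NULL, K = 0.00127) {
  score <- if (is.data.frame(scores)) scores$score else scores
  status <- as.integer(status)
  if (length(unique(status)) < 2) abort("Both case and control classes are required.")
  covar <- if (is.null(covariates)) {
    data.frame(row.names = seq_along(status))
  } else {
    as.data.frame(covariates)
  }
  r2_obs <- incremental_nagelkerke(status, covar, score)
  r2_lin <- incremental_linear_r2(status, covar, score)
  P <- mean(status)
  df <- data.frame(status = status, covar, score = score)
  # a perfectly separating score is a legitimate extreme here (AUC = 1);
  # the fitted-probability warnings carry no information
  fit <- suppressWarnings(glm(status ~ ., data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  p_assoc <- sm["score", "Pr(>|z|)"]

  structure(
    list(
      r2_obs = r2_obs,
      r2_liab = liability_r2(r2_lin, K, P),
      auc = auc_mann_whitney(score, status),
      p = p_assoc,
      beta = unname(coef(fit)["score"]),
      n = length(status), n_cases = sum(status), K = K, P = P
    ),
    class = "cprs_result"
  )
}

# Exact Mann-Whitney AUC of a score for cases vs controls.
auc_mann_whitney <- function(score, status) {
  r <- rank(score)
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.cprs_result <- function(x, ...) {
  cat(sprintf(
    "<cprs_result> n = %d (%d cases)  R2_obs = %.4f  R2_liab = %.4f  AUC = %.3f  p = %.3g\n",
    x$n, x$n_cases, x$r2_obs, x$r2_liab, x$auc, x$p))
  invisible(x)
}

#' Odds ratios across score strata
#'
#' Individuals are cut into score-quantile strata (default: bottom 5%,
#' 15%/20%/20%/20%/15% bands, top 5%); status is regressed on the stratum
#' factor plus covariates with the median-containing stratum as
#' reference, giving a per-stratum log-odds ratio and SE.
#'
#' @param scores [compute_prs()] tibble or numeric vector.
#' @param status Binary 0/1 vector.
#' @param covariates Optional data frame.
#' @param breaks Increasing quantile break points covering \[0, 1\].
#' @return Tibble of class `or_strata`: `stratum`, `q_lo`, `q_hi`, `n`,
#'   `n_cases`, `estimate`, `se`, `or`, `p`, `reference`.
#' @export
stratify_or <- function(scores, status, covariates = NULL,
                        breaks = c(0, 0.05, 0.2, 0.4, 0.6, 0.8, 0.95, 1)) {
  score <- if (is.data.frame(scores)) scores$score else scores
  status <- as.integer(status)
  if (is.unsorted(breaks) || breaks[1] != 0 || breaks[length(breaks)] != 1) {
    abort("`breaks` must increase from 0 to 1.")
  }
  qs <- quantile(score, probs = breaks, names = FALSE, type = 7)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  stratum <- cut(score, breaks = qs, labels = FALSE, include.lowest = TRUE)
  # Reference stratum: the one whose quantile interval (q_lo, q_hi]
  # contains the median; when 0.5 is itself a break the lower stratum is
  # the reference.
  ref <- findInterval(0.5, breaks, left.open = TRUE)
  counts <- table(factor(stratum, levels = seq_len(length(breaks) - 1)))
  if (any(counts == 0)) {
    warn(sprintf("%d empty stratum(a) dropped.", sum(counts == 0)))
  }
  f <- stats::relevel(factor(stratum), ref = as.character(ref))
  df <- data.frame(status = status, stratum = f)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- glm(status ~ ., data = df, family = binomial())
  sm <- summary(fit)$coefficients
  rows <- purrr::map_dfr(sort(unique(stratum)), function(s) {
    nm <- paste0("stratum", s)
    is_ref <- s == ref
    in_s <- stratum == s
    est <- if (is_ref) 0 else unname(sm[nm, "Estimate"])
    se <- if (is_ref) NA_real_ else unname(sm[nm, "Std. Error"])
    tibble(
      stratum = s, q_lo = breaks[s], q_hi = breaks[s + 1],
      n = sum(in_s), n_cases = sum(status[in_s]),
      estimate = est, se = se, or = exp(est),
      p = if (is_ref) NA_real_ else unname(sm[nm, "Pr(>|z|)"]),
      reference = is_ref
    )
  })
  structure(rows, class = c("or_strata", class(rows)))
}

#' Exclude the extended MHC region
#'
#' Removes variants inside the extended major histocompatibility complex,
#' by default chr6:25,000,000-35,000,000 (GRCh37, half-open).
#'
#' @param stats Tibble with `chrom` and `pos`.
#' @param chrom,start,end Region bounds.
#' @return `stats` without the MHC variants.
#' @export
exclude_mhc <- function(stats, chrom = "chr6", start = 25e6, end = 35e6) {
  filter(stats, !(.data$chrom == !!chrom & .data$pos >= start & .data$pos < end))
}
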