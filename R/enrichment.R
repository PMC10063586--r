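#' Greedy LD pruning of GWAS variants
#'
#' Variants are visited in ascending GWAS p order (most significant
#' first); a variant is kept iff no already-kept variant within
#' `window_kb` on the same chromosome has `r^2 > r2_threshold` with it.
#' Pairs absent from the LD reference are treated as r^2 = 0.  The result
#' is maximal under this rule: every dropped variant conflicts with a kept
#' one.
#'
#' @param stats Summary-statistics tibble (`variant_id`, `chrom`, `pos`,
#'   `p`, ...).
#' @param ld An [ld_ref()].
#' @param r2_threshold r-squared above which two variants conflict
#'   (default 0.01, the enrichment-scan setting; [clump_variants()] uses
#'   0.1).
#' @param window_kb Window half-width in kb (default 500, i.e. a 1-Mb
#'   window around each variant).
#' @return The kept subset of `stats`, in the input row order.
#' @export
prune_variants <- function(stats, ld, r2_threshold = 0.01, window_kb = 500) {
  stopifnot(inherits(ld, "ld_ref"))
  n <- nrow(stats)
  ord <- order(stats$p, seq_len(n))
  window_bp <- window_kb * 1000

  # Integer-indexed conflict adjacency restricted to variants in `stats`.
  row_of <- match(ld$pairs$id1, stats$variant_id)
  col_of <- match(ld$pairs$id2, stats$variant_id)
  keep_pair <- ld$pairs$r^2 > r2_threshold & !is.na(row_of) & !is.na(col_of)
  i1 <- c(row_of[keep_pair], col_of[keep_pair])
  i2 <- c(col_of[keep_pair], row_of[keep_pair])
  adj <- split(i2, factor(i1, levels = seq_len(n)))

  kept <- logical(n)
  for (i in ord) {
    nb <- adj[[i]]
    conflict <- length(nb) &&
      any(kept[nb] & stats$chrom[nb] == stats$chrom[i] &
            abs(stats$pos[nb] - stats$pos[i]) <= window_bp)
    if (!conflict) kept[i] <- TRUE
  }
  stats[kept, ]
}

#' Quantile-bin the enrichment confounders
#'
#' Bins the three matched confounders of the enrichment model: minor
#' allele frequency, distance to the nearest transcription start site
#' (minimum over all isoform TSSs of `|pos - tss|`), and the number of LD
#' proxies at `r^2 > 0.8`.  Bins are quantile bins; when a feature has
#' fewer distinct values than bins the bins collapse with a warning.
#'
#' @param pruned Pruned summary-statistics tibble.
#' @param genes A [gene_models()] object (non-empty TSS set).
#' @param ld An [ld_ref()].
#' @param n_bins Bins per feature (default 5).
#' @return Tibble: `variant_id`, `maf_bin`, `tss_bin`, `ldprox_bin`
#'   (integer bin codes), plus the raw `tss_distance` and `n_proxies`.
#' @export
bin_confounders <- function(pruned, genes, ld, n_bins = 5) {
  stopifnot(inherits(genes, "gene_models"), inherits(ld, "ld_ref"))
  if (!nrow(genes$isoforms)) abort("Gene models carry no isoform TSSs.")
  tss_dist <- nearest_tss_distance(pruned, genes)
  n_prox <- count_ld_proxies(ld, 0.8, pruned$variant_id)
  tibble(
    variant_id = pruned$variant_id,
    tss_distance = tss_dist,
    n_proxies = as.integer(n_prox[pruned$variant_id]),
    maf_bin = quantile_bin(pruned$maf, n_bins, "MAF"),
    tss_bin = quantile_bin(tss_dist, n_bins, "TSS distance"),
    ldprox_bin = quantile_bin(as.integer(n_prox[pruned$variant_id]), n_bins,
                              "LD proxy count")
  )
}

# Distance to the nearest isoform TSS on the variant's chromosome.
# Variants on chromosomes without any TSS get one more than the largest
# finite distance so they land in the top bin.
nearest_tss_distance <- function(stats, genes) {
  out <- rep(NA_real_, nrow(stats))
  for (ch in unique(stats$chrom)) {
    idx <- which(stats$chrom == ch)
    tss <- sort(genes$isoforms$tss[genes$isoforms$chrom == ch])
    if (!length(tss)) next
    p <- stats$pos[idx]
    j <- findInterval(p, tss)
    lo <- ifelse(j >= 1, abs(p - tss[pmax(j, 1)]), Inf)
    hi <- ifelse(j < length(tss), abs(tss[pmin(j + 1, length(tss))] - p), Inf)
    out[idx] <- pmin(lo, hi)
  }
  if (anyNA(out)) {
    fill <- if (all(is.na(out))) 0 else max(out, na.rm = TRUE) + 1
    out[is.na(out)] <- fill
  }
  out
}

#' Test enrichment of GWAS signal in one annotation at one threshold
#'
#' Dichotomizes the pruned variants at `y = 1\{p < threshold\}` and fits a
#' logistic regression of `y` on the annotation indicator plus categorical
#' confounder-bin dummies.  The reported estimate is the annotation's Wald
#' log-odds, `or = exp(estimate)`.  With no confounder bins this equals
#' the closed-form 2x2 log odds ratio.
#'
#' Cells with zero (or all) significant variants, or a constant annotation
#' column, are flagged `"untestable"` and carry no estimate.  Complete or
#' quasi-complete separation triggers a Firth-penalized fit, flagged
#' `"penalized"`.
#'
#' @param pruned Pruned summary-statistics tibble.
#' @param annot Integer 0/1 annotation vector aligned with `pruned`.
#' @param threshold GWAS p-value threshold T.
#' @param bins Optional [bin_confounders()] result aligned with `pruned`,
#'   or a prebuilt [confounder_design()] matrix (reused across many cells
#'   of a scan grid).
#' @return One-row tibble: `threshold`, `estimate`, `se`, `or`, `p`,
#'   `n_pruned`, `n_significant`, `n_annotated`, `status`
#'   (`"ok"`/`"penalized"`/`"untestable"`).
#' @export
test_enrichment <- function(pruned, annot, threshold, bins = NULL) {
  y <- as.integer(pruned$p < threshold)
  n <- length(y)
  n_sig <- sum(y)
  n_ann <- sum(annot)
  base <- tibble(threshold = threshold, estimate = NA_real_, se = NA_real_,
                 or = NA_real_, p = NA_real_, n_pruned = n,
                 n_significant = n_sig, n_annotated = n_ann,
                 status = "untestable")
  if (n_sig == 0 || n_sig == n || n_ann == 0 || n_ann == n) return(base)

  X <- cbind(`(Intercept)` = 1, annot = annot)
  if (!is.null(bins)) {
    B <- if (is.matrix(bins)) bins else confounder_design(bins)
    if (ncol(B)) X <- cbind(X, B)
  }
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  cf <- fit$coefficients
  # Separation is judged on the annotation term only: diverging nuisance
  # bin dummies (e.g. an empty significant stratum) leave the annotation
  # Wald estimate valid.
  separated <- !fit$converged || is.na(cf[["annot"]]) || abs(cf[["annot"]]) > 15
  if (!separated) {
    ok_cols <- !is.na(cf)
    W <- fit$weights
    XtWX <- crossprod(X[, ok_cols, drop = FALSE] * sqrt(W))
    V <- tryCatch(solve(XtWX), error = function(e) NULL)
    se_hat <- if (is.null(V)) NA_real_ else sqrt(V["annot", "annot"])
    if (!is.finite(se_hat) || se_hat > 15) {
      separated <- TRUE
    } else {
      est <- cf[["annot"]]
      return(mutate(base, estimate = est, se = !!se_hat, or = exp(est),
                    p = 2 * pnorm(-abs(est / !!se_hat)), status = "ok"))
    }
  }
  ff <- firth_logit(X, y)
  est <- ff$coef[["annot"]]
  se_hat <- ff$se[["annot"]]
  mutate(base, estimate = est, se = !!se_hat, or = exp(est),
         p = 2 * pnorm(-abs(est / !!se_hat)), status = "penalized")
}

#' Dummy design matrix for the confounder bins
#'
#' Expands the categorical bin codes of [bin_confounders()] into 0/1
#' dummy columns (first level dropped; single-level features contribute
#' nothing).  Building this once and passing it to [test_enrichment()]
#' avoids re-expanding the factors in every cell of a large grid.
#'
#' @param bins A [bin_confounders()] tibble.
#' @return Numeric matrix with one column per non-reference bin level;
#'   zero columns when every feature collapsed.
#' @export
confounder_design <- function(bins) {
  out <- matrix(numeric(0), nrow = nrow(bins), ncol = 0)
  for (col in c("maf_bin", "tss_bin", "ldprox_bin")) {
    f <- factor(bins[[col]])
    if (nlevels(f) > 1) {
      M <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(M) <- paste0(col, seq_len(ncol(M)))
      out <- cbind(out, M)
    }
  }
  out
}

# Firth-penalized logistic regression (Jeffreys prior), used as the
# documented fallback under separation.  Returns coefficients and Wald SEs.
firth_logit <- function(X, y, max_iter = 50, tol = 1e-8) {
  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- pmax(p * (1 - p), 1e-10)
    XW <- X * sqrt(W)
    XtWX <- crossprod(XW)
    Vinv <- tryCatch(solve(XtWX), error = function(e) MASS_ginv(XtWX))
    h <- rowSums((X %*% Vinv) * X) * W
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    delta <- drop(Vinv %*% U)
    delta <- pmin(pmax(delta, -5), 5)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  W <- pmax(p * (1 - p), 1e-10)
  V <- tryCatch(solve(crossprod(X * sqrt(W))), error = function(e) MASS_ginv(crossprod(X * sqrt(W))))
  list(coef = beta, se = sqrt(pmax(diag(V), 0)))
}

# Moore-Penrose pseudo-inverse via SVD (degenerate-design guard).
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Effective number of independent annotations
#'
#' Eigen-decomposes the correlation matrix of the annotation indicator
#' columns and returns the number of eigenvalues needed to reach 99.5% of
#' the total variance.  Constant columns are excluded (they carry no
#' testable signal).
#'
#' @param annot_matrix Matrix or tibble of 0/1 annotation columns (rows =
#'   pruned variants).
#' @return Integer >= 1.
#' @export
effective_n_annotations <- function(annot_matrix) {
  M <- as.matrix(annot_matrix)
  sds <- apply(M, 2, sd)
  M <- M[, sds > 0, drop = FALSE]
  if (ncol(M) <= 1) return(max(1L, ncol(M)))
  ev <- eigen(cor(M), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  as.integer(which(cumsum(ev) >= 0.995 * sum(ev))[1])
}

#' Run the full annotation-by-threshold enrichment scan
#'
#' Prunes the variants, bins the matched confounders, annotates the pruned
#' variants against every annotation (by default through LD proxies at
#' `r^2 > 0.8` as well as direct overlap), fits the enrichment regression
#' on the full annotation x threshold grid, and applies multiple-testing
#' control: Bonferroni at `alpha` over the effective number of independent
#' annotations (eigenvalue rule, see [effective_n_annotations()]), or
#' Benjamini-Hochberg over the testable grid via
#' `correction = "BH"`.
#'
#' @param stats Summary-statistics tibble.
#' @param annotations Named list of peak tibbles, one per annotation.
#' @param ld An [ld_ref()].
#' @param genes A [gene_models()] object (TSS confounder).
#' @param thresholds GWAS p-value thresholds T (default the eight-point
#'   grid 0.05, 1e-2, ..., 1e-8).
#' @param r2_threshold,window_kb Pruning parameters (defaults 0.01 /
#'   500 kb).
#' @param n_bins Confounder bins per feature.
#' @param use_proxies Annotate through LD proxies at `r^2 > 0.8` (default
#'   TRUE) in addition to direct overlap.
#' @param alpha Family-wise significance level (default 0.05).
#' @param correction `"eff_bonferroni"` (default) or `"BH"`.
#' @return A tibble of class `enrich_scan`, one row per (annotation,
#'   threshold) mirroring [test_enrichment()] plus `annotation` and
#'   `significant_after_correction`; attributes `n_eff` and `alpha`.
#' @export
run_enrichment_scan <- function(stats, annotations, ld, genes,
                                thresholds = c(0.05, 1e-2, 1e-3, 1e-4,
                                               1e-5, 1e-6, 1e-7, 1e-8),
                                r2_threshold = 0.01, window_kb = 500,
                                n_bins = 5, use_proxies = TRUE,
                                alpha = 0.05,
                                correction = c("eff_bonferroni", "BH")) {
  correction <- match.arg(correction)
  if (!length(annotations)) abort("Need at least one annotation.")
  pruned <- prune_variants(stats, ld, r2_threshold, window_kb)
  bins <- bin_confounders(pruned, genes, ld, n_bins)
  bdesign <- confounder_design(bins)
  proxies <- if (use_proxies) ld_proxy_map(ld, 0.8) else NULL
  amat <- build_annotation_matrix(pruned, annotations, proxies)
  acols <- as.matrix(amat[, -1, drop = FALSE])

  grid <- purrr::map_dfr(names(annotations), function(a) {
    av <- acols[, a]
    purrr::map_dfr(thresholds, function(T) {
      mutate(test_enrichment(pruned, av, T, bdesign), annotation = a,
             .before = 1)
    })
  })

  n_eff <- effective_n_annotations(acols)
  if (correction == "eff_bonferroni") {
    grid$significant_after_correction <- !is.na(grid$p) & grid$p < alpha / n_eff
  } else {
    testable <- !is.na(grid$p)
    q <- rep(NA_real_, nrow(grid))
    q[testable] <- p.adjust(grid$p[testable], method = "BH")
    grid$significant_after_correction <- !is.na(q) & q < alpha
  }
  structure(grid, class = c("enrich_scan", class(grid)),
            n_eff = n_eff, alpha = alpha, correction = correction,
            n_pruned = nrow(pruned))
}
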