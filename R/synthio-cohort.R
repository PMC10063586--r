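#' Simulate a genotype-phenotype cohort under the liability-threshold model
#'
#' Dosages are drawn per LD block by a Gaussian copula: a latent normal
#' vector with the block's signed correlation is thresholded to genotypes
#' \{0, 1, 2\} at the Hardy-Weinberg cut points implied by each variant's
#' allele frequency, which controls both MAF and r^2.  Liability is
#' `sum_j beta_j * standardized_dosage_j + N(0, 1 - h2)` and an individual
#' is a case iff liability exceeds `qnorm(1 - K)`.  Quantitative
#' phenotypes are planted on the standardized true genetic score with
#' small fixed covariate effects and noise scaled so the total variance is
#' approximately one.
#'
#' @param genome A [generate_genome()] result.
#' @param truth A [synthetic_truth()] supplying causal effects, `h2`, `K`
#'   and `phenotype_effects`.
#' @param n_individuals Cohort size for `sampling = "population"`.
#' @param sampling `"population"`, or a named vector
#'   `c(n_cases = ..., n_controls = ...)` for case-control ascertainment.
#' @param n_pcs Number of simulated ancestry principal components.
#' @param max_pool_factor Case-control ascertainment simulates candidates
#'   until both strata fill; it errors (suggesting a larger pool) if more
#'   than `max_pool_factor * n_cases / K` candidates are needed.
#' @param seed Integer seed.
#' @return An object of class `cohort_data`: list with `dosages`
#'   (individuals x variants matrix, dimnames set), `samples` (tibble:
#'   `sample_id`, `status`, `liability`, `genetic_score`, covariates
#'   `age`, `gender`, `disease_duration`, `pc1..`, plus one column per
#'   planted phenotype) and `variants` (the genome's variant table).
#' @export
generate_cohort <- function(genome, truth,
                            n_individuals = NULL,
                            sampling = "population",
                            n_pcs = 4,
                            max_pool_factor = 50,
                            seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(truth, "synthetic_truth"))
  v <- genome$variants
  beta <- setNames(numeric(nrow(v)), v$variant_id)
  if (length(truth$causal_variants)) {
    unknown <- setdiff(names(truth$causal_variants), v$variant_id)
    if (length(unknown)) abort("Truth has causal variants absent from the genome.")
    beta[names(truth$causal_variants)] <- truth$causal_variants
  }
  thr <- qnorm(1 - truth$K)
  noise_sd <- sqrt(1 - truth$h2)
  set.seed(as.integer(seed))

  sim_chunk <- function(n) {
    D <- .sim_dosages(genome, n)
    g <- drop(scale(D, center = 2 * v$maf,
                    scale = sqrt(2 * v$maf * (1 - v$maf))) %*% beta)
    liab <- g + rnorm(n, sd = noise_sd)
    list(D = D, g = g, liab = liab)
  }

  if (identical(sampling, "population")) {
    check_scalar_number(n_individuals, "n_individuals", lower = 1)
    ch <- sim_chunk(as.integer(n_individuals))
    D <- ch$D; g <- ch$g; liab <- ch$liab
  } else {
    n_cases <- as.integer(sampling[["n_cases"]])
    n_controls <- as.integer(sampling[["n_controls"]])
    if (is.na(n_cases) || is.na(n_controls)) {
      abort("Case-control `sampling` needs named `n_cases` and `n_controls`.")
    }
    pool_cap <- max_pool_factor * (n_cases / truth$K + n_controls)
    chunk <- max(500L, min(5000L, as.integer(2e7 / max(1, nrow(v)))))
    Dc <- list(); gc_ <- list(); lc <- list(); sc <- list()
    got_ca <- 0L; got_co <- 0L; drawn <- 0
    while (got_ca < n_cases || got_co < n_controls) {
      if (drawn > pool_cap) {
        abort(sprintf(
          "Could not ascertain %d cases at K = %.3g within the candidate pool; increase `max_pool_factor` or K.",
          n_cases, truth$K))
      }
      ch <- sim_chunk(chunk)
      drawn <- drawn + chunk
      is_case <- ch$liab > thr
      take_ca <- which(is_case)[seq_len(min(sum(is_case), n_cases - got_ca))]
      take_co <- which(!is_case)[seq_len(min(sum(!is_case), n_controls - got_co))]
      take <- c(take_ca, take_co)
      if (length(take)) {
        Dc[[length(Dc) + 1L]] <- ch$D[take, , drop = FALSE]
        gc_[[length(gc_) + 1L]] <- ch$g[take]
        lc[[length(lc) + 1L]] <- ch$liab[take]
        sc[[length(sc) + 1L]] <- is_case[take]
        got_ca <- got_ca + length(take_ca)
        got_co <- got_co + length(take_co)
      }
    }
    D <- do.call(rbind, Dc); g <- unlist(gc_); liab <- unlist(lc)
  }

  n <- nrow(D)
  sample_id <- sprintf("ind%06d", seq_len(n))
  dimnames(D) <- list(sample_id, v$variant_id)
  status <- as.integer(liab > thr)

  age <- rnorm(n, 45, 10)
  gender <- rbinom(n, 1, 0.5)
  duration <- abs(rnorm(n, 8, 5))
  pcs <- matrix(rnorm(n * n_pcs), n, n_pcs,
                dimnames = list(NULL, paste0("pc", seq_len(n_pcs))))

  g_sd <- sd(g)
  g_std <- if (is.finite(g_sd) && g_sd > 0) (g - mean(g)) / g_sd else rep(0, n)

  samples <- tibble(
    sample_id = sample_id, status = status,
    liability = liab, genetic_score = g_std,
    age = age, gender = gender, disease_duration = duration
  )
  samples <- dplyr::bind_cols(samples, as_tibble(pcs))

  if (length(truth$phenotype_effects)) {
    age_std <- standardize(age, "age")
    gender_c <- gender - mean(gender)
    for (ph in names(truth$phenotype_effects)) {
      b <- truth$phenotype_effects[[ph]]
      eps_sd <- sqrt(max(1 - b^2 - 0.02, 0.1))
      samples[[ph]] <- b * g_std + 0.1 * age_std + 0.1 * gender_c +
        rnorm(n, sd = eps_sd)
    }
  }

  structure(list(dosages = D, samples = samples, variants = v),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %d individuals x %d variants (%d cases)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$samples$status)))
  invisible(x)
}

# Gaussian-copula dosage simulation: latent per-block MVN thresholded at
# Hardy-Weinberg cut points.
.sim_dosages <- function(genome, n) {
  v <- genome$variants
  D <- matrix(0L, n, nrow(v))
  idx_by_block <- split(seq_len(nrow(v)), v$block)
  for (b in names(genome$block_r)) {
    idx <- idx_by_block[[b]]
    R <- genome$block_r[[b]]
    L <- chol(R + diag(1e-6, nrow(R)))
    Z <- matrix(rnorm(n * length(idx)), n, length(idx)) %*% L
    U <- pnorm(Z)
    p <- v$maf[idx]
    c1 <- rep((1 - p)^2, each = n)
    c2 <- rep((1 - p)^2 + 2 * p * (1 - p), each = n)
    D[, idx] <- (U >= c1) + (U >= c2)
  }
  D
}

#' Simulate an ascertained case-control cohort at the score level
#'
#' A latent-liability oracle used to validate the liability-scale R^2
#' transformation: the score is standard normal, liability is
#' `sqrt(r2_liab) * score + sqrt(1 - r2_liab) * e`, disease status is
#' thresholded at prevalence `K`, and cases/controls are ascertained to
#' the requested counts.  By construction the score explains exactly
#' `r2_liab` of liability variance in the population.
#'
#' @param n_cases,n_controls Ascertained stratum sizes.
#' @param r2_liab Liability variance fraction explained by the score.
#' @param K Population prevalence.
#' @param seed Integer seed.
#' @return Tibble with `score`, `liability`, `status`.
#' @export
simulate_liability_scores <- function(n_cases, n_controls, r2_liab, K,
                                      seed = 1L) {
  check_scalar_number(r2_liab, "r2_liab", lower = 0, upper = 1)
  check_scalar_number(K, "K", lower = 1e-12, upper = 1 - 1e-12)
  set.seed(as.integer(seed))
  thr <- qnorm(1 - K)
  sc <- numeric(0); li <- numeric(0); st <- integer(0)
  got_ca <- 0L; got_co <- 0L
  chunk <- max(10000L, as.integer(ceiling(2 * n_cases / K / 50)))
  guard <- 0L
  while (got_ca < n_cases || got_co < n_controls) {
    guard <- guard + 1L
    if (guard > 1000L) abort("Ascertainment failed; K too small for requested counts.")
    s <- rnorm(chunk)
    l <- sqrt(r2_liab) * s + sqrt(1 - r2_liab) * rnorm(chunk)
    case <- l > thr
    take_ca <- which(case)[seq_len(min(sum(case), n_cases - got_ca))]
    take_co <- which(!case)[seq_len(min(sum(!case), n_controls - got_co))]
    take <- c(take_ca, take_co)
    sc <- c(sc, s[take]); li <- c(li, l[take])
    st <- c(st, as.integer(case[take]))
    got_ca <- got_ca + length(take_ca); got_co <- got_co + length(take_co)
  }
  tibble(score = sc, liability = li, status = st)
}
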