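#' Simulate GWAS summary statistics over a genome model
#'
#' Z-scores are drawn per LD block from a multivariate normal whose
#' correlation is the signed LD matrix and whose mean is the LD-propagated
#' non-centrality: for variant i,
#' `mean_i = sum_j r_ij * beta_j * sqrt(2 * maf_j * (1 - maf_j) * n_eff)`,
#' the standard propagation of causal signal onto proxies.  Two-sided
#' p-values come from the normal tail; the reported per-variant effect is
#' `beta_hat = z * se` with `se = 1 / sqrt(2 * maf * (1 - maf) * n_eff)`
#' (log-odds scale for a 1:1 case-control design of effective size
#' `n_eff`).
#'
#' Near-singular block correlation matrices are stabilised with a ridge of
#' 1e-6 on the diagonal before the Cholesky factorisation; this is applied
#' unconditionally and its bias is negligible at that magnitude.
#'
#' @param genome A [generate_genome()] result.
#' @param truth A [synthetic_truth()]; `truth$causal_variants` supplies the
#'   liability/log-odds effects `beta` (may be empty for a null scan).
#' @param n_eff Effective sample size (> 0).
#' @param seed Integer seed; fixed seed reproduces the scan exactly.
#' @return A summary-statistics tibble: `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`, `maf`, `info`,
#'   `z`.
#' @export
#' @examples
#' g <- generate_genome(50, block_size = 5, seed = 1)
#' s <- generate_gwas(g, synthetic_truth(), n_eff = 1e4, seed = 2)
generate_gwas <- function(genome, truth, n_eff, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(truth, "synthetic_truth"))
  check_scalar_number(n_eff, "n_eff", lower = 1)
  v <- genome$variants
  beta <- setNames(numeric(nrow(v)), v$variant_id)
  cv <- truth$causal_variants
  if (length(cv)) {
    unknown <- setdiff(names(cv), v$variant_id)
    if (length(unknown)) {
      abort(sprintf("Causal variants absent from genome: %s",
                    paste(utils::head(unknown, 3), collapse = ", ")))
    }
    beta[names(cv)] <- cv
  }
  ncp_unit <- sqrt(2 * v$maf * (1 - v$maf) * n_eff)

  set.seed(as.integer(seed))
  z <- numeric(nrow(v))
  idx_by_block <- split(seq_len(nrow(v)), v$block)
  for (b in names(genome$block_r)) {
    idx <- idx_by_block[[b]]
    R <- genome$block_r[[b]]
    mu <- drop(R %*% (beta[idx] * ncp_unit[idx]))
    L <- chol(R + diag(1e-6, nrow(R)))
    z[idx] <- mu + drop(crossprod(L, rnorm(length(idx))))
  }

  se <- 1 / ncp_unit
  mutate(
    select(v, -"block"),
    beta = z * se,
    se = se,
    p = pmax(2 * pnorm(-abs(z)), .Machine$double.xmin),
    info = 1,
    z = z
  )
}
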