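#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a score evaluation
#'
#' `tidy()` returns the score term (log-odds per unit score with its
#' Wald p); `glance()` returns the one-row accuracy summary (observed and
#' liability-scale R^2, AUC, sample sizes).
#'
#' @param x A `cprs_result` from [evaluate_scores()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cprs_result <- function(x, ...) {
  tibble(term = "score", estimate = x$beta, p.value = x$p)
}

#' @rdname tidy.cprs_result
#' @export
glance.cprs_result <- function(x, ...) {
  tibble(
    r2_obs = x$r2_obs, r2_liab = x$r2_liab, auc = x$auc, p = x$p,
    n = x$n, n_cases = x$n_cases, K = x$K, case_fraction = x$P
  )
}

#' Tidy a score model
#'
#' `tidy()` returns the selected variants and weights; `glance()` the
#' model metadata.
#'
#' @param x A [score_model()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.score_model <- function(x, ...) {
  x$variants
}

#' @rdname tidy.score_model
#' @export
glance.score_model <- function(x, ...) {
  tibble(n_variants = nrow(x$variants), p_threshold = x$p_threshold,
         cell_type = x$cell_type, universe = x$universe,
         mhc_excluded = x$mhc_excluded)
}

#' Plot an enrichment scan
#'
#' Odds ratio against the GWAS p-value threshold, one line per
#' annotation; corrected-significant cells are filled.
#'
#' @param object An `enrich_scan` from [run_enrichment_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrich_scan <- function(object, ...) {
  df <- filter(as_tibble(object), .data$status != "untestable")
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$threshold), y = .data$or,
    colour = .data$annotation, group = .data$annotation
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant_after_correction),
                        size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                name = "significant") +
    ggplot2::labs(x = expression(-log[10](T)), y = "odds ratio",
                  colour = "annotation") +
    ggplot2::theme_minimal()
}

#' Plot odds ratios across score strata
#'
#' @param object An `or_strata` from [stratify_or()].
#' @param ... Unused.
#' @return A ggplot object with OR point estimates and +/- 1 SE bars on
#'   the log-odds scale.
#' @export
autoplot.or_strata <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$q_lo + df$q_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$or)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = exp(.data$estimate - .data$se),
                                        ymax = exp(.data$estimate + .data$se)),
                           width = 0.02, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$reference), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "score quantile (stratum midpoint)", y = "odds ratio") +
    ggplot2::theme_minimal()
}

#' Gene-level association dot plot
#'
#' @param results A [gene_level_test()] (optionally [fdr_filter()]-ed)
#'   tibble.
#' @param alpha FDR line when `q` is present.
#' @return A ggplot object.
#' @export
plot_gene_results <- function(results, alpha = 0.05) {
  df <- mutate(results, idx = row_number())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = -log10(.data$p)))
  if ("risk" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$risk)) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                              `TRUE` = "firebrick"),
                                   name = "risk gene")
  } else {
    p <- p + ggplot2::geom_point(colour = "grey30")
  }
  p + ggplot2::labs(x = "gene index", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
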