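#' Covariate-adjusted linear association of a score with a phenotype
#'
#' Score and phenotype are standardized to mean 0, SD 1 on the complete
#' cases before fitting, so the reported `beta` is a standardized
#' coefficient.  `r2` is the incremental R^2 of
#' `phenotype ~ covariates + score` over covariates-only (equivalently,
#' the squared partial correlation of score and phenotype given the
#' covariates, scaled by `1 - R^2_covariates`).
#'
#' @param score Numeric score vector (or [compute_prs()] tibble).
#' @param phenotype Numeric phenotype vector.
#' @param covariates Optional data frame (e.g. age, gender,
#'   disease_duration).
#' @param phenotype_name,label Labels carried into the result row.
#' @return One-row tibble: `phenotype`, `label`, `beta`, `beta_raw`,
#'   `se`, `r2`, `p`, `n`.
#' @export
assoc_linear <- function(score, phenotype, covariates = NULL,
                         phenotype_name = "phenotype", label = NA_character_) {
  score <- if (is.data.frame(score)) score$score else score
  covar <- if (is.null(covariates)) {
    data.frame(row.names = seq_along(score))
  } else {
    as.data.frame(covariates)
  }
  cc <- complete.cases(score, phenotype) &
    (if (ncol(covar)) complete.cases(covar) else TRUE)
  score <- score[cc]; phenotype <- phenotype[cc]
  covar <- covar[cc, , drop = FALSE]
  n <- length(score)
  raw_sd_score <- sd(score); raw_sd_ph <- sd(phenotype)
  s <- standardize(score, "score")
  y <- standardize(phenotype, "phenotype")

  df <- data.frame(y = y, covar)
  fit0 <- lm(y ~ ., data = df)
  df$s <- s
  fit1 <- lm(y ~ ., data = df)
  sm <- summary(fit1)$coefficients
  beta <- unname(sm["s", "Estimate"])
  tibble(
    phenotype = phenotype_name, label = label,
    beta = beta,
    beta_raw = beta * raw_sd_ph / raw_sd_score,
    se = unname(sm["s", "Std. Error"]),
    r2 = max(summary(fit1)$r.squared - summary(fit0)$r.squared, 0),
    p = unname(sm["s", "Pr(>|t|)"]),
    n = n
  )
}

#' Covariate-adjusted logistic association of a score with a binary outcome
#'
#' The score is standardized before fitting; `beta` is the log-odds per
#' SD of score with a two-sided Wald p.  Separation triggers a
#' Firth-penalized refit, flagged in `status`.
#'
#' @param score Numeric score vector (or [compute_prs()] tibble).
#' @param outcome Binary 0/1 vector (e.g. relapse within 5 years), both
#'   classes present.
#' @param covariates Optional data frame.
#' @param outcome_name,label Labels carried into the result row.
#' @return One-row tibble: `phenotype`, `label`, `beta`, `se`, `or`, `p`,
#'   `n`, `status`.
#' @export
assoc_binary <- function(score, outcome, covariates = NULL,
                         outcome_name = "outcome", label = NA_character_) {
  score <- if (is.data.frame(score)) score$score else score
  outcome <- as.integer(outcome)
  covar <- if (is.null(covariates)) {
    data.frame(row.names = seq_along(score))
  } else {
    as.data.frame(covariates)
  }
  cc <- complete.cases(score, outcome) &
    (if (ncol(covar)) complete.cases(covar) else TRUE)
  score <- score[cc]; outcome <- outcome[cc]
  covar <- covar[cc, , drop = FALSE]
  if (length(unique(outcome)) < 2) abort("Both outcome classes are required.")
  s <- standardize(score, "score")

  X <- cbind(`(Intercept)` = 1, s = s)
  if (ncol(covar)) {
    X <- cbind(X, as.matrix(
      model.matrix(~., data = covar)[, -1, drop = FALSE]))
  }
  fit <- suppressWarnings(glm.fit(X, outcome, family = binomial()))
  cf <- fit$coefficients
  separated <- !fit$converged || is.na(cf[["s"]]) || abs(cf[["s"]]) > 15
  status_flag <- "ok"
  if (!separated) {
    ok_cols <- !is.na(cf)
    V <- tryCatch(solve(crossprod(X[, ok_cols, drop = FALSE] *
                                    sqrt(fit$weights))),
                  error = function(e) NULL)
    if (is.null(V) || !is.finite(V["s", "s"]) || sqrt(V["s", "s"]) > 15) {
      separated <- TRUE
    } else {
      beta <- cf[["s"]]; se <- sqrt(V["s", "s"])
    }
  }
  if (separated) {
    ff <- firth_logit(X, outcome)
    beta <- ff$coef[["s"]]; se <- ff$se[["s"]]
    status_flag <- "penalized"
  }
  tibble(
    phenotype = outcome_name, label = label,
    beta = beta, se = se, or = exp(beta),
    p = 2 * pnorm(-abs(beta / se)),
    n = length(outcome), status = status_flag
  )
}

#' Multiple-testing flags over an association grid
#'
#' Benjamini-Hochberg across the phenotype x universe grid by default;
#' Bonferroni via `method = "bonferroni"`.
#'
#' @param results Tibble with a `p` column (rows = phenotype x universe
#'   cells).
#' @param alpha Significance level (default 0.05).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return `results` with added `p_adj` and `significant` columns.
#' @export
multiple_testing <- function(results, alpha = 0.05,
                             method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!nrow(results)) abort("No association results supplied.")
  mutate(results,
         p_adj = p.adjust(.data$p, method = method),
         significant = .data$p_adj < alpha)
}
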