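#' Pool multiply-imputed regression fits by Rubin's rules
#'
#' Combines M analyses of pseudo-class-imputed outcomes: pooled point
#' estimate \eqn{\bar{Q}} (mean of the M estimates), within-imputation
#' variance \eqn{\bar{W}} (mean sampling variance), between-imputation
#' variance \eqn{B} (variance of the estimates), total variance
#' \eqn{T = \bar{W} + (1 + 1/M) B}, and Barnard-Rubin degrees of freedom
#' for the t-based interval.  Odds ratios and their 95% intervals are
#' formed on the log-odds scale and exponentiated.
#'
#' @param fits A list of M >= 2 [fit_cluster_logit()] objects sharing a
#'   design.
#' @param conf_level Interval level (default 0.95).
#' @return A `pooled_result` object; [tidy.pooled_result()] gives the per
#'   coefficient table.
#' @export
pool_rubin <- function(fits, conf_level = 0.95) {
  m <- length(fits)
  if (m < 2) rlang::abort("pooling requires M >= 2 fits")
  terms <- names(fits[[1]]$coef)
  for (f in fits) {
    if (!identical(names(f$coef), terms)) {
      rlang::abort("fits have mismatched coefficient names")
    }
  }
  est <- t(vapply(fits, function(f) unname(f$coef), numeric(length(terms))))
  vars <- t(vapply(fits, function(f) unname(diag(f$vcov)),
                   numeric(length(terms))))
  est <- matrix(est, nrow = m)
  vars <- matrix(vars, nrow = m)

  q_bar <- colMeans(est)
  w_bar <- colMeans(vars)
  b <- apply(est, 2L, stats::var)
  t_var <- w_bar + (1 + 1 / m) * b

  nu_com <- fits[[1]]$n_obs - length(terms)
  lambda <- (1 + 1 / m) * b / t_var
  nu_old <- ifelse(lambda > 0, (m - 1) / lambda^2, Inf)
  nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
  df <- 1 / (1 / nu_old + 1 / nu_obs)

  alpha <- 1 - conf_level
  tq <- stats::qt(1 - alpha / 2, df)
  table <- tibble::tibble(
    term = terms, estimate = q_bar, w_bar = w_bar, b = b, t_var = t_var,
    std.error = sqrt(t_var), df = df,
    statistic = q_bar / sqrt(t_var),
    p.value = 2 * stats::pt(-abs(q_bar / sqrt(t_var)), df),
    or = exp(q_bar),
    or.conf.low = exp(q_bar - tq * sqrt(t_var)),
    or.conf.high = exp(q_bar + tq * sqrt(t_var))
  )
  structure(list(table = table, m = m, nu_com = nu_com,
                 conf_level = conf_level,
                 n_obs = fits[[1]]$n_obs,
                 n_clusters = fits[[1]]$n_clusters),
            class = "pooled_result")
}

#' @rdname pool_rubin
#' @param x A `pooled_result`.
#' @param ... Unused.
#' @export
tidy.pooled_result <- function(x, ...) x$table

#' @rdname pool_rubin
#' @export
glance.pooled_result <- function(x, ...) {
  tibble::tibble(m = x$m, n_obs = x$n_obs, n_clusters = x$n_clusters,
                 nu_com = x$nu_com, conf_level = x$conf_level)
}

#' @export
print.pooled_result <- function(x, digits = 2, ...) {
  cat(sprintf("<pooled_result: M = %d imputations, %d obs, %d clusters>\n",
              x$m, x$n_obs, x$n_clusters))
  tab <- x$table
  cat(sprintf("  %-28s OR %5.*f  (%.*f-%.*f)\n", tab$term, digits, tab$or,
              digits, tab$or.conf.low, digits, tab$or.conf.high), sep = "")
  invisible(x)
}

#' Structural model: pseudo-class membership on sanitation access
#'
#' Composes the downstream half of the pipeline: draw M pseudo-class
#' memberships from the fitted measurement model, code each imputation's
#' outcome as membership in class 1 (consistent latrine use), fit a
#' household-clustered logistic regression of the outcome on basic
#' sanitation access per imputation — unadjusted, and adjusted for
#' educational attainment, Afro-Ecuadorian ethnicity, gender, cement walls
#' and household asset deprivation — and pool by Rubin's rules.
#' Referent categories: less-than-basic sanitation, less-than-primary
#' education, Chachi/Mestizo/other ethnicity, male, non-cement walls,
#' asset-deprived household.
#'
#' @param data Survey tibble aligned row-for-row with `fit`.
#' @param fit The measurement-model [fit_lca()].
#' @param m Number of pseudo-class imputations.
#' @param seed Seed for the draws; the whole result is reproducible from
#'   it.
#' @param sex_interaction Experimental flag adding a sanitation-by-gender
#'   interaction to the adjusted model (off by default; the study design
#'   is too small to support it).
#' @return A `structural_result`: `unadjusted` and `adjusted`
#'   [pool_rubin()] results, per-imputation tidy tables, and the draws.
#' @export
run_structural_pipeline <- function(data, fit, m = 5, seed = NULL,
                                    sex_interaction = FALSE) {
  stopifnot(nrow(data) == nrow(fit$tau))
  draws <- draw_pseudo_classes(fit, m = m, seed = seed)
  dd <- binarize_sanitation(data)
  dd$female <- as.integer(dd$sex == "female")
  dd$afro_ecuadorian <- as.integer(dd$ethnicity == "afro_ecuadorian")
  dd$education <- factor(dd$education,
                         levels = latuse_covariate_levels()$education)
  dd$cement <- as.integer(dd$cement_walls == "yes")
  dd$non_asset_deprived <- as.integer(dd$asset_deprived == "no")

  adj_rhs <- "basic_sanitation + education + afro_ecuadorian + female + cement + non_asset_deprived"
  if (sex_interaction) adj_rhs <- paste(adj_rhs, "+ basic_sanitation:female")

  fit_one <- function(formula_str, outcome) {
    dd$.class1 <- as.integer(outcome == 1L)
    fit_cluster_logit(dd, stats::as.formula(formula_str),
                      cluster = "household_id")
  }
  unadj_fits <- lapply(seq_len(m), function(i)
    fit_one(".class1 ~ basic_sanitation", draws$draws[, i]))
  adj_fits <- lapply(seq_len(m), function(i)
    fit_one(paste(".class1 ~", adj_rhs), draws$draws[, i]))

  structure(list(
    unadjusted = pool_rubin(unadj_fits),
    adjusted = pool_rubin(adj_fits),
    per_imputation = list(
      unadjusted = purrr::imap_dfr(unadj_fits, ~ dplyr::mutate(tidy.cluster_logit(.x),
                                                               imputation = .y)),
      adjusted = purrr::imap_dfr(adj_fits, ~ dplyr::mutate(tidy.cluster_logit(.x),
                                                           imputation = .y))
    ),
    draws = draws, m = m, seed = seed
  ), class = "structural_result")
}

#' @export
print.structural_result <- function(x, ...) {
  cat("Unadjusted model:\n"); print(x$unadjusted)
  cat("Adjusted model:\n"); print(x$adjusted)
  invisible(x)
}
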