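#' Logistic regression with household-clustered standard errors
#'
#' Maximum-likelihood logistic fit with a cluster-aggregated sandwich
#' covariance: scores are summed within clusters (households) before the
#' outer product, with the small-sample factor G/(G-1).  Respondents in
#' the same household share unmeasured environment, so observations are
#' not independent and model-based standard errors would be too small.
#' Rows with a missing outcome or missing covariates are dropped
#' (complete-case), with the count recorded.
#'
#' @param data A data frame holding outcome, covariates and cluster id.
#' @param formula Model formula; the response must be coded 0/1.
#' @param cluster Cluster variable name (string) or a vector aligned with
#'   `data` rows; `NULL` treats every row as its own cluster, which
#'   reduces the estimator to plain heteroskedasticity-robust.
#' @param cadjust Apply the G/(G-1) small-sample factor (default TRUE).
#' @param separation_bound Absolute coefficient size beyond which complete
#'   or quasi-complete separation is declared.
#' @return A `cluster_logit` object: `coef`, `vcov` (cluster-robust),
#'   `n_obs`, `n_clusters`, `n_dropped`, the underlying `glm` fit, and the
#'   outcome coding record.
#' @export
fit_cluster_logit <- function(data, formula, cluster = "household_id",
                              cadjust = TRUE, separation_bound = 15) {
  mf_vars <- all.vars(formula)
  cl_vec <- if (is.null(cluster)) NULL
            else if (is.character(cluster) && length(cluster) == 1L) data[[cluster]]
            else cluster
  keep <- stats::complete.cases(data[, mf_vars, drop = FALSE])
  if (!is.null(cl_vec)) keep <- keep & !is.na(cl_vec)
  n_dropped <- sum(!keep)
  dat <- data[keep, , drop = FALSE]
  cl_vec <- if (is.null(cl_vec)) seq_len(nrow(dat)) else cl_vec[keep]

  outcome <- stats::model.response(stats::model.frame(formula, dat))
  if (!all(outcome %in% c(0, 1))) {
    rlang::abort("outcome must be coded 0/1")
  }
  g <- length(unique(cl_vec))
  if (g < 2) rlang::abort("need at least 2 clusters",
                          class = "latuse_cluster_error")

  fit <- stats::glm(formula, family = stats::binomial(), data = dat)
  coefs <- stats::coef(fit)
  big <- which(abs(coefs) > separation_bound)
  if (length(big) > 0) {
    rlang::abort(sprintf("separation detected for covariate(s): %s",
                         paste(names(coefs)[big], collapse = ", ")),
                 class = "latuse_separation_error")
  }
  vc <- sandwich::vcovCL(fit, cluster = cl_vec, type = "HC0",
                         cadjust = cadjust)
  structure(list(coef = coefs, vcov = vc, n_obs = nrow(dat),
                 n_clusters = g, n_dropped = n_dropped, glm_fit = fit,
                 outcome = deparse(formula[[2]]),
                 outcome_coding = "1 = member of class 1 (consistent use)"),
            class = "cluster_logit")
}

#' @export
print.cluster_logit <- function(x, ...) {
  cat(sprintf("<cluster_logit: %d obs in %d clusters (%d dropped)>\n",
              x$n_obs, x$n_clusters, x$n_dropped))
  print(tidy.cluster_logit(x))
  invisible(x)
}

#' @rdname fit_cluster_logit
#' @param x A `cluster_logit` object.
#' @param ... Unused.
#' @export
tidy.cluster_logit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(se),
                 statistic = unname(x$coef / se),
                 p.value = 2 * stats::pnorm(-abs(unname(x$coef / se))))
}

#' @rdname fit_cluster_logit
#' @export
glance.cluster_logit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_clusters = x$n_clusters,
                 n_dropped = x$n_dropped,
                 deviance = x$glm_fit$deviance, aic = x$glm_fit$aic)
}
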