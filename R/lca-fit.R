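#' Fit a latent class model to polytomous survey indicators
#'
#' Maximum-likelihood estimation of a finite mixture of independent
#' multinomials by expectation-maximization.  Individuals with missing
#' items contribute the likelihood of their observed items only
#' (full-information maximum likelihood under a missing-at-random
#' assumption), so no respondent is dropped.  The observed-data likelihood
#' is
#' \deqn{L = \prod_i \sum_k \pi_k \prod_{j \in obs(i)} \rho_{j,k,y_{ij}}}
#' with class prevalences \eqn{\pi} and class-conditional item-response
#' probabilities \eqn{\rho}.  The fit is the best of `n_starts` random
#' restarts; classes are relabeled in order of decreasing prevalence, so
#' class 1 is always the largest (in the reference latrine-use model, the
#' consistent-user class).
#'
#' Computation collapses the data to distinct response patterns, so run
#' time scales with the number of patterns rather than the sample size.
#'
#' @param data A survey tibble (or any data frame containing the indicator
#'   columns as factors/characters over the codebook categories).
#' @param indicators Character vector of indicator column ids; defaults to
#'   every codebook indicator present in `data`.
#' @param k Number of latent classes (>= 1).
#' @param n_starts Random EM restarts.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol`.
#' @param seed Optional integer seed controlling the random restarts.
#' @param se_method `"observed_information"` (default) inverts the analytic
#'   observed-data Hessian in an unconstrained logit parameterization and
#'   delta-methods back to probabilities; `"sandwich"` additionally
#'   requires `cluster` and uses household-aggregated score outer products;
#'   `"none"` skips standard errors.
#' @param cluster Optional cluster (household) id vector for the sandwich
#'   method; defaults to `data$household_id` when present.
#' @param codebook Codebook giving the category sets.
#' @return An object of class `lca_fit`; see [tidy.lca_fit()],
#'   [glance.lca_fit()], [posterior()], [relative_entropy()],
#'   [pearson_gof()].
#' @examples
#' model <- latrine_use_model()
#' sim <- generate_from_fit(model, n = 500, seed = 1)
#' fit <- fit_lca(sim, k = 2, n_starts = 10, seed = 1)
#' glance(fit)
#' @export
fit_lca <- function(data, indicators = NULL, k = 2, n_starts = 50,
                    max_iter = 5000, tol = 1e-8, seed = NULL,
                    se_method = c("observed_information", "sandwich", "none"),
                    cluster = NULL, codebook = default_codebook()) {
  se_method <- match.arg(se_method)
  if (k < 1) rlang::abort("k must be >= 1")
  if (tol <= 0) rlang::abort("tol must be > 0")
  if (is.null(indicators)) {
    indicators <- intersect(codebook$indicators$id, names(data))
  }
  if (length(indicators) == 0) rlang::abort("no indicator columns found")
  categories <- codebook$categories
  y <- encode_responses(data, indicators, categories)
  n <- nrow(y)
  if (n <= k) rlang::abort("need more individuals than classes (N > K)")
  obs_per_item <- colSums(!is.na(y))
  if (any(obs_per_item == 0)) {
    rlang::abort(sprintf("indicator `%s` has no observed responses",
                         indicators[which(obs_per_item == 0)[1]]))
  }

  pat <- collapse_patterns(y)
  if (k > nrow(pat$p)) {
    rlang::abort(sprintf(
      "k = %d exceeds the %d distinct response patterns; the model is not identifiable",
      k, nrow(pat$p)), class = "latuse_identifiability_error")
  }

  n_cat <- length(categories)
  runs <- with_seed_if(seed, {
    lapply(seq_len(n_starts), function(s) {
      init <- random_init(length(indicators), k, n_cat)
      em_multinomial_mixture(pat$p, pat$w, init$pi, init$rho, max_iter, tol)
    })
  })
  start_logliks <- vapply(runs, function(r) r$loglik, numeric(1))
  conv <- vapply(runs, function(r) r$converged, logical(1))
  if (!any(conv)) {
    rlang::abort("no EM restart converged", class = "latuse_convergence_error",
                 start_logliks = start_logliks)
  }
  best <- runs[[which.max(ifelse(conv, start_logliks, -Inf))]]

  # relabel classes by descending prevalence
  ord <- order(best$pi, decreasing = TRUE)
  pi_hat <- best$pi[ord]
  rho_hat <- best$rho[, ord, , drop = FALSE]
  tau_pat <- best$tau[, ord, drop = FALSE]
  dimnames(rho_hat) <- list(indicators, paste0("class", seq_len(k)), categories)
  names(pi_hat) <- paste0("class", seq_len(k))

  tau <- tau_pat[pat$index, , drop = FALSE]
  colnames(tau) <- names(pi_hat)
  p_free <- n_params_lca(k, rep(n_cat, length(indicators)))

  fit <- structure(list(
    pi = pi_hat, rho = rho_hat, tau = tau,
    loglik = best$loglik, n_params = p_free,
    bic = compute_bic(best$loglik, p_free, n),
    rel_entropy = relative_entropy(tau),
    x2 = NULL, gof_p = NULL,
    se_pi = NULL, se_rho = NULL, boundary = NULL,
    converged = TRUE, n_iter = best$n_iter, ll_trace = best$ll_trace,
    start_logliks = start_logliks,
    k = k, n = n, indicators = indicators, categories = categories,
    n_patterns = nrow(pat$p), seed = seed, se_method = se_method,
    patterns = pat
  ), class = "lca_fit")

  if (se_method != "none") {
    if (is.null(cluster) && "household_id" %in% names(data)) {
      cluster <- data$household_id
    }
    fit <- estimate_ses(fit, method = se_method, cluster = cluster)
  }
  fit
}

encode_responses <- function(data, indicators, categories) {
  absent <- setdiff(indicators, names(data))
  if (length(absent) > 0) {
    rlang::abort(sprintf("data is missing indicator column(s): %s",
                         paste(absent, collapse = ", ")),
                 class = "latuse_schema_error")
  }
  y <- matrix(NA_integer_, nrow(data), length(indicators))
  for (j in seq_along(indicators)) {
    x <- data[[indicators[j]]]
    x <- as.character(x)
    bad <- which(!is.na(x) & !(x %in% categories))
    if (length(bad) > 0) {
      rlang::abort(sprintf("invalid response \"%s\" for `%s` at row %d",
                           x[bad[1]], indicators[j], bad[1]),
                   class = "latuse_validation_error")
    }
    y[, j] <- match(x, categories)
  }
  y
}

collapse_patterns <- function(y) {
  key <- apply(y, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  p <- y[first, , drop = FALSE]
  index <- match(key, key[first])
  list(p = p, w = as.numeric(tabulate(index, nbins = nrow(p))), index = index)
}

random_init <- function(n_item, k, n_cat) {
  pi <- stats::rgamma(k, 1)
  rho <- array(stats::rgamma(n_item * k * n_cat, 1), dim = c(n_item, k, n_cat))
  list(pi = pi / sum(pi),
       rho = rho / array(rep(apply(rho, c(1, 2), sum), n_cat),
                         dim = dim(rho)))
}

# E-step quantities for a pattern matrix: per-pattern, per-class
# log-likelihood contributions and posteriors.  rho is floored inside the
# logs to avoid -Inf; reported estimates may still reach the boundary.
lca_estep <- function(p, pi, rho, floor = 1e-10) {
  n_pat <- nrow(p)
  k <- length(pi)
  logf <- matrix(0, n_pat, k)
  for (j in seq_len(ncol(p))) {
    yj <- p[, j]
    obs <- which(!is.na(yj))
    if (length(obs) == 0) next
    lr <- log(pmax(matrix(rho[j, , ], nrow = k), floor))  # K x C
    logf[obs, ] <- logf[obs, ] + t(lr[, yj[obs], drop = FALSE])
  }
  a <- sweep(logf, 2L, log(pmax(pi, floor)), "+")
  lse <- row_logsumexp(a)
  list(tau = exp(a - lse), lse = lse)
}

em_multinomial_mixture <- function(p, w, pi, rho, max_iter, tol) {
  n_cat <- dim(rho)[3]
  k <- length(pi)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e <- lca_estep(p, pi, rho)
    ll <- sum(w * e$lse)
    ll_trace <- c(ll_trace, ll)
    # the rho floor inside the E-step logs can cost a sub-1e-7 wiggle near
    # boundary optima; only a material decrease is a genuine failure
    if (is.finite(ll_old) && ll < ll_old - 1e-6 * (abs(ll_old) + 1)) {
      rlang::abort("EM log-likelihood decreased; numerical failure")
    }
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    wk <- w * e$tau                       # n_pat x K
    pi <- colSums(wk) / sum(w)
    for (j in seq_len(ncol(p))) {
      yj <- p[, j]
      obs <- which(!is.na(yj))
      denom <- colSums(wk[obs, , drop = FALSE])
      num <- matrix(0, n_cat, k)
      agg <- rowsum(wk[obs, , drop = FALSE], group = yj[obs])
      num[as.integer(rownames(agg)), ] <- agg
      rho[j, , ] <- t(num) / pmax(denom, 1e-300)
    }
  }
  e <- lca_estep(p, pi, rho)
  list(pi = pi, rho = rho, tau = e$tau, loglik = sum(w * e$lse),
       n_iter = iter, converged = converged, ll_trace = ll_trace)
}

#' Number of free parameters of a polytomous latent class model
#'
#' @param k Number of classes.
#' @param n_categories Integer vector of category counts per indicator.
#' @return `(k - 1) + k * sum(n_categories - 1)`.
#' @export
n_params_lca <- function(k, n_categories) {
  (k - 1L) + k * sum(n_categories - 1L)
}

#' Bayesian information criterion
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters.
#' @param n Sample size.
#' @return `-2 * loglik + n_params * log(n)`.
#' @export
compute_bic <- function(loglik, n_params, n) {
  stopifnot(n >= 1)
  -2 * loglik + n_params * log(n)
}

#' Relative entropy of a posterior classification
#'
#' One minus the mean posterior Shannon entropy normalized by its maximum
#' `log(K)`: values near 1 indicate cleanly separated classes, values near
#' 0 indicate no separation.  Defined as 1 for a one-class model.
#'
#' @param tau An N x K posterior matrix (rows sum to 1) or an [fit_lca()]
#'   object.
#' @return A scalar in \[0, 1\].
#' @export
relative_entropy <- function(tau) {
  if (inherits(tau, "lca_fit")) tau <- tau$tau
  tau <- as.matrix(tau)
  if (ncol(tau) == 1) return(1)
  assert_prob_rows(tau, what = "tau")
  h <- -tau * log(tau)
  h[!is.finite(h)] <- 0  # 0 * log(0) := 0
  1 - sum(h) / (nrow(tau) * log(ncol(tau)))
}

#' Posterior class-membership probabilities for response vectors
#'
#' Bayes' rule under the fitted model:
#' \eqn{\tau_k \propto \pi_k \prod_{j \in obs} \rho_{j,k,y_j}}.  A fully
#' missing response vector returns the class prevalences themselves.
#'
#' @param fit An [fit_lca()] object.
#' @param newdata A data frame with the fit's indicator columns (category
#'   strings or factors; `NA` = missing).
#' @return A tibble with one class-probability column per class.
#' @export
posterior <- function(fit, newdata) {
  y <- encode_responses(newdata, fit$indicators, fit$categories)
  e <- lca_estep(y, fit$pi, fit$rho)
  tibble::as_tibble(as.data.frame(e$tau)) |>
    stats::setNames(names(fit$pi))
}

#' @export
print.lca_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<lca_fit: %d classes, %d indicators, N = %d>\n",
              x$k, length(x$indicators), x$n))
  cat("  prevalences:", paste(sprintf("%.*f", digits, x$pi), collapse = ", "), "\n")
  cat(sprintf("  logLik %.2f | BIC %.1f | relative entropy %.3f\n",
              x$loglik, x$bic, x$rel_entropy))
  if (!is.null(x$x2)) {
    cat(sprintf("  Pearson X2 %.1f (bootstrap p = %s)\n", x$x2,
                format(x$gof_p %||% NA)))
  }
  invisible(x)
}

#' @export
logLik.lca_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}
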