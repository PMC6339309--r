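#' Pearson goodness of fit with a parametric-bootstrap p-value
#'
#' Compares observed counts of complete response patterns with the counts
#' the fitted mixture implies.  The statistic sums `(O - E)^2 / E` over
#' every distinct observed pattern plus one aggregate cell holding the
#' total expected mass of patterns never observed (O = 0).  With J
#' three-category indicators the contingency table has `3^J` cells, so at
#' survey sample sizes the asymptotic chi-square reference is meaningless;
#' the p-value is instead obtained by parametric bootstrap: simulate
#' complete responders from the fitted model, refit (warm-started EM) and
#' recompute the statistic.
#'
#' Patterns are defined on complete-response individuals only; respondents
#' with missing items still inform estimation (FIML) but not the statistic.
#'
#' @param fit A fitted [fit_lca()] object.
#' @param data The survey data the model was fitted to.
#' @param b Number of bootstrap replicates (0 skips the p-value).
#' @param seed Optional seed for the bootstrap.
#' @return A list `(x2, p_value, df_cells, n_complete, boot_stats)`.
#' @export
pearson_gof <- function(fit, data, b = 200, seed = NULL) {
  y <- encode_responses(data, fit$indicators, fit$categories)
  cc <- stats::complete.cases(y)
  if (!any(cc)) rlang::abort("no complete-response individuals")
  y <- y[cc, , drop = FALSE]
  x2 <- pearson_x2(y, fit$pi, fit$rho)

  boot_stats <- numeric(0)
  p_value <- NA_real_
  if (b > 0) {
    boot_stats <- with_seed_if(seed, {
      vapply(seq_len(b), function(r) {
        y_b <- simulate_patterns(fit$pi, fit$rho, nrow(y))
        pat <- collapse_patterns(y_b)
        refit <- em_multinomial_mixture(pat$p, pat$w, fit$pi, fit$rho,
                                        max_iter = 2000, tol = 1e-8)
        pearson_x2(y_b, refit$pi, refit$rho)
      }, numeric(1))
    })
    p_value <- (1 + sum(boot_stats >= x2)) / (b + 1)
  }
  list(x2 = x2, p_value = p_value,
       df_cells = length(fit$categories)^length(fit$indicators),
       n_complete = nrow(y), boot_stats = boot_stats)
}

pearson_x2 <- function(y_complete, pi, rho) {
  pat <- collapse_patterns(y_complete)
  probs <- pattern_prob(pat$p, pi, rho)
  n <- sum(pat$w)
  expected <- n * probs
  if (any(expected <= 0)) {
    rlang::abort("zero expected mass in an observed cell (numerical underflow)")
  }
  rest <- n * max(1 - sum(probs), 0)
  sum((pat$w - expected)^2 / expected) + rest
}

# mixture-implied probability of each (complete) response pattern
pattern_prob <- function(p, pi, rho) {
  k <- length(pi)
  f <- matrix(1, nrow(p), k)
  for (j in seq_len(ncol(p))) {
    f <- f * t(matrix(rho[j, , ], nrow = k)[, p[, j], drop = FALSE])
  }
  as.numeric(f %*% pi)
}

# draw n complete response-pattern rows from (pi, rho)
simulate_patterns <- function(pi, rho, n) {
  k <- length(pi)
  n_item <- dim(rho)[1]
  n_cat <- dim(rho)[3]
  cls <- sample.int(k, n, replace = TRUE, prob = pi)
  y <- matrix(NA_integer_, n, n_item)
  for (j in seq_len(n_item)) {
    u <- stats::runif(n)
    cum <- t(apply(matrix(rho[j, , ], nrow = k), 1L, cumsum))  # K x C
    cum_i <- cum[cls, , drop = FALSE]
    y[, j] <- 1L + rowSums(u > cum_i + 1e-15)
    y[, j] <- pmin(y[, j], n_cat)
  }
  y
}
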