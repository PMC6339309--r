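#' Compare latent class solutions and choose the number of classes
#'
#' Fits a latent class model for each candidate number of classes and
#' applies the selection rule used for the latrine-use models: prefer the
#' lowest BIC; when solutions are near-tied (BIC within `delta_bic`),
#' reject any solution containing a class whose expected size
#' `N * min(pi)` falls below `min_class_n` — a class of a handful of
#' respondents cannot be distinguished in later structural modelling —
#' and require relative entropy of at least `entropy_min` for acceptance.
#'
#' @param data Survey tibble.
#' @param k_values Integer vector of candidate class counts.
#' @param indicators,n_starts,seed,codebook Passed to [fit_lca()]; each
#'   candidate is fitted with a seed derived deterministically from `seed`.
#' @param min_class_n Minimum acceptable expected class size.
#' @param entropy_min Minimum acceptable relative entropy (ignored for
#'   one-class models, whose entropy is 1 by convention).
#' @param delta_bic Near-tie width on the BIC scale.
#' @param boot_b Bootstrap replicates for the goodness-of-fit p-value per
#'   candidate (0 = report the statistic only).
#' @return An `lca_comparison` object: comparison table (one row per K),
#'   the fitted models, the selected K and the rule that fired.
#' @export
compare_class_solutions <- function(data, k_values = c(2, 3),
                                    indicators = NULL, n_starts = 50,
                                    seed = NULL, min_class_n = 10,
                                    entropy_min = 0.80, delta_bic = 2,
                                    boot_b = 0,
                                    codebook = default_codebook()) {
  stopifnot(all(k_values >= 1))
  fits <- lapply(seq_along(k_values), function(i) {
    fit <- fit_lca(data, indicators = indicators, k = k_values[i],
                   n_starts = n_starts,
                   seed = if (is.null(seed)) NULL else seed + i,
                   se_method = "none", codebook = codebook)
    gof <- pearson_gof(fit, data, b = boot_b,
                       seed = if (is.null(seed)) NULL else seed + 1000L + i)
    fit$x2 <- gof$x2
    fit$gof_p <- gof$p_value
    fit
  })
  names(fits) <- paste0("k", k_values)

  tab <- purrr::map2_dfr(fits, k_values, function(f, k) {
    tibble::tibble(
      k = k, loglik = f$loglik, n_params = f$n_params, bic = f$bic,
      x2 = f$x2, gof_p = f$gof_p, rel_entropy = f$rel_entropy,
      pi = list(unname(f$pi)),
      min_expected_n = f$n * min(f$pi),
      small_class = k > 1 && f$n * min(f$pi) < min_class_n,
      low_entropy = k > 1 && f$rel_entropy < entropy_min
    )
  })

  acceptable <- !tab$small_class & !tab$low_entropy
  if (!any(acceptable)) {
    rlang::abort("no candidate class solution is acceptable",
                 class = "latuse_no_acceptable_model", comparison = tab)
  }
  best_overall <- which.min(tab$bic)
  sel <- which(acceptable)[which.min(tab$bic[acceptable])]
  rule <- if (sel == best_overall) {
    "lowest BIC"
  } else if (tab$bic[sel] - tab$bic[best_overall] < delta_bic) {
    sprintf("near-tie (dBIC < %g) broken against a class with expected n < %g",
            delta_bic, min_class_n)
  } else {
    "lowest-BIC solution rejected by interpretability/entropy guard"
  }

  structure(list(table = tab, fits = fits, selected_k = tab$k[sel],
                 decision = rule, min_class_n = min_class_n,
                 entropy_min = entropy_min, delta_bic = delta_bic),
            class = "lca_comparison")
}

#' @export
print.lca_comparison <- function(x, ...) {
  cat("<lca_comparison>\n")
  print(dplyr::select(x$table, -"pi"))
  cat(sprintf("selected K = %d (%s)\n", x$selected_k, x$decision))
  invisible(x)
}

#' Prune indicators whose conditional probabilities do not separate classes
#'
#' An indicator is uninformative when its class-conditional item
#' probability confidence intervals overlap between the two classes for
#' every response category; such indicators are removed and the model
#' refitted once on the survivors.  Intervals are Wald 95% intervals
#' (`rho +/- z * SE`, truncated to \[0, 1\]); a probability estimated at
#' the boundary has a degenerate (point) interval, so it is disjoint from
#' any interval not containing that point.  Verdicts are computed in a
#' single pass over the full-indicator fit, not sequentially, so the
#' result does not depend on indicator order.
#'
#' @param fit A two-class [fit_lca()] with standard errors.
#' @param data The survey data (used for the refit).
#' @param conf_level Confidence level of the Wald intervals.
#' @param refit Refit on the retained indicators (default TRUE).
#' @param n_starts,seed Passed to the refit.
#' @return An `lca_prune` object: `retained`, `removed`, the per-category
#'   `ci_table` with the overlap verdicts, and `refit`.
#' @export
prune_uninformative <- function(fit, data, conf_level = 0.95, refit = TRUE,
                                n_starts = 50, seed = NULL,
                                codebook = default_codebook()) {
  if (fit$k != 2) {
    rlang::abort("the CI-overlap pruning rule is defined for two-class models")
  }
  if (is.null(fit$se_rho)) {
    rlang::abort("fit has no standard errors; rerun fit_lca with se_method != 'none'")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  for (j in seq_along(fit$indicators)) {
    for (cc in seq_along(fit$categories)) {
      e1 <- fit$rho[j, 1, cc]; s1 <- fit$se_rho[j, 1, cc]
      e2 <- fit$rho[j, 2, cc]; s2 <- fit$se_rho[j, 2, cc]
      lo1 <- max(e1 - z * s1, 0); hi1 <- min(e1 + z * s1, 1)
      lo2 <- max(e2 - z * s2, 0); hi2 <- min(e2 + z * s2, 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        indicator = fit$indicators[j], category = fit$categories[cc],
        est_class1 = e1, lo_class1 = lo1, hi_class1 = hi1,
        est_class2 = e2, lo_class2 = lo2, hi_class2 = hi2,
        boundary = fit$boundary[j, 1, cc] || fit$boundary[j, 2, cc],
        disjoint = ci_disjoint(lo1, hi1, lo2, hi2)
      )
    }
  }
  ci_table <- dplyr::bind_rows(rows)
  verdict <- ci_table |>
    dplyr::group_by(.data$indicator) |>
    dplyr::summarise(informative = any(.data$disjoint), .groups = "drop")
  retained <- fit$indicators[fit$indicators %in%
                               verdict$indicator[verdict$informative]]
  removed <- setdiff(fit$indicators, retained)

  refit_obj <- NULL
  if (refit && length(retained) > 0) {
    refit_obj <- fit_lca(data, indicators = retained, k = 2,
                         n_starts = n_starts, seed = seed,
                         codebook = codebook)
  }
  structure(list(retained = retained, removed = removed,
                 ci_table = ci_table, refit = refit_obj,
                 conf_level = conf_level),
            class = "lca_prune")
}

ci_disjoint <- function(lo1, hi1, lo2, hi2) (lo1 > hi2) || (lo2 > hi1)

#' @export
print.lca_prune <- function(x, ...) {
  cat(sprintf("<lca_prune: %d retained, %d removed (%.0f%% Wald CIs)>\n",
              length(x$retained), length(x$removed), 100 * x$conf_level))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$removed)) cat("removed: ", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Mixture-implied versus observed indicator marginals
#'
#' The fitted model implies marginal category proportions
#' \eqn{\sum_k \pi_k \rho_{jkc}}; comparing these with the observed
#' proportions is a quick coherence check of the measurement model (for a
#' one-class model the two agree exactly).
#'
#' @param fit A fitted [fit_lca()].
#' @param data Survey data; when omitted, only implied marginals are
#'   returned.
#' @return A tibble with `indicator`, `category`, `implied`, `observed`,
#'   `abs_dev`.
#' @export
mixture_marginal_check <- function(fit, data = NULL) {
  implied <- apply(fit$rho, c(1, 3), function(rc) sum(fit$pi * rc))
  out <- tibble::as_tibble(as.data.frame.table(implied,
                                               responseName = "implied",
                                               stringsAsFactors = FALSE)) |>
    stats::setNames(c("indicator", "category", "implied"))
  if (!is.null(data)) {
    y <- encode_responses(data, fit$indicators, fit$categories)
    obs <- purrr::map_dfr(seq_along(fit$indicators), function(j) {
      yj <- y[, j]
      tibble::tibble(indicator = fit$indicators[j],
                     category = fit$categories,
                     observed = as.numeric(
                       table(factor(yj, levels = seq_along(fit$categories)))) /
                       sum(!is.na(yj)))
    })
    out <- dplyr::left_join(out, obs, by = c("indicator", "category")) |>
      dplyr::mutate(abs_dev = abs(.data$implied - .data$observed))
  }
  out
}
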