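#' Simulate a study-like survey dataset with known class labels
#'
#' Draws a complete synthetic survey from a [latrine_use_model()]:
#' household sizes from a zero-truncated Poisson, household covariates
#' (sanitation ladder, wall material, asset deprivation) and individual
#' covariates (sex, ethnicity, education, payment type, age) from the
#' study population's marginals, latent class per individual with optional
#' within-household concordance and an optional structural effect of basic
#' sanitation on class membership, indicator responses from the
#' class-conditional probabilities, and MCAR item nonresponse at the
#' model's configured rate.  Covariates are independent of class unless an
#' exposure effect is requested.  The true class labels are returned in a
#' `.true_class` column for recovery studies.
#'
#' @param model A [latrine_use_model()].
#' @param n_households Number of households (default 98, the study scale,
#'   giving about 251 individuals).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A validated survey tibble plus `.true_class` (1 = consistent
#'   class) and `basic_sanitation`.
#' @export
generate_survey <- function(model, n_households = 98, seed = NULL) {
  if (model$concordance < 0 || model$concordance > 1) {
    rlang::abort("concordance must lie in [0, 1]")
  }
  with_seed_if(seed, {
    lambda <- model$household_lambda
    sizes <- stats::qpois(stats::runif(n_households,
                                       stats::ppois(0, lambda), 1), lambda)
    n <- sum(sizes)
    hh <- rep(sprintf("hh%03d", seq_len(n_households)), sizes)

    cm <- model$covariate_marginals
    draw_cat <- function(probs, n_draw) {
      lev <- names(probs)
      out <- sample(lev, n_draw, replace = TRUE, prob = probs)
      out[out == "missing"] <- NA
      out
    }
    # household-level attributes, shared by all members
    hh_san <- draw_cat(cm$sanitation, n_households)
    hh_walls <- draw_cat(cm$cement_walls, n_households)
    hh_asset <- draw_cat(cm$asset_deprived, n_households)
    basic_h <- as.integer(hh_san == "basic")

    # class-1 probability per household: intercept solved so the marginal
    # prevalence equals pi1 whatever the exposure effect
    beta <- model$exposure_log_or
    p_basic <- unname(cm$sanitation["basic"])
    alpha <- if (beta == 0) stats::qlogis(model$pi[1]) else {
      stats::uniroot(function(a) {
        (1 - p_basic) * stats::plogis(a) + p_basic * stats::plogis(a + beta) -
          model$pi[1]
      }, c(-20, 20))$root
    }
    p1_h <- stats::plogis(alpha + beta * ifelse(is.na(basic_h), 0, basic_h))

    # within-household concordance: an individual inherits the household
    # class draw with probability sqrt(concordance), giving pairwise
    # class correlation equal to `concordance`
    kappa <- sqrt(model$concordance)
    hh_class <- ifelse(stats::runif(n_households) < p1_h, 1L, 2L)
    own_class <- ifelse(stats::runif(n) < p1_h[rep(seq_len(n_households), sizes)],
                        1L, 2L)
    inherit <- stats::runif(n) < kappa
    cls <- ifelse(inherit, hh_class[rep(seq_len(n_households), sizes)],
                  own_class)

    y <- matrix(NA_integer_, n, length(model$indicators))
    for (j in seq_along(model$indicators)) {
      u <- stats::runif(n)
      cum <- t(apply(matrix(model$rho[j, , ], nrow = 2), 1L, cumsum))
      y[, j] <- pmin(1L + rowSums(u > cum[cls, , drop = FALSE] + 1e-15),
                     length(model$categories))
    }
    if (model$missing_rate > 0) {
      y[matrix(stats::runif(length(y)) < model$missing_rate, n)] <- NA_integer_
    }

    age <- pmin(floor(13 + stats::rexp(n, 1 / 14)), 90)
    out <- tibble::tibble(
      individual_id = sprintf("ind%04d", seq_len(n)),
      household_id = hh)
    for (j in seq_along(model$indicators)) {
      out[[model$indicators[j]]] <- model$categories[y[, j]]
    }
    noise_ids <- setdiff(default_codebook()$indicators$id, model$indicators)
    for (id in noise_ids) out[[id]] <- NA_character_
    out$age <- age
    out$sex <- draw_cat(cm$sex, n)
    out$ethnicity <- draw_cat(cm$ethnicity, n)
    out$education <- draw_cat(cm$education, n)
    out$payment_type <- draw_cat(cm$payment_type, n)
    rep_h <- rep(seq_len(n_households), sizes)
    out$cement_walls <- hh_walls[rep_h]
    out$asset_deprived <- hh_asset[rep_h]
    out$sanitation <- hh_san[rep_h]
    out <- as_survey(out)
    out <- binarize_sanitation(out)
    out$.true_class <- cls
    out
  })
}

#' Simulate indicator responses from a fitted or reference model
#'
#' Parametric-bootstrap generator: draws `n` complete responders from
#' `(pi, rho)` only — no households, no covariates.  Used by the
#' goodness-of-fit bootstrap and by parameter-recovery studies.
#'
#' @param fit An [fit_lca()] object or a [latrine_use_model()].
#' @param n Number of individuals (0 gives an empty tibble with the
#'   indicator columns).
#' @param seed Integer seed.
#' @return A tibble of indicator factor columns.
#' @export
generate_from_fit <- function(fit, n, seed = NULL) {
  pi <- fit$pi
  rho <- fit$rho
  indicators <- if (inherits(fit, "lca_fit")) fit$indicators else fit$indicators
  categories <- fit$categories
  y <- if (n > 0) {
    with_seed_if(seed, simulate_patterns(pi, rho, n))
  } else {
    matrix(integer(0), 0, length(indicators))
  }
  out <- tibble::as_tibble(stats::setNames(
    lapply(seq_along(indicators), function(j) {
      factor(categories[y[, j]], levels = categories)
    }), indicators))
  out
}
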