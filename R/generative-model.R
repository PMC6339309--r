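# Reference quantities for the rural-Ecuador latrine-use study population:
# the modal class-conditional response probabilities of the final
# two-class, five-indicator model (with their standard errors) and the
# class prevalences.  Together with the observed indicator marginals these
# determine the full generative model up to printed rounding.
latuse_printed_conditionals <- function() {
  tibble::tribble(
    ~id,                  ~class, ~category,   ~value, ~se,
    "men_dry_season",      1L,    "agree",      0.85,  0.03,
    "men_dry_season",      2L,    "dont_know",  0.53,  0.11,
    "neighbors_rainy",     1L,    "agree",      1.00,  0.00,
    "neighbors_rainy",     2L,    "dont_know",  0.57,  0.11,
    "children_rainy",      1L,    "agree",      0.96,  0.02,
    "children_rainy",      2L,    "agree",      0.60,  0.08,
    "household_crowding",  1L,    "disagree",   0.52,  0.03,
    "household_crowding",  2L,    "disagree",   0.70,  0.07,
    "neighbors_latrine",   1L,    "agree",      0.90,  0.02,
    "neighbors_latrine",   2L,    "agree",      0.71,  0.07
  )
}

LATUSE_REFERENCE_PI <- c(0.78, 0.22)

# Table-1-style covariate marginals for the study population (proportions
# over all respondents, missing included), used by the survey generator
latuse_covariate_marginals <- function() {
  norm <- function(x) x / sum(x)
  list(
    sex = norm(c(female = 162, male = 89)),
    ethnicity = norm(c(afro_ecuadorian = 157, mestizo_other = 33, chachi = 61)),
    education = norm(c(less_than_primary = 63, primary = 51,
                       less_than_secondary = 90, secondary = 43,
                       missing = 4)),
    payment_type = norm(c(solely_cash = 118, cash_and_kind = 16,
                          not_paid = 41, not_employed = 76)),
    cement_walls = norm(c(yes = 115, no = 128, missing = 8)),
    asset_deprived = norm(c(yes = 152, no = 98, missing = 1)),
    sanitation = norm(c(basic = 132, shared = 83, unimproved = 13,
                        none = 22, missing = 2))
  )
}

#' Complete class-conditional probabilities from marginals and modal values
#'
#' The full J x K x C response-probability array of a two-class model is
#' recoverable from published summaries: the per-indicator marginal
#' category proportions, one modal conditional probability per class, and
#' the class prevalences, through the mixture constraints
#' \eqn{m_{jc} = \sum_k \pi_k \rho_{jkc}} plus the per-class sum-to-one
#' constraints.  When the two printed conditionals concern the same
#' category the system is underdetermined by one degree of freedom and the
#' minimum-norm least-squares completion is used.  Marginal rows are
#' normalized to sum to one before solving; a printed value at 1.00 fixes
#' its class row to a point mass.  Small negative solutions produced by
#' printed rounding are clipped to zero and the class row renormalized;
#' larger infeasibilities raise an error.
#'
#' @param marginals A tibble with columns `id`, `agree`, `disagree`,
#'   `dont_know` (defaults to the instrument table restricted to the five
#'   final indicators).
#' @param printed A tibble `id`, `class`, `category`, `value` of modal
#'   conditionals (one per class per indicator).
#' @param pi Class prevalences (larger class first).
#' @param clip_tol Largest negative solution treated as rounding noise.
#' @return A list: `rho` (J x 2 x C array), `pi`, `residuals` (per
#'   indicator, the largest absolute deviation of the implied marginal
#'   from the input marginal), `clipped` (ids where clipping occurred).
#' @export
reconstruct_generative_params <- function(marginals = NULL, printed = NULL,
                                          pi = LATUSE_REFERENCE_PI,
                                          clip_tol = 0.03) {
  if (is.null(printed)) printed <- latuse_printed_conditionals()
  if (is.null(marginals)) {
    marginals <- dplyr::filter(latuse_indicator_table(),
                               .data$id %in% unique(printed$id))
  }
  stopifnot(length(pi) == 2, abs(sum(pi) - 1) < 1e-8)
  categories <- LATUSE_CATEGORIES
  ids <- marginals$id
  rho <- array(NA_real_, dim = c(length(ids), 2, length(categories)),
               dimnames = list(ids, c("class1", "class2"), categories))
  resid <- numeric(length(ids))
  clipped <- character(0)

  for (i in seq_along(ids)) {
    m <- as.numeric(marginals[i, categories])
    m <- m / sum(m)
    r <- matrix(NA_real_, 2, length(categories))
    pr <- dplyr::filter(printed, .data$id == ids[i])
    if (nrow(pr) == 0) {
      rlang::abort(sprintf("no printed conditionals for indicator `%s`", ids[i]))
    }
    for (q in seq_len(nrow(pr))) {
      r[pr$class[q], match(pr$category[q], categories)] <- pr$value[q]
    }
    # a printed boundary value pins the whole class row
    for (cl in 1:2) {
      hit <- which(!is.na(r[cl, ]) & r[cl, ] >= 0.995)
      if (length(hit) == 1) {
        r[cl, ] <- 0
        r[cl, hit] <- 1
      }
    }
    # nonnegative completion: solve, pin negative unknowns to zero,
    # re-solve the remainder (active-set style)
    unknown <- is.na(r)
    for (pass in 1:6) {
      r_try <- solve_mixture_row(r, m, pi)
      neg <- unknown & r_try < -1e-9
      if (!any(neg)) {
        r <- r_try
        break
      }
      clipped <- unique(c(clipped, ids[i]))
      r[neg] <- 0            # pin at the boundary, re-solve the rest
      unknown <- unknown & !neg
    }
    r[r < 0] <- 0
    r <- r / rowSums(r)
    rho[i, , ] <- r
    resid[i] <- max(abs(as.numeric(pi %*% r) - m))
    if (resid[i] > clip_tol) {
      rlang::abort(sprintf(
        "reconstruction infeasible for indicator `%s` (implied-marginal residual %.3f exceeds tolerance %.2f)",
        ids[i], resid[i], clip_tol), class = "latuse_reconstruction_error")
    }
  }
  list(rho = rho, pi = stats::setNames(pi, c("class1", "class2")),
       residuals = tibble::tibble(id = ids, max_abs_dev = resid),
       clipped = clipped)
}

# least-squares completion of one indicator's 2 x C conditional matrix
# under the row-sum and mixture constraints; known entries enter the
# right-hand side, unknowns are solved minimum-norm via the pseudoinverse
solve_mixture_row <- function(r, m, pi) {
  unknown <- which(is.na(r))
  if (length(unknown) == 0) return(r)
  n_cat <- ncol(r)
  eqs <- list()
  rhs <- numeric(0)
  add_eq <- function(coef_mat, target) {
    known_part <- sum(coef_mat[!is.na(r)] * r[!is.na(r)])
    coefs <- coef_mat[unknown]
    if (all(coefs == 0)) return(invisible(NULL))
    eqs[[length(eqs) + 1L]] <<- coefs
    rhs[length(rhs) + 1L] <<- target - known_part
    invisible(NULL)
  }
  for (cl in 1:2) {  # row sums
    cm <- matrix(0, 2, n_cat); cm[cl, ] <- 1
    add_eq(cm, 1)
  }
  for (cc in seq_len(n_cat)) {  # mixture constraints
    cm <- matrix(0, 2, n_cat); cm[, cc] <- pi
    add_eq(cm, m[cc])
  }
  a <- do.call(rbind, eqs)
  x <- as.numeric(MASS::ginv(a) %*% rhs)
  r[unknown] <- x
  r
}

#' The reference two-class generative model of latrine use
#'
#' Assembles the full generative model the synthetic-data tools simulate
#' from: class prevalences (0.78 consistent, 0.22 inconsistent), the
#' reconstructed three-category conditional response probabilities of the
#' five informative indicators (see
#' [reconstruct_generative_params()]), the study population's covariate
#' marginals, a zero-truncated-Poisson household-size distribution
#' calibrated to 251 individuals in 98 households, a within-household
#' class-concordance parameter, and an (off by default) structural
#' exposure effect of basic sanitation on class membership.
#'
#' @param include_noise Also generate the eleven pruned indicators as
#'   class-independent noise with the instrument's marginal proportions
#'   (their true conditionals were never published).
#' @param concordance Pairwise within-household correlation of class
#'   membership (implemented by giving each individual probability
#'   `sqrt(concordance)` of inheriting a household-level class draw, which
#'   preserves the marginal prevalence exactly).
#' @param exposure_log_or Log odds ratio of basic sanitation on
#'   consistent-class membership; 0 reproduces the null structure of the
#'   study population.
#' @param missing_rate MCAR item-nonresponse probability per indicator.
#' @param mean_household_size Expected individuals (>= 13 y) per household.
#' @return A `latuse_model` object usable by [generate_survey()] and
#'   [generate_from_fit()].
#' @export
latrine_use_model <- function(include_noise = FALSE, concordance = 0.3,
                              exposure_log_or = 0, missing_rate = 0,
                              mean_household_size = 251 / 98) {
  rec <- reconstruct_generative_params()
  rho <- rec$rho
  indicators <- dimnames(rho)[[1]]
  if (include_noise) {
    tab <- latuse_indicator_table()
    noise_ids <- setdiff(tab$id, indicators)
    full <- array(NA_real_, dim = c(nrow(tab), 2, 3),
                  dimnames = list(tab$id, c("class1", "class2"),
                                  LATUSE_CATEGORIES))
    for (id in noise_ids) {
      m <- as.numeric(tab[tab$id == id, LATUSE_CATEGORIES])
      m <- m / sum(m)
      full[id, 1, ] <- m
      full[id, 2, ] <- m
    }
    full[indicators, , ] <- rho
    rho <- full
    indicators <- tab$id
  }
  # zero-truncated Poisson rate with the requested truncated mean
  lambda <- stats::uniroot(function(l) l / (1 - exp(-l)) - mean_household_size,
                           c(1e-6, 50))$root
  structure(list(
    pi = rec$pi, rho = rho, indicators = indicators,
    categories = LATUSE_CATEGORIES,
    covariate_marginals = latuse_covariate_marginals(),
    household_lambda = lambda,
    concordance = concordance, exposure_log_or = exposure_log_or,
    missing_rate = missing_rate,
    reconstruction = rec["residuals"]
  ), class = "latuse_model")
}

#' @export
print.latuse_model <- function(x, ...) {
  cat(sprintf("<latuse_model: %d indicators, pi = (%.2f, %.2f), concordance %.2f, exposure log-OR %.2f>\n",
              length(x$indicators), x$pi[1], x$pi[2], x$concordance,
              x$exposure_log_or))
  invisible(x)
}
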