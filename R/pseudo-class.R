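#' Pseudo-class draws of latent class membership
#'
#' Classification is uncertain, so a single modal assignment understates
#' the variance of any downstream model.  The pseudo-class approach
#' imputes membership M times: for each individual and imputation, a
#' uniform draw is inverted through the individual's posterior
#' class-membership probabilities (the smallest class index whose
#' cumulative posterior reaches the draw).  Over many draws the per-class
#' frequency of each individual reproduces their posterior.
#'
#' @param fit An [fit_lca()] object, or an N x K posterior matrix.
#' @param m Number of imputations (default 5).
#' @param seed Integer seed; the draw matrix is fully reproducible from it.
#' @return A `pseudo_class_draws` object with `draws` (N x M integer
#'   matrix), `modal` (most frequent label per individual, ties broken
#'   toward the lower label), `tie` (logical flag per individual), `m`,
#'   `seed`.
#' @export
draw_pseudo_classes <- function(fit, m = 5, seed = NULL) {
  tau <- if (inherits(fit, "lca_fit")) fit$tau else as.matrix(fit)
  stopifnot(m >= 1)
  assert_prob_rows(tau, what = "tau")
  n <- nrow(tau)
  k <- ncol(tau)
  cum <- t(apply(tau, 1L, cumsum))
  draws <- with_seed_if(seed, {
    u <- matrix(stats::runif(n * m), n, m)
    d <- matrix(1L, n, m)
    for (kk in seq_len(k - 1L)) {
      d <- d + (u > cum[, kk])
    }
    d
  })
  out <- structure(list(draws = draws, m = m, k = k, seed = seed),
                   class = "pseudo_class_draws")
  md <- modal_membership(out)
  out$modal <- md$label
  out$tie <- md$tie
  out
}

#' Modal class membership across pseudo-class imputations
#'
#' @param draws A [draw_pseudo_classes()] object or an N x M label matrix.
#' @return A tibble with `label` (most frequent class per individual; ties
#'   broken toward the lower label index) and `tie` (whether a tie
#'   occurred — impossible for K = 2 with odd M).
#' @export
modal_membership <- function(draws) {
  d <- if (inherits(draws, "pseudo_class_draws")) draws$draws else as.matrix(draws)
  k <- max(d)
  counts <- vapply(seq_len(k), function(kk) rowSums(d == kk),
                   numeric(nrow(d)))
  counts <- matrix(counts, nrow = nrow(d))
  label <- max.col(counts, ties.method = "first")
  top <- counts[cbind(seq_len(nrow(d)), label)]
  tie <- rowSums(counts == top) > 1
  tibble::tibble(label = as.integer(label), tie = tie)
}

#' @export
print.pseudo_class_draws <- function(x, ...) {
  cat(sprintf("<pseudo_class_draws: N = %d, M = %d, K = %d; %d tie(s)>\n",
              nrow(x$draws), x$m, x$k, sum(x$tie)))
  invisible(x)
}

#' Class composition by background characteristics
#'
#' Proportion of each demographic stratum assigned (modally) to class 1 —
#' in the latrine-use model, the consistent-user class — with binomial
#' standard errors `sqrt(p (1 - p) / n)`.
#'
#' @param data Survey tibble.
#' @param labels Integer class labels aligned with `data` rows (e.g. the
#'   `modal` component of [draw_pseudo_classes()]).
#' @param age_breaks Cut points for the age strata.
#' @return A tibble `variable`, `category`, `proportion`, `se`, `n`; empty
#'   strata report `n = 0` and an undefined (`NA`) proportion.
#' @export
class_by_demographics <- function(data, labels,
                                  age_breaks = c(13, 18, 22, 27, 37, Inf),
                                  codebook = default_codebook()) {
  stopifnot(length(labels) == nrow(data))
  in_class1 <- as.integer(labels == 1L)
  age_lab <- paste0(age_breaks[-length(age_breaks)], "-",
                    c(age_breaks[-c(1, length(age_breaks))] - 1, "max"))
  strata <- list(age_group = as.character(cut(data$age, breaks = age_breaks,
                                              labels = age_lab, right = FALSE)))
  for (cv in names(codebook$covariates)) {
    strata[[cv]] <- as.character(data[[cv]])
  }
  purrr::imap_dfr(strata, function(x, nm) {
    levs <- if (nm == "age_group") age_lab else codebook$covariates[[nm]]
    purrr::map_dfr(levs, function(lv) {
      idx <- which(!is.na(x) & x == lv)
      n <- length(idx)
      p <- if (n > 0) mean(in_class1[idx]) else NA_real_
      tibble::tibble(variable = nm, category = lv, proportion = p,
                     se = if (n > 0) sqrt(p * (1 - p) / n) else NA_real_,
                     n = n)
    })
  })
}
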