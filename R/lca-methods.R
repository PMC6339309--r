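#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Broom-style accessors for fitted latent class models
#'
#' `tidy()` returns one row per (indicator, class, category) with the
#' conditional response probability, its standard error and a boundary
#' flag; `glance()` returns the one-row fit summary; `augment()` appends
#' posterior class probabilities and the modal class to the data the model
#' was fitted to.
#'
#' @param x,object An [fit_lca()] object.
#' @param data For `augment()`, the data to append to (defaults to a
#'   tibble of posteriors only).
#' @param ... Unused.
#' @export
tidy.lca_fit <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame.table(x$rho, responseName = "estimate",
                                               stringsAsFactors = FALSE)) |>
    stats::setNames(c("indicator", "class", "category", "estimate"))
  if (!is.null(x$se_rho)) {
    se_tab <- tibble::as_tibble(as.data.frame.table(x$se_rho,
                                                    responseName = "std.error",
                                                    stringsAsFactors = FALSE)) |>
      stats::setNames(c("indicator", "class", "category", "std.error"))
    bd_tab <- tibble::as_tibble(as.data.frame.table(x$boundary,
                                                    responseName = "boundary",
                                                    stringsAsFactors = FALSE)) |>
      stats::setNames(c("indicator", "class", "category", "boundary"))
    out <- out |>
      dplyr::left_join(se_tab, by = c("indicator", "class", "category")) |>
      dplyr::left_join(bd_tab, by = c("indicator", "class", "category"))
  }
  out
}

#' @rdname tidy.lca_fit
#' @export
glance.lca_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, n_indicators = length(x$indicators),
                 loglik = x$loglik, n_params = x$n_params, bic = x$bic,
                 rel_entropy = x$rel_entropy,
                 x2 = x$x2 %||% NA_real_, gof_p = x$gof_p %||% NA_real_,
                 n_patterns = x$n_patterns, n_iter = x$n_iter,
                 converged = x$converged)
}

#' @rdname tidy.lca_fit
#' @export
augment.lca_fit <- function(x, data = NULL, ...) {
  tau <- tibble::as_tibble(as.data.frame(x$tau))
  names(tau) <- paste0(".posterior_", names(x$pi))
  tau$.class <- max.col(x$tau, ties.method = "first")
  if (is.null(data)) return(tau)
  stopifnot(nrow(data) == nrow(tau))
  dplyr::bind_cols(tibble::as_tibble(data), tau)
}

#' Serialize and restore a fitted latent class model as JSON
#'
#' Stores estimates, standard errors, fit statistics and the fitting
#' configuration with full numeric precision, so every report table is
#' regenerable from the artifact without refitting.  Posteriors are not
#' stored; recompute them from the data with [posterior()].
#'
#' @param fit An [fit_lca()] object.
#' @param path Output path (`.json`).
#' @return `read_lca_fit()` returns an `lca_fit` object (without `tau` and
#'   pattern internals).
#' @export
write_lca_fit <- function(fit, path) {
  flat <- function(a) if (is.null(a)) NULL else as.numeric(a)
  payload <- list(
    pi = as.list(fit$pi),
    rho = flat(fit$rho), se_rho = flat(fit$se_rho),
    se_pi = if (is.null(fit$se_pi)) NULL else as.numeric(fit$se_pi),
    boundary = flat(fit$boundary),
    loglik = fit$loglik, n_params = fit$n_params, bic = fit$bic,
    rel_entropy = fit$rel_entropy, x2 = fit$x2, gof_p = fit$gof_p,
    k = fit$k, n = fit$n, indicators = as.list(fit$indicators),
    categories = as.list(fit$categories), n_patterns = fit$n_patterns,
    seed = fit$seed, se_method = fit$se_method,
    start_logliks = fit$start_logliks
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_lca_fit
#' @export
read_lca_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- c(length(p$indicators), p$k, length(p$categories))
  dnames <- list(p$indicators, names(p$pi), p$categories)
  to_arr <- function(a) {
    if (is.null(a)) return(NULL)
    array(as.numeric(a), dim = dims, dimnames = dnames)
  }
  structure(list(
    pi = unlist(p$pi), rho = to_arr(p$rho), se_rho = to_arr(p$se_rho),
    se_pi = if (is.null(p$se_pi)) NULL else
      stats::setNames(as.numeric(p$se_pi), names(p$pi)),
    boundary = if (is.null(p$boundary)) NULL else to_arr(p$boundary) > 0,
    loglik = p$loglik, n_params = p$n_params, bic = p$bic,
    rel_entropy = p$rel_entropy, x2 = p$x2, gof_p = p$gof_p,
    k = p$k, n = p$n, indicators = p$indicators, categories = p$categories,
    n_patterns = p$n_patterns, seed = p$seed, se_method = p$se_method,
    start_logliks = p$start_logliks, converged = TRUE, tau = NULL
  ), class = "lca_fit")
}
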