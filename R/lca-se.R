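# Standard errors for the latent class model.
#
# Works in an unconstrained parameterization: a (K-1)-dimensional softmax
# for the prevalences and, per (indicator, class), a softmax over the
# categories not estimated at the boundary.  Scores and the observed-data
# Hessian are analytic: with s_ik the complete-data score of class k,
#   grad l_i = sum_k tau_ik s_ik
#   hess l_i = sum_k tau_ik (D_ik + s_ik s_ik') - grad l_i grad l_i'
# (a Louis-type identity), which keeps the computation a single pass over
# the distinct response patterns.

BOUNDARY_TOL <- 1e-6

build_param_map <- function(pi, rho, btol = BOUNDARY_TOL) {
  k <- length(pi)
  n_item <- dim(rho)[1]
  n_cat <- dim(rho)[3]
  idx <- 0L
  alpha_idx <- if (k >= 2) seq_len(k - 1L) else integer(0)
  idx <- length(alpha_idx)
  items <- vector("list", n_item * k)
  for (j in seq_len(n_item)) {
    for (cl in seq_len(k)) {
      active <- which(rho[j, cl, ] > btol)
      n_free <- max(length(active) - 1L, 0L)
      par_idx <- if (n_free > 0) idx + seq_len(n_free) else integer(0)
      idx <- idx + n_free
      items[[(j - 1L) * k + cl]] <- list(j = j, cl = cl, active = active,
                                         par_idx = par_idx)
    }
  }
  list(alpha_idx = alpha_idx, items = items, n_par = idx,
       k = k, n_item = n_item, n_cat = n_cat)
}

# observed-data Hessian and per-pattern scores in the free parameterization
lca_score_hessian <- function(patterns, pi, rho, map) {
  p <- patterns$p
  w <- patterns$w
  n_pat <- nrow(p)
  k <- map$k
  n_par <- map$n_par
  e <- lca_estep(p, pi, rho)
  tau <- e$tau

  hess <- matrix(0, n_par, n_par)
  scores <- matrix(0, n_pat, n_par)

  # curvature of the complete-data log-density, accumulated in closed form:
  # the alpha block is pattern-independent; each (j, class) block enters
  # with total weight sum over patterns observing j of w * tau.
  if (k >= 2) {
    pi_f <- pi[-1]
    d_alpha <- -(diag(pi_f, nrow = k - 1L) - tcrossprod(pi_f))
    hess[map$alpha_idx, map$alpha_idx] <- sum(w) * d_alpha
  }
  for (it in map$items) {
    if (length(it$par_idx) == 0) next
    obs <- which(!is.na(p[, it$j]))
    w_eff <- sum(w[obs] * tau[obs, it$cl])
    r_free <- rho[it$j, it$cl, it$active[-1]]
    block <- -(diag(r_free, nrow = length(r_free)) - tcrossprod(r_free))
    hess[it$par_idx, it$par_idx] <-
      hess[it$par_idx, it$par_idx] + w_eff * block
  }

  # score terms per pattern
  for (pp in seq_len(n_pat)) {
    g <- numeric(n_par)
    outer_acc <- matrix(0, n_par, n_par)
    for (cl in seq_len(k)) {
      s <- numeric(n_par)
      if (k >= 2) {
        s[map$alpha_idx] <- as.numeric(seq_len(k)[-1] == cl) - pi[-1]
      }
      for (j in seq_len(ncol(p))) {
        yj <- p[pp, j]
        if (is.na(yj)) next
        it <- map$items[[(j - 1L) * k + cl]]
        if (length(it$par_idx) == 0) next
        free_cats <- it$active[-1]
        s[it$par_idx] <- as.numeric(free_cats == yj) - rho[j, cl, free_cats]
      }
      g <- g + tau[pp, cl] * s
      outer_acc <- outer_acc + tau[pp, cl] * tcrossprod(s)
    }
    scores[pp, ] <- g
    hess <- hess + w[pp] * (outer_acc - tcrossprod(g))
  }
  list(hess = hess, scores = scores, tau = tau)
}

#' Standard errors for a fitted latent class model
#'
#' @param fit A converged [fit_lca()] object.
#' @param method `"observed_information"` inverts the analytic
#'   observed-data Hessian; `"sandwich"` is the cluster-robust estimator
#'   aggregating scores within clusters (households), with the small-sample
#'   factor G/(G-1).  With no `cluster` supplied the sandwich treats each
#'   individual as its own cluster, i.e. plain heteroskedasticity-robust.
#' @param cluster Cluster id vector aligned with the fitting data rows.
#' @return The fit with `se_pi`, `se_rho` and a logical `boundary` array
#'   filled in.  Probabilities estimated at the boundary (0 or 1) get
#'   standard error 0 and `boundary = TRUE`.
#' @export
estimate_ses <- function(fit, method = c("observed_information", "sandwich"),
                         cluster = NULL) {
  method <- match.arg(method)
  if (!isTRUE(fit$converged)) rlang::abort("fit did not converge")
  map <- build_param_map(fit$pi, fit$rho)
  sh <- lca_score_hessian(fit$patterns, fit$pi, fit$rho, map)
  info <- -sh$hess
  vcov_theta <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vcov_theta)) {
    diag_names <- describe_params(map, fit)
    bad <- which(abs(diag(info)) < 1e-10)
    rlang::abort(sprintf(
      "singular information matrix%s",
      if (length(bad) > 0) paste0(" (flat block: ",
                                  paste(diag_names[bad], collapse = ", "), ")")
      else ""), class = "latuse_singular_information")
  }
  if (method == "sandwich") {
    g_ind <- sh$scores[fit$patterns$index, , drop = FALSE]
    if (is.null(cluster)) cluster <- seq_len(nrow(g_ind))
    g_cl <- rowsum(g_ind, group = as.character(cluster))
    n_cl <- nrow(g_cl)
    if (n_cl < 2) rlang::abort("sandwich standard errors need >= 2 clusters")
    meat <- crossprod(g_cl) * n_cl / (n_cl - 1)
    vcov_theta <- vcov_theta %*% meat %*% vcov_theta
  }

  k <- fit$k
  n_cat <- length(fit$categories)
  se_pi <- rep(0, k)
  if (k >= 2) {
    jac <- matrix(0, k, k - 1L)
    for (kk in seq_len(k)) {
      for (m in seq_len(k - 1L)) {
        jac[kk, m] <- fit$pi[kk] * ((kk == m + 1L) - fit$pi[m + 1L])
      }
    }
    se_pi <- sqrt(pmax(diag(jac %*% vcov_theta[map$alpha_idx, map$alpha_idx,
                                               drop = FALSE] %*% t(jac)), 0))
  }
  names(se_pi) <- names(fit$pi)

  se_rho <- array(0, dim = dim(fit$rho), dimnames = dimnames(fit$rho))
  boundary <- fit$rho <= BOUNDARY_TOL | fit$rho >= 1 - BOUNDARY_TOL
  for (it in map$items) {
    if (length(it$par_idx) == 0) next
    act <- it$active
    r_act <- fit$rho[it$j, it$cl, act]
    jac <- matrix(0, length(act), length(act) - 1L)
    for (a in seq_along(act)) {
      for (b in seq_len(length(act) - 1L)) {
        jac[a, b] <- r_act[a] * ((a == b + 1L) - r_act[b + 1L])
      }
    }
    v <- vcov_theta[it$par_idx, it$par_idx, drop = FALSE]
    se_rho[it$j, it$cl, act] <- sqrt(pmax(diag(jac %*% v %*% t(jac)), 0))
  }
  se_rho[boundary] <- 0

  fit$se_pi <- se_pi
  fit$se_rho <- se_rho
  fit$boundary <- boundary
  fit$se_method <- method
  fit$vcov_theta <- vcov_theta
  fit
}

describe_params <- function(map, fit) {
  out <- character(map$n_par)
  if (length(map$alpha_idx) > 0) {
    out[map$alpha_idx] <- paste0("pi[", seq_along(map$alpha_idx) + 1L, "]")
  }
  for (it in map$items) {
    if (length(it$par_idx) == 0) next
    out[it$par_idx] <- paste0("rho[", fit$indicators[it$j], ",class", it$cl,
                              ",", fit$categories[it$active[-1]], "]")
  }
  out
}

# full log-likelihood as a function of the free parameter vector; used by
# tests to cross-check the analytic Hessian against numeric differentiation
lca_loglik_theta <- function(theta, map, patterns, pi0, rho0) {
  pi <- pi0
  rho <- rho0
  if (map$k >= 2) {
    a <- c(0, theta[map$alpha_idx])
    pi <- exp(a - max(a)) / sum(exp(a - max(a)))
  }
  for (it in map$items) {
    if (length(it$par_idx) == 0) next
    eta <- c(0, theta[it$par_idx])
    r <- exp(eta - max(eta)) / sum(exp(eta - max(eta)))
    rho[it$j, it$cl, ] <- 0
    rho[it$j, it$cl, it$active] <- r
  }
  e <- lca_estep(patterns$p, pi, rho)
  sum(patterns$w * e$lse)
}

theta_from_fit <- function(fit, map) {
  theta <- numeric(map$n_par)
  if (map$k >= 2) theta[map$alpha_idx] <- log(fit$pi[-1] / fit$pi[1])
  for (it in map$items) {
    if (length(it$par_idx) == 0) next
    r <- fit$rho[it$j, it$cl, it$active]
    theta[it$par_idx] <- log(r[-1] / r[1])
  }
  theta
}
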