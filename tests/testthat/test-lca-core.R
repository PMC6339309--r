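test_that("one-class fit reduces to observed category proportions", {
  sim <- generate_from_fit(latrine_use_model(), n = 300, seed = 21)
  fit <- fit_lca(sim, k = 1, n_starts = 3, seed = 1)
  expect_equal(unname(fit$pi), 1)
  expect_true(all(fit$tau == 1))
  expect_equal(fit$rel_entropy, 1)
  y <- table(sim$men_dry_season)
  expect_equal(unname(fit$rho["men_dry_season", 1, ]),
               unname(as.numeric(y) / sum(y)), tolerance = 1e-8)
  # K = 1 standard errors equal the multinomial closed form
  p_hat <- fit$rho["men_dry_season", 1, ]
  expect_equal(unname(fit$se_rho["men_dry_season", 1, ]),
               unname(sqrt(p_hat * (1 - p_hat) / 300)), tolerance = 1e-6)
})

test_that("EM log-likelihood is monotone and restarts agree at the optimum", {
  sim <- generate_from_fit(latrine_use_model(), n = 200, seed = 22)
  fit <- fit_lca(sim, k = 2, n_starts = 10, seed = 3, se_method = "none")
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  expect_true(fit$converged)
  # class labels are ordered by prevalence
  expect_true(all(diff(fit$pi) <= 0))
  # a different restart seed reaches the same maximum
  fit2 <- fit_lca(sim, k = 2, n_starts = 10, seed = 99, se_method = "none")
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-6)
})

test_that("best-restart EM attains the grid-search maximum on tiny instances", {
  set.seed(31)
  for (rep in 1:3) {
    y <- cbind(sample(1:2, 12, replace = TRUE), sample(1:2, 12, replace = TRUE))
    dat <- binary_indicator_tibble(y)
    fit <- fit_lca(dat, indicators = c("item_a", "item_b"), k = 2,
                   n_starts = 30, seed = rep, se_method = "none")
    oracle <- grid_loglik_max(y)
    expect_gte(fit$loglik, oracle - 1e-3)
  }
})

test_that("posterior follows Bayes' rule, and no data returns the prior", {
  rho <- array(c(0.8, 0.6, 0.3, 0.4, 0.2, 0.4, 0.7, 0.6), dim = c(2, 2, 2))
  dimnames(rho) <- list(c("i1", "i2"), c("class1", "class2"),
                        c("agree", "disagree"))
  fit <- fake_fit(pi = c(class1 = 0.6, class2 = 0.4), rho = rho,
                  categories = c("agree", "disagree"))
  nd <- tibble::tibble(i1 = c("agree", NA), i2 = c("disagree", NA))
  tau <- posterior(fit, nd)
  # hand Bayes: class1 0.6*0.8*0.2, class2 0.4*0.3*0.7
  p1 <- 0.6 * rho["i1", "class1", "agree"] * rho["i2", "class1", "disagree"]
  p2 <- 0.4 * rho["i1", "class2", "agree"] * rho["i2", "class2", "disagree"]
  expect_equal(tau$class1[1], p1 / (p1 + p2), tolerance = 1e-12)
  expect_equal(unlist(tau[2, ], use.names = FALSE), c(0.6, 0.4),
               tolerance = 1e-12)
  # deterministic signature pattern pins the class
  rho_det <- rho
  rho_det["i1", , ] <- c(1, 0, 0, 1)  # class1 always agree, class2 never
  fit_det <- fake_fit(pi = c(class1 = 0.5, class2 = 0.5), rho = rho_det,
                      categories = c("agree", "disagree"))
  tau_det <- posterior(fit_det, tibble::tibble(i1 = "agree", i2 = NA))
  expect_equal(unlist(tau_det, use.names = FALSE), c(1, 0))
  expect_error(posterior(fit, tibble::tibble(i1 = "maybe", i2 = NA)),
               class = "latuse_validation_error")
})

test_that("information criteria follow their closed forms", {
  expect_equal(compute_bic(0, 0, 10), 0)
  expect_equal(compute_bic(-100, 5, 100), 223.03, tolerance = 1e-3)
  expect_equal(n_params_lca(2, rep(3, 5)), 21)
  expect_equal(n_params_lca(1, rep(3, 16)), 32)
})

test_that("relative entropy spans separation extremes and is label-invariant", {
  perfect <- matrix(rep(c(1, 0), 5), ncol = 2, byrow = TRUE)
  expect_equal(relative_entropy(perfect), 1)
  flat <- matrix(0.5, 7, 2)
  expect_equal(relative_entropy(flat), 0)
  set.seed(4)
  tau <- matrix(stats::runif(40), 20, 2)
  tau <- tau / rowSums(tau)
  e <- relative_entropy(tau)
  expect_equal(relative_entropy(tau[sample(20), ]), e)
  expect_equal(relative_entropy(tau[, 2:1]), e)
  expect_error(relative_entropy(matrix(c(0.6, 0.6), 1, 2)), "sum to 1")
})

test_that("analytic observed information matches numeric differentiation", {
  sim <- generate_from_fit(latrine_use_model(), n = 150, seed = 23)
  fit <- fit_lca(sim, indicators = c("men_dry_season", "children_rainy"),
                 k = 2, n_starts = 10, seed = 5, se_method = "none")
  map <- latuse:::build_param_map(fit$pi, fit$rho)
  sh <- latuse:::lca_score_hessian(fit$patterns, fit$pi, fit$rho, map)
  theta <- latuse:::theta_from_fit(fit, map)
  h_num <- pracma::hessian(function(th) {
    latuse:::lca_loglik_theta(th, map, fit$patterns, fit$pi, fit$rho)
  }, theta)
  expect_equal(sh$hess, h_num, tolerance = 1e-4)
  # gradient is ~0 at the optimum
  g <- colSums(fit$patterns$w * sh$scores)
  expect_lt(max(abs(g)), 1e-4)
})

test_that("boundary estimates report zero SEs with a boundary flag", {
  # perfectly separated two-cluster data drives rho to 0/1
  y <- rbind(matrix(1L, 10, 2), matrix(2L, 8, 2))
  dat <- binary_indicator_tibble(y)
  fit <- fit_lca(dat, indicators = c("item_a", "item_b"), k = 2,
                 n_starts = 10, seed = 6)
  expect_true(any(fit$boundary))
  expect_true(all(fit$se_rho[fit$boundary] == 0))
  expect_equal(unname(fit$rho["item_a", "class1", "agree"]), 1, tolerance = 1e-6)
})

test_that("sandwich SEs with singleton households equal the unclustered form", {
  sim <- generate_from_fit(latrine_use_model(), n = 120, seed = 24)
  fit <- fit_lca(sim, k = 2, n_starts = 10, seed = 7, se_method = "none")
  a <- estimate_ses(fit, method = "sandwich", cluster = NULL)
  b <- estimate_ses(fit, method = "sandwich",
                    cluster = as.character(seq_len(120)))
  expect_equal(a$se_rho, b$se_rho, tolerance = 1e-12)
  expect_equal(a$se_pi, b$se_pi, tolerance = 1e-12)
})

test_that("identifiability and convergence failures raise typed errors", {
  y <- matrix(1L, 8, 2)  # a single response pattern
  dat <- binary_indicator_tibble(y)
  expect_error(fit_lca(dat, indicators = c("item_a", "item_b"), k = 2,
                       n_starts = 2, seed = 1),
               class = "latuse_identifiability_error")
  expect_error(fit_lca(fixture_survey(), k = 5, n_starts = 2, seed = 1))
})

test_that("Pearson X2 is zero at an exactly deterministic model", {
  y <- rbind(matrix(1L, 12, 2), matrix(2L, 9, 2))
  dat <- binary_indicator_tibble(y)
  fit <- fit_lca(dat, indicators = c("item_a", "item_b"), k = 2,
                 n_starts = 10, seed = 8, se_method = "none")
  gof <- pearson_gof(fit, dat, b = 0)
  expect_equal(gof$x2, 0, tolerance = 1e-6)
})

test_that("single-indicator X2 equals the classic one-way Pearson statistic", {
  counts <- c(agree = 30, disagree = 15, dont_know = 5)
  dat <- tibble::tibble(men_dry_season = rep(names(counts), counts))
  probs <- c(0.55, 0.35, 0.10)
  rho <- array(probs, dim = c(1, 1, 3),
               dimnames = list("men_dry_season", "class1",
                               c("agree", "disagree", "dont_know")))
  fit <- fake_fit(pi = c(class1 = 1), rho = rho)
  gof <- pearson_gof(fit, dat, b = 0)
  expected <- 50 * probs
  expect_equal(gof$x2, sum((counts - expected)^2 / expected), tolerance = 1e-10)
})

test_that("bootstrap p-value is well calibrated under the true model", {
  model <- latrine_use_model()
  set.seed(41)
  ps <- replicate(20, {
    sim <- generate_from_fit(model, n = 120)
    fit <- fit_lca(sim, k = 2, n_starts = 5, se_method = "none")
    pearson_gof(fit, sim, b = 39)$p_value
  })
  # under the null, p-values should not pile up near 0
  expect_gt(mean(ps > 0.05), 0.6)
  expect_gt(mean(ps), 0.25)
})

test_that("fitted models serialize to JSON and restore exactly", {
  sim <- generate_from_fit(latrine_use_model(), n = 150, seed = 25)
  fit <- fit_lca(sim, k = 2, n_starts = 5, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_lca_fit(fit, path)
  back <- read_lca_fit(path)
  expect_equal(back$pi, fit$pi, tolerance = 1e-12)
  expect_equal(back$rho, fit$rho, tolerance = 1e-12)
  expect_equal(back$se_rho, fit$se_rho, tolerance = 1e-12)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(back$bic, fit$bic, tolerance = 1e-12)
  expect_identical(back$indicators, fit$indicators)
})

test_that("tidy, glance and augment expose the fit in tabular form", {
  sim <- generate_from_fit(latrine_use_model(), n = 150, seed = 26)
  fit <- fit_lca(sim, k = 2, n_starts = 5, seed = 10)
  td <- tidy(fit)
  expect_equal(nrow(td), 5 * 2 * 3)
  expect_true(all(c("estimate", "std.error", "boundary") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_equal(gl$bic, fit$bic)
  aug <- augment(fit, sim)
  expect_equal(nrow(aug), 150)
  expect_true(all(aug$.class %in% 1:2))
})
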