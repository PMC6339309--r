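test_that("pseudo-class draws invert the posterior and are seed-reproducible", {
  tau <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  d1 <- draw_pseudo_classes(tau, m = 7, seed = 71)
  d2 <- draw_pseudo_classes(tau, m = 7, seed = 71)
  expect_identical(d1$draws, d2$draws)
  expect_true(all(d1$draws[1, ] == 1L))
  expect_true(all(d1$draws[2, ] == 2L))

  # marginal reproduction of tau over many draws
  big <- draw_pseudo_classes(rbind(c(0.5, 0.5)), m = 10000, seed = 72)
  expect_lt(abs(mean(big$draws == 1L) - 0.5), 0.015)

  set.seed(73)
  tau_r <- matrix(runif(30), 15, 2)
  tau_r <- tau_r / rowSums(tau_r)
  many <- draw_pseudo_classes(tau_r, m = 4000, seed = 74)
  freq1 <- rowMeans(many$draws == 1L)
  expect_lt(max(abs(freq1 - tau_r[, 1])), 0.05)
})

test_that("modal membership is the row mode with lower-label tie-breaking", {
  expect_equal(modal_membership(rbind(c(1, 1, 2, 1, 2)))$label, 1L)
  expect_equal(modal_membership(rbind(c(2, 2, 2, 2, 2)))$label, 2L)
  tie <- modal_membership(rbind(c(1, 2, 1, 2)))
  expect_equal(tie$label, 1L)
  expect_true(tie$tie)
  # odd M with two classes can never tie
  d <- draw_pseudo_classes(matrix(0.5, 50, 2), m = 5, seed = 75)
  expect_false(any(d$tie))
})

test_that("demographic class table has valid proportions and binomial SEs", {
  sim <- generate_survey(latrine_use_model(), n_households = 98, seed = 76)
  labels <- rep(1L, nrow(sim))
  tab <- class_by_demographics(sim, labels)
  expect_true(all(tab$proportion[tab$n > 0] == 1))
  labels2 <- sim$.true_class
  tab2 <- class_by_demographics(sim, labels2)
  ok <- tab2$n > 0
  expect_true(all(tab2$proportion[ok] >= 0 & tab2$proportion[ok] <= 1))
  expect_equal(tab2$se[ok],
               sqrt(tab2$proportion[ok] * (1 - tab2$proportion[ok]) / tab2$n[ok]))
  # overall class-1 share tracks the generating prevalence
  expect_lt(abs(mean(labels2 == 1L) - 0.78), 0.10)
})

test_that("unadjusted clustered logit equals the 2x2 log odds ratio", {
  # 40 exposed (28 events), 60 unexposed (30 events)
  dat <- tibble::tibble(
    y = c(rep(1, 28), rep(0, 12), rep(1, 30), rep(0, 30)),
    x = c(rep(1, 40), rep(0, 60)),
    household_id = as.character(1:100))
  fit <- fit_cluster_logit(dat, y ~ x)
  lor <- log((28 / 12) / (30 / 30))
  expect_equal(unname(fit$coef["x"]), lor, tolerance = 1e-6)
})

test_that("singleton clusters reduce the sandwich to the unclustered form", {
  set.seed(81)
  dat <- tibble::tibble(y = rbinom(80, 1, 0.5), x = rnorm(80),
                        household_id = as.character(1:80))
  fit <- fit_cluster_logit(dat, y ~ x, cadjust = FALSE)
  hc0 <- sandwich::vcovHC(fit$glm_fit, type = "HC0")
  expect_equal(unname(fit$vcov), unname(hc0), tolerance = 1e-10)
  # the cluster-count small-sample factor scales the meat by G/(G-1)
  fit_adj <- fit_cluster_logit(dat, y ~ x, cadjust = TRUE)
  expect_equal(unname(fit_adj$vcov), unname(hc0) * 80 / 79, tolerance = 1e-10)
})

test_that("separation and degenerate clustering raise typed errors", {
  dat <- tibble::tibble(y = c(rep(0, 20), rep(1, 20)),
                        x = c(rep(0, 20), rep(1, 20)),
                        household_id = rep(c("a", "b"), 20))
  expect_error(fit_cluster_logit(dat, y ~ x),
               class = "latuse_separation_error")
  one <- tibble::tibble(y = rbinom(30, 1, 0.5), x = rnorm(30),
                        household_id = rep("h1", 30))
  expect_error(fit_cluster_logit(one, y ~ x),
               class = "latuse_cluster_error")
})

test_that("Rubin pooling reproduces its closed forms", {
  mk <- function(b, v) {
    structure(list(coef = c(x = b), vcov = matrix(v, 1, 1, dimnames = list("x", "x")),
                   n_obs = 100, n_clusters = 40), class = "cluster_logit")
  }
  pooled <- pool_rubin(lapply(0:4, mk, v = 1))
  tab <- tidy(pooled)
  expect_equal(tab$estimate, 2)
  expect_equal(tab$w_bar, 1)
  expect_equal(tab$b, 2.5)
  expect_equal(tab$t_var, 1 + (1 + 1 / 5) * 2.5)  # = 4
  expect_equal(tab$t_var, 4)
  expect_true(tab$or.conf.low < exp(2) && exp(2) < tab$or.conf.high)

  # identical estimates: no between-imputation variance
  same <- pool_rubin(lapply(rep(1.3, 4), mk, v = 0.25))
  st <- tidy(same)
  expect_equal(st$b, 0)
  expect_equal(st$t_var, st$w_bar)
  expect_error(pool_rubin(list(mk(1, 1))), "M >= 2")
  bad <- mk(1, 1); names(bad$coef) <- "z"
  expect_error(pool_rubin(list(mk(1, 1), bad)), "mismatched")
})

test_that("total variance is monotone in the between-imputation spread", {
  mk <- function(b) structure(list(coef = c(x = b),
                                   vcov = matrix(1, 1, 1), n_obs = 50,
                                   n_clusters = 25), class = "cluster_logit")
  t_narrow <- tidy(pool_rubin(lapply(c(1, 1.1, 0.9, 1.05, 0.95), mk)))$t_var
  t_wide <- tidy(pool_rubin(lapply(c(0, 2, -1, 3, 1), mk)))$t_var
  expect_lt(t_narrow, t_wide)
  expect_gte(t_narrow, 1)  # T >= W-bar
})

test_that("the structural pipeline is deterministic and degenerates cleanly", {
  sim <- generate_survey(latrine_use_model(), n_households = 80, seed = 82)
  fit <- fit_lca(sim, indicators = final_indicators(), k = 2, n_starts = 8,
                 seed = 83, se_method = "none")
  r1 <- run_structural_pipeline(sim, fit, m = 5, seed = 84)
  r2 <- run_structural_pipeline(sim, fit, m = 5, seed = 84)
  expect_identical(tidy(r1$adjusted), tidy(r2$adjusted))
  expect_identical(r1$draws$draws, r2$draws$draws)

  # deterministic posteriors make all imputations identical: B = 0
  fit_det <- fit
  fit_det$tau <- (fit$tau >= 0.5) * 1
  r3 <- run_structural_pipeline(sim, fit_det, m = 5, seed = 85)
  expect_equal(max(tidy(r3$unadjusted)$b), 0)
  expect_equal(tidy(r3$unadjusted)$t_var, tidy(r3$unadjusted)$w_bar)
})

test_that("the pooled exposure OR recovers a built-in structural effect", {
  model <- latrine_use_model(exposure_log_or = log(2))
  sim <- generate_survey(model, n_households = 400, seed = 86)
  fit <- fit_lca(sim, indicators = final_indicators(), k = 2, n_starts = 10,
                 seed = 87, se_method = "none")
  res <- run_structural_pipeline(sim, fit, m = 5, seed = 88)
  tab <- dplyr::filter(tidy(res$unadjusted), term == "basic_sanitation")
  expect_true(tab$or.conf.low < 2 && 2 < tab$or.conf.high)
  expect_gt(tab$or, 1.3)
})
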