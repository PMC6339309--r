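test_that("reconstruction solves the exactly determined indicator by hand", {
  rec <- reconstruct_generative_params()
  r <- rec$rho["men_dry_season", , ]
  # hand solution of the mixture constraints at pi = (0.78, 0.22)
  expect_equal(unname(r["class2", "agree"]), 0.077, tolerance = 0.005)
  expect_equal(unname(r["class1", "disagree"]), 0.069, tolerance = 0.005)
  expect_equal(unname(r["class1", "dont_know"]), 0.081, tolerance = 0.005)
  expect_equal(unname(r["class2", "disagree"]), 0.393, tolerance = 0.005)
  # printed conditionals are preserved
  expect_equal(unname(r["class1", "agree"]), 0.85, tolerance = 1e-6)
  expect_equal(unname(r["class2", "dont_know"]), 0.53, tolerance = 1e-6)
})

test_that("reconstruction inverts an exactly consistent forward model", {
  pi0 <- c(0.7, 0.3)
  rho0 <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
  marg <- as.numeric(pi0 %*% rho0)
  marginals <- tibble::tibble(id = "toy", agree = marg[1], disagree = marg[2],
                              dont_know = marg[3])
  printed <- tibble::tibble(id = "toy", class = c(1L, 2L),
                            category = c("agree", "dont_know"),
                            value = c(0.7, 0.6))
  rec <- reconstruct_generative_params(marginals, printed, pi = pi0)
  expect_equal(unname(rec$rho["toy", , ]), unname(rho0), tolerance = 1e-8)
  expect_lt(rec$residuals$max_abs_dev, 1e-10)
})

test_that("a printed boundary value pins the whole class row", {
  rec <- reconstruct_generative_params()
  r1 <- rec$rho["neighbors_rainy", "class1", ]
  expect_equal(unname(r1), c(1, 0, 0))
  # rows are simplexes
  expect_equal(unname(apply(rec$rho, c(1, 2), sum)),
               matrix(1, 5, 2), tolerance = 1e-10)
  expect_true(all(rec$rho >= 0))
})

test_that("implied marginals stay within printed-rounding distance", {
  rec <- reconstruct_generative_params()
  expect_lt(max(rec$residuals$max_abs_dev), 0.02)
})

test_that("an infeasible printed system raises a reconstruction error", {
  marginals <- tibble::tibble(id = "bad", agree = 0.9, disagree = 0.05,
                              dont_know = 0.05)
  printed <- tibble::tibble(id = "bad", class = c(1L, 2L),
                            category = c("agree", "agree"),
                            value = c(0.2, 0.1))  # implies marginal 0.17, not 0.9
  expect_error(reconstruct_generative_params(marginals, printed,
                                             pi = c(0.7, 0.3)),
               class = "latuse_reconstruction_error")
})

test_that("generated surveys match the study's scale and structure", {
  sim <- generate_survey(latrine_use_model(), n_households = 98, seed = 91)
  expect_identical(sim, generate_survey(latrine_use_model(),
                                        n_households = 98, seed = 91))
  expect_gt(nrow(sim), 180)
  expect_lt(nrow(sim), 330)
  expect_equal(length(unique(sim$household_id)), 98)
  expect_lt(abs(mean(sim$.true_class == 1L) - 0.78), 0.10)
  expect_lt(abs(mean(sim$sex == "female") - 0.65), 0.10)
  # output validates against the codebook
  expect_silent(validate_survey(dplyr::select(sim, -".true_class",
                                              -"basic_sanitation")))
})

test_that("a null exposure effect leaves class independent of sanitation", {
  sim <- generate_survey(latrine_use_model(), n_households = 1500, seed = 92)
  by_exp <- tapply(sim$.true_class == 1L, sim$basic_sanitation, mean)
  expect_lt(abs(by_exp["1"] - by_exp["0"]), 0.03)
})

test_that("household concordance produces the configured pairwise correlation", {
  sim <- generate_survey(latrine_use_model(concordance = 0.3),
                         n_households = 3000, seed = 93)
  z <- as.integer(sim$.true_class == 1L)
  hh <- sim$household_id
  # moment estimate of the within-household pairwise correlation
  pairs <- do.call(rbind, lapply(split(seq_along(z), hh), function(idx) {
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    cbind(z[cmb[1, ]], z[cmb[2, ]])
  }))
  p <- mean(z)
  r_hat <- (mean(pairs[, 1] * pairs[, 2]) - p^2) / (p * (1 - p))
  expect_lt(abs(r_hat - 0.3), 0.06)

  zero <- generate_survey(latrine_use_model(concordance = 0),
                          n_households = 4000, seed = 94)
  z0 <- as.integer(zero$.true_class == 1L)
  pairs0 <- do.call(rbind, lapply(split(seq_along(z0), zero$household_id),
                                  function(idx) {
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    cbind(z0[cmb[1, ]], z0[cmb[2, ]])
  }))
  p0 <- mean(z0)
  r0 <- (mean(pairs0[, 1] * pairs0[, 2]) - p0^2) / (p0 * (1 - p0))
  expect_lt(abs(r0), 0.05)
})

test_that("noise indicators are class-independent with instrument marginals", {
  model <- latrine_use_model(include_noise = TRUE)
  expect_equal(length(model$indicators), 16)
  expect_equal(unname(model$rho["daily_use", "class1", ]),
               unname(model$rho["daily_use", "class2", ]))
  tab <- latuse_indicator_table()
  m <- as.numeric(tab[tab$id == "daily_use", c("agree", "disagree", "dont_know")])
  expect_equal(unname(model$rho["daily_use", "class1", ]), m / sum(m),
               tolerance = 1e-10)
})

test_that("parametric simulation converges to the model marginals", {
  model <- latrine_use_model()
  empty <- generate_from_fit(model, n = 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_identical(names(empty), model$indicators)
  big <- generate_from_fit(model, n = 20000, seed = 95)
  implied <- apply(model$rho, c(1, 3), function(rc) sum(model$pi * rc))
  for (j in model$indicators) {
    obs <- as.numeric(table(big[[j]])) / 20000
    expect_lt(max(abs(obs - implied[j, ])), 0.02)
  }
})

test_that("fitting recovers the generating parameters at large N", {
  model <- latrine_use_model()
  sim <- generate_from_fit(model, n = 5000, seed = 96)
  fit <- fit_lca(sim, k = 2, n_starts = 15, seed = 97, se_method = "none")
  rmse <- sqrt(mean(c(fit$pi - model$pi, fit$rho - model$rho)^2))
  expect_lt(rmse, 0.02)
})

test_that("item nonresponse is injected at the configured rate", {
  model <- latrine_use_model(missing_rate = 0.15)
  sim <- generate_survey(model, n_households = 400, seed = 98)
  y <- as.matrix(dplyr::select(sim, dplyr::all_of(final_indicators())))
  expect_lt(abs(mean(is.na(y)) - 0.15), 0.02)
  # FIML still fits through the missingness
  fit <- fit_lca(sim, indicators = final_indicators(), k = 2, n_starts = 8,
                 seed = 99, se_method = "none")
  expect_lt(abs(fit$pi[1] - 0.78), 0.06)
})
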