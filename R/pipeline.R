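#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the configuration driving
#' [run_pipeline()].  Every stochastic stage — EM restarts, the
#' goodness-of-fit bootstrap, pseudo-class draws, simulation — must carry
#' an explicit seed: the pipeline refuses to run on silent global RNG
#' state, because auditability of the stochastic stages is the point of
#' the artifact.
#'
#' @param input Path to a survey CSV, or `NULL` to simulate input with
#'   [generate_survey()].
#' @param k_values Candidate class counts for model comparison.
#' @param n_starts,tol EM settings.
#' @param m Pseudo-class imputations.
#' @param boot_b Goodness-of-fit bootstrap replicates.
#' @param conf_level Pruning CI level.
#' @param n_households Households to simulate when `input` is `NULL`.
#' @param seeds Named list of integer seeds: `fit`, `gof`, `impute`, and
#'   `simulate` (when simulating).  All required, no defaults.
#' @return A `latuse_config` list.
#' @export
pipeline_config <- function(input = NULL, k_values = c(2, 3), n_starts = 50,
                            tol = 1e-8, m = 5, boot_b = 200,
                            conf_level = 0.95, n_households = 98,
                            seeds = list()) {
  need <- c("fit", "gof", "impute", if (is.null(input)) "simulate")
  absent <- setdiff(need, names(seeds))
  if (length(absent) > 0) {
    rlang::abort(sprintf("explicit seed(s) required for stage(s): %s",
                         paste(absent, collapse = ", ")),
                 class = "latuse_config_error")
  }
  structure(list(input = input, k_values = k_values, n_starts = n_starts,
                 tol = tol, m = m, boot_b = boot_b, conf_level = conf_level,
                 n_households = n_households,
                 seeds = lapply(seeds, as.integer)),
            class = "latuse_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname pipeline_config
#' @param config A `latuse_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate a survey to files
#'
#' Wraps [generate_survey()] under a pipeline configuration: writes the
#' standard survey CSV plus a ground-truth class-label CSV.
#'
#' @param config A [pipeline_config()] with a `simulate` seed.
#' @param out_dir Output directory (created if needed).
#' @param model Generative model (default [latrine_use_model()]).
#' @return Paths of the written files, invisibly.
#' @export
simulate_study <- function(config, out_dir, model = latrine_use_model()) {
  if (is.null(config$seeds$simulate)) {
    rlang::abort("config has no `simulate` seed", class = "latuse_config_error")
  }
  if (config$n_households < 2) {
    rlang::warn("a single household gives one cluster; clustered standard errors will fail downstream")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_survey(model, n_households = config$n_households,
                         seed = config$seeds$simulate)
  survey_path <- file.path(out_dir, "survey.csv")
  truth_path <- file.path(out_dir, "true_classes.csv")
  write_survey(dplyr::select(sim, -".true_class", -"basic_sanitation"),
               survey_path)
  readr::write_csv(dplyr::select(sim, "individual_id",
                                 true_class = ".true_class"), truth_path)
  invisible(c(survey = survey_path, truth = truth_path))
}

#' Run the full measurement-to-structural pipeline
#'
#' Executes the sequential workflow: fit the measurement model on all 16
#' indicators for each candidate number of classes, compare and select,
#' prune uninformative indicators by the CI-overlap rule and refit, draw
#' pseudo-class memberships, fit household-clustered logistic regressions
#' of membership on basic sanitation (unadjusted and adjusted) per
#' imputation, and pool by Rubin's rules.  Writes the report bundle:
#' descriptive, comparison, conditional-probability, demographic and
#' pooled-odds-ratio tables as CSV, the selected model as JSON, and a run
#' log with seeds, restart counts, convergence status and dropped-row
#' counts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Directory for the report bundle.
#' @return Invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- c(sprintf("latuse pipeline | R %s", getRversion()),
                 sprintf("seeds: %s", paste(names(config$seeds),
                                            unlist(config$seeds),
                                            sep = "=", collapse = " ")))
  stage <- "input"
  result <- tryCatch({
    data <- if (is.null(config$input)) {
      sim <- generate_survey(latrine_use_model(include_noise = TRUE),
                             n_households = config$n_households,
                             seed = config$seeds$simulate)
      dplyr::select(sim, -".true_class", -"basic_sanitation")
    } else {
      read_survey(config$input)
    }
    log_lines <- c(log_lines, sprintf("N = %d individuals, %d households",
                                      nrow(data),
                                      length(unique(data$household_id))))
    readr::write_csv(descriptive_table(data),
                     file.path(out_dir, "table_descriptives.csv"))

    stage <- "compare"
    cmp <- compare_class_solutions(data, k_values = config$k_values,
                                   n_starts = config$n_starts,
                                   seed = config$seeds$fit,
                                   boot_b = config$boot_b)
    readr::write_csv(dplyr::mutate(cmp$table,
                                   pi = purrr::map_chr(.data$pi, ~ paste(round(.x, 2), collapse = "; "))),
                     file.path(out_dir, "table_comparison.csv"))
    log_lines <- c(log_lines, sprintf("selected K = %d (%s)",
                                      cmp$selected_k, cmp$decision))

    stage <- "prune"
    full_fit <- fit_lca(data, k = cmp$selected_k, n_starts = config$n_starts,
                        seed = config$seeds$fit)
    pr <- prune_uninformative(full_fit, data, conf_level = config$conf_level,
                              n_starts = config$n_starts,
                              seed = config$seeds$fit + 1L)
    readr::write_csv(pr$ci_table, file.path(out_dir, "table_ci_overlap.csv"))
    final_fit <- pr$refit %||% full_fit
    gof <- pearson_gof(final_fit, data, b = config$boot_b,
                       seed = config$seeds$gof)
    final_fit$x2 <- gof$x2
    final_fit$gof_p <- gof$p_value
    readr::write_csv(tidy(final_fit),
                     file.path(out_dir, "table_conditionals.csv"))
    write_lca_fit(final_fit, file.path(out_dir, "model.json"))
    log_lines <- c(log_lines,
                   sprintf("final model: %d indicators retained (%s); entropy %.3f; X2 %.1f (p = %.3f); %d/%d EM starts converged",
                           length(final_fit$indicators),
                           paste(final_fit$indicators, collapse = ", "),
                           final_fit$rel_entropy, gof$x2, gof$p_value,
                           sum(is.finite(final_fit$start_logliks)),
                           length(final_fit$start_logliks)))

    stage <- "structural"
    structural <- run_structural_pipeline(data, final_fit, m = config$m,
                                          seed = config$seeds$impute)
    demo <- class_by_demographics(data, structural$draws$modal)
    readr::write_csv(demo, file.path(out_dir, "table_class_by_demographics.csv"))
    or_table <- dplyr::bind_rows(
      dplyr::mutate(tidy(structural$unadjusted), model = "unadjusted"),
      dplyr::mutate(tidy(structural$adjusted), model = "adjusted"))
    readr::write_csv(or_table, file.path(out_dir, "table_odds_ratios.csv"))
    readr::write_csv(structural$per_imputation$adjusted,
                     file.path(out_dir, "per_imputation_estimates.csv"))
    log_lines <- c(log_lines,
                   sprintf("structural model: %d imputations; %d rows dropped (complete case)",
                           config$m, nrow(data) - structural$adjusted$n_obs))

    list(data = data, comparison = cmp, prune = pr, fit = final_fit,
         gof = gof, structural = structural, demographics = demo)
  }, error = function(e) {
    writeLines(c(log_lines, sprintf("ERROR at stage `%s`: %s", stage,
                                    conditionMessage(e))), log_path)
    rlang::abort(sprintf("pipeline failed at stage `%s`: %s", stage,
                         conditionMessage(e)), parent = e)
  })
  writeLines(c(log_lines, "status: complete"), log_path)
  invisible(result)
}
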