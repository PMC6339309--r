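#' Read, validate and write latrine-use survey data
#'
#' Survey files are RFC-4180 CSV with a header row: `individual_id`,
#' `household_id`, one column per indicator id holding category strings
#' (`agree`, `disagree`, `dont_know`, empty = item nonresponse), `age`, and
#' the categorical covariates of the schema.  Unknown category strings are
#' rejected, never coerced.
#'
#' @param path File path.
#' @param codebook A [default_codebook()] object.
#' @return A validated survey tibble: identifiers as character, indicators
#'   and categorical covariates as factors over their closed level sets,
#'   `age` numeric.
#' @seealso [validate_survey()], [write_survey()]
#' @export
read_survey <- function(path, codebook = default_codebook()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  as_survey(raw, codebook)
}

#' @rdname read_survey
#' @param data A data frame of character/factor columns to validate and
#'   convert.
#' @export
as_survey <- function(data, codebook = default_codebook()) {
  ind_ids <- codebook$indicators$id
  required <- c("individual_id", "household_id", ind_ids, "age",
                names(codebook$covariates))
  absent <- setdiff(required, names(data))
  if (length(absent) > 0) {
    rlang::abort(sprintf("survey data is missing required column(s): %s",
                         paste(absent, collapse = ", ")),
                 class = "latuse_schema_error")
  }
  out <- tibble::as_tibble(data)
  out$individual_id <- as.character(out$individual_id)
  out$household_id <- as.character(out$household_id)
  if (anyDuplicated(out$individual_id)) {
    rlang::abort("individual_id values must be unique",
                 class = "latuse_validation_error")
  }
  if (any(is.na(out$household_id))) {
    rlang::abort("every individual must have a household_id",
                 class = "latuse_validation_error")
  }
  for (id in ind_ids) {
    out[[id]] <- check_levels(out[[id]], codebook$categories, id)
  }
  for (cv in names(codebook$covariates)) {
    out[[cv]] <- check_levels(out[[cv]], codebook$covariates[[cv]], cv)
  }
  out$age <- as.numeric(out$age)
  out[, required]
}

check_levels <- function(x, levels, column) {
  x <- as.character(x)
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("invalid value \"%s\" for `%s` at row %d (allowed: %s)",
              x[bad[1]], column, bad[1], paste(levels, collapse = ", ")),
      class = "latuse_validation_error")
  }
  factor(x, levels = levels)
}

#' @rdname read_survey
#' @export
validate_survey <- function(data, codebook = default_codebook()) {
  invisible(as_survey(data, codebook))
}

#' @rdname read_survey
#' @export
write_survey <- function(data, path, codebook = default_codebook()) {
  data <- as_survey(data, codebook)
  out <- dplyr::mutate(data, dplyr::across(dplyr::where(is.factor), as.character))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Dichotomize household sanitation access
#'
#' Collapses the four-level sanitation ladder into the exposure used in the
#' structural model: basic sanitation (an improved facility not shared with
#' other households) versus anything less.  Missing sanitation propagates as
#' `NA`.
#'
#' @param data A survey tibble.
#' @return The input with an added integer column `basic_sanitation`
#'   (1 = basic, 0 = shared/unimproved/none, `NA` = missing).
#' @export
binarize_sanitation <- function(data) {
  dplyr::mutate(data,
    basic_sanitation = dplyr::case_when(
      is.na(.data$sanitation) ~ NA_integer_,
      .data$sanitation == "basic" ~ 1L,
      TRUE ~ 0L
    ))
}

#' Descriptive covariate table
#'
#' Frequency distribution of the background covariates, with missingness
#' shown as its own category so that proportions (including the missing
#' row) sum to 1 within each variable.  Age is summarized by median and SD.
#'
#' @param data A survey tibble.
#' @return A tibble with columns `variable`, `category`, `proportion`, `n`
#'   (and `median`/`sd` filled for the age row).
#' @export
descriptive_table <- function(data, codebook = default_codebook()) {
  n_total <- nrow(data)
  cat_rows <- purrr::map_dfr(names(codebook$covariates), function(cv) {
    x <- as.character(data[[cv]])
    x[is.na(x)] <- "missing"
    lev <- c(codebook$covariates[[cv]], "missing")
    counts <- table(factor(x, levels = lev))
    tibble::tibble(
      variable = cv,
      category = lev,
      n = as.integer(counts),
      proportion = as.numeric(counts) / n_total
    )
  })
  cat_rows <- dplyr::filter(cat_rows, !(.data$category == "missing" & .data$n == 0))
  age_row <- tibble::tibble(
    variable = "age", category = "years", n = sum(!is.na(data$age)),
    proportion = NA_real_,
    median = stats::median(data$age, na.rm = TRUE),
    sd = stats::sd(data$age, na.rm = TRUE)
  )
  dplyr::bind_rows(age_row,
                   dplyr::mutate(cat_rows, median = NA_real_, sd = NA_real_))
}
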