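#' @importFrom rlang .data
NULL

# canonical response categories; the integer encoding (agree = 0,
# disagree = 1, dont_know = 2) is fixed so conditional-probability arrays
# are comparable across runs and serialized artifacts
LATUSE_CATEGORIES <- c("agree", "disagree", "dont_know")

# the five indicators that survive pruning in the reference model
LATUSE_FINAL_FIVE <- c("men_dry_season", "neighbors_rainy", "children_rainy",
                       "household_crowding", "neighbors_latrine")

# per-indicator observed marginal proportions (agree / disagree / dont_know)
# for the full 16-item instrument, as tabulated for the rural-Ecuador study
# population the synthetic generator emulates
latuse_indicator_table <- function() {
  tibble::tribble(
    ~id,                  ~question,                                                                                              ~agree, ~disagree, ~dont_know,
    "latrine_anxiety",    "When I use the latrine, it causes me to feel anxious.",                                                0.19,   0.82,      0.00,
    "daily_use",          "I use the latrine every day.",                                                                         0.91,   0.09,      0.00,
    "rain_avoidance",     "I do not use the latrine when it is raining because I do not want to get wet.",                        0.81,   0.19,      0.00,
    "men_dry_season",     "During the dry season, I think that most of the men in my village regularly use a latrine.",           0.68,   0.14,      0.18,
    "neighbors_rainy",    "During the rainy season, I think all of my neighbors regularly use a latrine.",                        0.80,   0.07,      0.14,
    "children_rainy",     "During the rainy season, I think that most of the children in my village regularly use a latrine.",    0.87,   0.08,      0.04,
    "household_crowding", "There are too many people in this household for one latrine.",                                         0.43,   0.56,      0.01,
    "neighbors_latrine",  "If my household did not have its own latrine, I would use my neighbor's latrine.",                     0.86,   0.14,      0.00,
    "cabin_too_small",    "The cabin of the latrine is too small for me to use.",                                                 0.26,   0.73,      0.01,
    "pleasing_look",      "I am pleased with how the latrine looks.",                                                             0.64,   0.35,      0.01,
    "basin_strength",     "The latrine's basin is strong enough to hold my weight.",                                              0.92,   0.06,      0.01,
    "clean_enough",       "The latrine is clean enough to use.",                                                                  0.87,   0.10,      0.03,
    "outside_convenient", "It is more convenient to defecate outside than to return home to use the latrine.",                    0.44,   0.55,      0.00,
    "morning_routine",    "My morning routine is not suited for using the latrine to defecate.",                                  0.33,   0.66,      0.01,
    "night_convenient",   "It is more convenient to use the latrine at night than to defecate in a container within my household.", 0.85, 0.15,      0.01,
    "night_danger",       "It is dangerous to use the latrine at night.",                                                         0.36,   0.64,      0.00
  )
}

# closed covariate category sets; "missing" is a display category in
# descriptive tables but stored as NA in the data
latuse_covariate_levels <- function() {
  list(
    sex          = c("female", "male"),
    ethnicity    = c("afro_ecuadorian", "mestizo_other", "chachi"),
    education    = c("less_than_primary", "primary", "less_than_secondary",
                     "secondary"),
    payment_type = c("solely_cash", "cash_and_kind", "not_paid",
                     "not_employed"),
    cement_walls = c("yes", "no"),
    asset_deprived = c("yes", "no"),
    sanitation   = c("basic", "shared", "unimproved", "none")
  )
}

#' Codebook for the latrine-use survey instrument
#'
#' Describes the 16 psychosocial indicators (three ordered response
#' categories each: agree, disagree, don't know), the covariate schema, and
#' the fixed category-to-integer encoding used by every reader, writer and
#' model in the package.  "Don't know" is a substantive response category —
#' in the reference two-class model it is a class-defining modal response —
#' while true item nonresponse is a separate missing value (`NA`) handled by
#' full-information maximum likelihood downstream.
#'
#' @param indicators Character vector of indicator ids to include; defaults
#'   to the full 16-item instrument.  [final_indicators()] gives the five
#'   ids retained by the confidence-interval-overlap pruning rule.
#' @return A `latuse_codebook` object: a list with `indicators` (a tibble of
#'   id, question and marginal response proportions), `categories`, the
#'   `encoding` map (agree = 0, disagree = 1, dont_know = 2) and the
#'   covariate level sets.
#' @examples
#' cb <- default_codebook()
#' cb$indicators$id
#' @export
default_codebook <- function(indicators = NULL) {
  tab <- latuse_indicator_table()
  if (!is.null(indicators)) {
    missing_ids <- setdiff(indicators, tab$id)
    if (length(missing_ids) > 0) {
      rlang::abort(sprintf("unknown indicator id(s): %s",
                           paste(missing_ids, collapse = ", ")))
    }
    tab <- tab[match(indicators, tab$id), ]
  }
  structure(
    list(
      indicators = tab,
      categories = LATUSE_CATEGORIES,
      encoding = stats::setNames(seq_along(LATUSE_CATEGORIES) - 1L,
                                 LATUSE_CATEGORIES),
      covariates = latuse_covariate_levels()
    ),
    class = "latuse_codebook"
  )
}

#' @rdname default_codebook
#' @export
final_indicators <- function() LATUSE_FINAL_FIVE

#' @export
print.latuse_codebook <- function(x, ...) {
  cat(sprintf("<latuse_codebook: %d indicators, %d response categories>\n",
              nrow(x$indicators), length(x$categories)))
  print(x$indicators[, c("id", "agree", "disagree", "dont_know")])
  invisible(x)
}
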