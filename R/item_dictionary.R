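#' Read an item dictionary
#'
#' The item dictionary is the schema for assessment items: for each item code
#' it records the clinical domain, the valid ordinal range, any special codes
#' (for example `8`, "activity did not occur"), membership in the
#' auto-population indicator sets, whether the item lives in the CHA
#' functional supplement, and — for the synthetic generator — the loadings on
#' the five latent health dimensions, the residual noise SD, and the marginal
#' category probabilities whose standard-normal quantiles act as fixed
#' discretization thresholds.
#'
#' @param path Path to a dictionary CSV. Defaults to the dictionary shipped
#'   with the package.
#' @return A tibble with one row per item and list-columns `probs` (marginal
#'   category probabilities), `loadings` (length-5 numeric, one per latent
#'   dimension) and `special_codes` (integer, possibly empty).
#' @export
read_item_dictionary <- function(path = system.file("extdata", "item_dictionary.csv",
                                                    package = "raiqc")) {
  if (!file.exists(path)) {
    abort(paste0("item dictionary not found: ", path), class = "raiqc_schema_error")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(special_codes = "character"))
  needed <- c("item", "domain", "min_code", "max_code", "special_codes",
              "probs", "loadings", "noise_sd", "fs_dependent",
              "set_adl9", "set_iadl_perf7", "set_iadl_cap7", "set_mood9")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("item dictionary is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "raiqc_schema_error")
  }
  split_num <- function(x) lapply(strsplit(x, ";", fixed = TRUE), as.numeric)
  dict <- tibble::as_tibble(raw)
  dict$probs <- split_num(dict$probs)
  dict$loadings <- split_num(dict$loadings)
  dict$special_codes <- lapply(strsplit(dict$special_codes, ";", fixed = TRUE),
                               function(x) as.integer(x[nzchar(x)]))
  validate_item_dictionary(dict)
  dict
}

#' Default item dictionary
#'
#' Cached copy of the dictionary shipped under `inst/extdata`.
#' @return A tibble; see [read_item_dictionary()].
#' @export
default_item_dictionary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_item_dictionary()
    cache
  }
})

validate_item_dictionary <- function(dict) {
  if (anyDuplicated(dict$item)) {
    abort("duplicate item codes in dictionary", class = "raiqc_schema_error")
  }
  for (i in seq_len(nrow(dict))) {
    rng <- dict$min_code[i]:dict$max_code[i]
    if (dict$min_code[i] > dict$max_code[i]) {
      abort(paste0("item ", dict$item[i], ": min_code > max_code"),
            class = "raiqc_schema_error")
    }
    if (length(dict$probs[[i]]) != length(rng) ||
        abs(sum(dict$probs[[i]]) - 1) > 1e-8 || any(dict$probs[[i]] < 0)) {
      abort(paste0("item ", dict$item[i], ": category probabilities must be a ",
                   "nonnegative vector over the code range summing to 1"),
            class = "raiqc_schema_error")
    }
    if (length(dict$loadings[[i]]) != length(LATENT_DIMS)) {
      abort(paste0("item ", dict$item[i], ": loadings must have length ",
                   length(LATENT_DIMS)), class = "raiqc_schema_error")
    }
    if (any(dict$special_codes[[i]] %in% rng)) {
      abort(paste0("item ", dict$item[i], ": special codes overlap the ordinal range"),
            class = "raiqc_schema_error")
    }
  }
  invisible(dict)
}

#' Items belonging to a named indicator or scale set
#'
#' @param dictionary An item dictionary tibble.
#' @param set One of `"adl9"`, `"iadl_perf7"`, `"iadl_cap7"`, `"iadl_both14"`
#'   or `"mood9"` (the auto-population indicator sets), or one of the scale
#'   item sets `"adl_long_form"`, `"iadl_performance"`, `"iadl_capacity"`,
#'   `"drs"`.
#' @return Character vector of item codes.
#' @export
item_set <- function(dictionary = default_item_dictionary(), set) {
  switch(set,
    adl9        = dictionary$item[dictionary$set_adl9],
    iadl_perf7  = dictionary$item[dictionary$set_iadl_perf7],
    iadl_cap7   = dictionary$item[dictionary$set_iadl_cap7],
    iadl_both14 = dictionary$item[dictionary$set_iadl_perf7 | dictionary$set_iadl_cap7],
    mood9       = dictionary$item[dictionary$set_mood9],
    adl_long_form    = ADL_LF_ITEMS,
    iadl_performance = IADL_PERF_ITEMS,
    iadl_capacity    = IADL_CAP_ITEMS,
    drs              = DRS_ITEMS,
    abort(paste0("unknown item set: ", set), class = "raiqc_schema_error")
  )
}

# Constituent items of the summary scales.
ADL_LF_ITEMS <- c("adl_bed_mobility", "adl_transfer", "adl_locomotion",
                  "adl_dressing", "adl_eating", "adl_toilet_use", "adl_hygiene")
IADL_PERF_ITEMS <- c("iadl_meal_prep_perf", "iadl_housework_perf", "iadl_phone_perf")
IADL_CAP_ITEMS <- c("iadl_meal_prep_cap", "iadl_housework_cap", "iadl_phone_cap")
DRS_ITEMS <- c("mood_negative_statements", "mood_anger", "mood_unrealistic_fears",
               "mood_health_complaints", "mood_anxious_complaints",
               "mood_sad_expression", "mood_crying")
ADLH_ITEMS <- c("adl_hygiene", "adl_toilet_use", "adl_locomotion", "adl_eating")
CPS_ITEMS <- c("cog_short_term_memory", "cog_decision_making",
               "cog_making_self_understood", "cog_comatose", "adl_eating")
CHESS_SYMPTOMS <- c("sym_vomiting", "sym_dehydration", "sym_insufficient_fluid",
                    "sym_weight_loss", "sym_dyspnea", "sym_edema")
CHESS_ITEMS <- c(CHESS_SYMPTOMS, "decline_decision", "decline_adl", "end_stage_disease")
PAIN_ITEMS <- c("pain_frequency", "pain_intensity")
MAPLE_ITEMS <- c("beh_wandering", "beh_behaviour_symptoms", "falls", "env_hazard")
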