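# interRAI summary scales computed from ordinal item codes.
#
# Sum scales (ADL Long Form, IADL performance/capacity, DRS) are plain item
# sums after special-code recoding. The hierarchical scales (CPS, ADL
# Hierarchy, CHESS, MAPLe) are decision rules over the canonical driver
# items; the exact trees shipped here are documented simplified forms (the
# versions are recorded in `SCALE_ALGORITHM_VERSIONS`). The Pain Scale is a
# lookup in the combination table shipped as a data file.

#' Versions of the shipped scale decision rules
#' @export
SCALE_ALGORITHM_VERSIONS <- c(cps = "raiqc-cps-1", adl_hierarchy = "raiqc-adlh-1",
                              chess = "raiqc-chess-1", maple = "raiqc-maple-1",
                              pain = "raiqc-pain-1")

scoring_error <- function(item, msg) {
  abort(paste0("scoring error: item `", item, "`: ", msg),
        class = "raiqc_scoring_error")
}

as_item_frame <- function(items) {
  if (is.data.frame(items)) return(items)
  if (is.numeric(items) && !is.null(names(items))) {
    return(tibble::as_tibble(as.list(items)))
  }
  abort("items must be a data frame or a named numeric vector",
        class = "raiqc_scoring_error")
}

# Fetch an item column, recoding special code 8 ("activity did not occur")
# to the maximal-dependence code and validating the range.
item_codes <- function(items, name, max_code, special_to = max_code) {
  if (!name %in% names(items)) {
    scoring_error(name, "required item column is absent")
  }
  x <- as.numeric(items[[name]])
  x[!is.na(x) & x == 8] <- special_to
  bad <- !is.na(x) & (x < 0 | x > max_code)
  if (any(bad)) {
    scoring_error(name, paste0("code outside 0-", max_code,
                               " (after special-code recoding)"))
  }
  x
}

sum_scale <- function(items, item_names, max_code, recode = identity) {
  m <- vapply(item_names, function(nm) recode(item_codes(items, nm, max_code)),
              numeric(nrow(as_item_frame(items))))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  out <- rowSums(m)
  as.integer(round(out))
}

#' ADL Long Form scale (0-28)
#'
#' Sum of seven ADL self-performance items (bed mobility, transfer,
#' locomotion, dressing, eating, toilet use, personal hygiene), each coded
#' 0-4. `NA` if any required item is missing.
#'
#' @param items Data frame (or named vector) of item codes.
#' @return Integer vector in 0-28.
#' @export
adl_long_form <- function(items) {
  items <- as_item_frame(items)
  sum_scale(items, ADL_LF_ITEMS, 4)
}

#' IADL Performance scale (0-9)
#'
#' Sum of three IADL self-performance items (meal preparation, ordinary
#' housework, phone use), each coded 0-3.
#' @inheritParams adl_long_form
#' @return Integer vector in 0-9.
#' @export
iadl_performance <- function(items) {
  items <- as_item_frame(items)
  sum_scale(items, IADL_PERF_ITEMS, 3)
}

#' IADL Capacity scale (0-6)
#'
#' Sum of three IADL capacity items, each coded 0-2.
#' @inheritParams adl_long_form
#' @return Integer vector in 0-6.
#' @export
iadl_capacity <- function(items) {
  items <- as_item_frame(items)
  sum_scale(items, IADL_CAP_ITEMS, 2)
}

#' Depression Rating Scale (0-14)
#'
#' Sum of seven mood items, each capped at 2 before summation so the scale
#' spans 0 (no mood symptoms) to 14 (all symptoms present).
#' @inheritParams adl_long_form
#' @return Integer vector in 0-14.
#' @export
drs <- function(items) {
  items <- as_item_frame(items)
  sum_scale(items, DRS_ITEMS, 3, recode = function(x) pmin(x, 2))
}

pain_table_env <- new.env(parent = emptyenv())

pain_combination_table <- function() {
  if (is.null(pain_table_env$tab)) {
    path <- system.file("extdata", "pain_scale_table.csv", package = "raiqc")
    pain_table_env$tab <- read.csv(path)
  }
  pain_table_env$tab
}

#' Pain Scale (0-3)
#'
#' Combines pain frequency (0 none, 1 less than daily, 2 daily) and pain
#' intensity (0 none, 1 mild, 2 moderate, 3 severe) via the shipped
#' combination table: 0 = no pain, 3 = daily severe pain; nondecreasing in
#' both inputs.
#'
#' @param frequency,intensity Integer item codes (vectors).
#' @return Integer vector in 0-3; `NA` where either input is `NA`.
#' @export
pain_scale <- function(frequency, intensity) {
  tab <- pain_combination_table()
  bad_f <- !is.na(frequency) & !frequency %in% unique(tab$pain_frequency)
  bad_i <- !is.na(intensity) & !intensity %in% unique(tab$pain_intensity)
  if (any(bad_f)) scoring_error("pain_frequency", "invalid code")
  if (any(bad_i)) scoring_error("pain_intensity", "invalid code")
  key <- paste(frequency, intensity)
  lut <- setNames(tab$pain_scale, paste(tab$pain_frequency, tab$pain_intensity))
  out <- unname(lut[key])
  out[is.na(frequency) | is.na(intensity)] <- NA_integer_
  as.integer(out)
}

#' Cognitive Performance Scale (0-6)
#'
#' Decision rule over short-term memory, daily decision making, making self
#' understood, consciousness and the eating ADL: comatose scores 6; severely
#' impaired decision making scores 5, or 6 when eating is totally dependent;
#' otherwise an impairment count (memory problem, any decision impairment,
#' any communication impairment) maps 0/1 to 0/1 and 2+ to 2, 3 or 4
#' depending on how many of decision making and communication are at least
#' moderately impaired.
#'
#' @inheritParams adl_long_form
#' @return Integer vector in 0-6.
#' @export
cps <- function(items) {
  items <- as_item_frame(items)
  memory <- item_codes(items, "cog_short_term_memory", 1)
  decision <- item_codes(items, "cog_decision_making", 3)
  understood <- item_codes(items, "cog_making_self_understood", 3)
  comatose <- item_codes(items, "cog_comatose", 1)
  eating <- item_codes(items, "adl_eating", 4)

  n <- length(memory)
  out <- rep(NA_integer_, n)
  ok <- !(is.na(memory) | is.na(decision) | is.na(understood) | is.na(comatose))
  imp <- (memory == 1) + (decision >= 1) + (understood >= 1)
  sev <- (decision >= 2) + (understood >= 2)
  base <- ifelse(imp == 0, 0L, ifelse(imp == 1, 1L, 2L + pmin(sev, 2L)))
  out[ok] <- base[ok]
  sev_dec <- ok & decision == 3
  out[sev_dec] <- ifelse(is.na(eating[sev_dec]), 5L,
                         ifelse(eating[sev_dec] == 4, 6L, 5L))
  out[ok & comatose == 1] <- 6L
  out
}

#' ADL Hierarchy scale (0-6)
#'
#' Classifies ADL loss by the disablement process using personal hygiene and
#' toilet use (early/middle loss), locomotion (middle loss) and eating (late
#' loss): 0 all independent; 1 no item above supervision; 2 no item above
#' limited assistance; 3 extensive assistance on hygiene or toilet use only;
#' 4 extensive assistance on locomotion; 5 severe impairment of eating;
#' 6 total dependence on all four items.
#'
#' @inheritParams adl_long_form
#' @return Integer vector in 0-6.
#' @export
adl_hierarchy <- function(items) {
  items <- as_item_frame(items)
  hygiene <- item_codes(items, "adl_hygiene", 4)
  toilet <- item_codes(items, "adl_toilet_use", 4)
  locomotion <- item_codes(items, "adl_locomotion", 4)
  eating <- item_codes(items, "adl_eating", 4)
  n <- length(hygiene)
  out <- rep(NA_integer_, n)
  ok <- !(is.na(hygiene) | is.na(toilet) | is.na(locomotion) | is.na(eating))
  mx <- pmax(hygiene, toilet, locomotion, eating)
  val <- ifelse(mx == 0, 0L,
         ifelse(mx <= 1, 1L,
         ifelse(mx <= 2, 2L,
         ifelse(hygiene == 4 & toilet == 4 & locomotion == 4 & eating == 4, 6L,
         ifelse(eating >= 3, 5L,
         ifelse(locomotion >= 3, 4L, 3L))))))
  out[ok] <- val[ok]
  out
}

#' CHESS health-instability scale (0-5)
#'
#' Sums a capped symptom count (0, 1, or 2 for two or more of: vomiting,
#' dehydration, insufficient fluid intake, weight loss, shortness of breath,
#' edema) with indicators for decline in decision making, decline in ADL
#' status, and end-stage disease, capped at 5.
#'
#' @inheritParams adl_long_form
#' @return Integer vector in 0-5.
#' @export
chess <- function(items) {
  items <- as_item_frame(items)
  syms <- vapply(CHESS_SYMPTOMS, function(nm) item_codes(items, nm, 1),
                 numeric(nrow(items)))
  if (!is.matrix(syms)) syms <- matrix(syms, nrow = 1)
  dd <- item_codes(items, "decline_decision", 1)
  da <- item_codes(items, "decline_adl", 1)
  es <- item_codes(items, "end_stage_disease", 1)
  s <- rowSums(syms)
  out <- pmin(5, pmin(s, 2) + dd + da + es)
  as.integer(out)
}

#' MAPLe priority level (1-5)
#'
#' Simplified Method for Assigning Priority Levels driven by the canonical
#' risk factors: level 5 for wandering or combined extensive ADL and
#' cognitive impairment; level 4 for extensive ADL impairment, moderate or
#' worse cognitive impairment, or behaviour symptoms; level 3 for falls,
#' home environment hazards, any ADL impairment, mild-plus cognitive
#' impairment or notable IADL difficulty; level 2 for lesser IADL or
#' cognitive findings; level 1 for the self-reliant. For CHA records the
#' functional supplement is required (gated in [score_assessments()]).
#'
#' @inheritParams adl_long_form
#' @param adlh,cps_score,iadl_cap Precomputed scale scores (same length).
#' @return Integer vector in 1-5.
#' @export
maple <- function(items, adlh, cps_score, iadl_cap) {
  items <- as_item_frame(items)
  wander <- item_codes(items, "beh_wandering", 1)
  beh <- item_codes(items, "beh_behaviour_symptoms", 1)
  falls <- item_codes(items, "falls", 1)
  env <- item_codes(items, "env_hazard", 1)
  n <- length(wander)
  out <- rep(NA_integer_, n)
  ok <- !(is.na(wander) | is.na(beh) | is.na(falls) | is.na(env) |
            is.na(adlh) | is.na(cps_score) | is.na(iadl_cap))
  val <- ifelse(wander == 1 | (adlh >= 3 & cps_score >= 3), 5L,
         ifelse(adlh >= 3 | cps_score >= 3 | beh == 1, 4L,
         ifelse(falls == 1 | env == 1 | adlh >= 1 | cps_score >= 2 | iadl_cap >= 3, 3L,
         ifelse(iadl_cap >= 1 | cps_score >= 1, 2L, 1L))))
  out[ok] <- val[ok]
  out
}

#' Cut-off indicator
#'
#' `TRUE` when a non-null score meets or exceeds the threshold; `NA` scores
#' yield `NA` (excluded from prevalence denominators downstream).
#'
#' @param score Numeric score vector.
#' @param threshold Cut-off value (scores at or above flag `TRUE`).
#' @return Logical vector.
#' @export
cutoff_indicator <- function(score, threshold) {
  score >= threshold
}

#' Score a cohort: append scale and cut-off columns
#'
#' Computes every summary scale and the standard cut-off indicators
#' (score of 3 or more for CPS, DRS, MAPLe, ADLH and both IADL scales) for
#' each record. For CHA records without a completed functional supplement,
#' MAPLe and the supplement-dependent scores are `NA`.
#'
#' @param records Cohort tibble.
#' @param dictionary Item dictionary (used for set lookups only).
#' @return `records` with appended columns `adl_long_form`, `adl_hierarchy`,
#'   `iadl_performance`, `iadl_capacity`, `drs`, `cps`, `chess`, `pain`,
#'   `maple`, `informal_hours_total`, and logical `*_ge3` cut-off columns.
#' @export
score_assessments <- function(records, dictionary = default_item_dictionary()) {
  out <- records
  out$adl_long_form <- adl_long_form(records)
  out$adl_hierarchy <- adl_hierarchy(records)
  out$iadl_performance <- iadl_performance(records)
  out$iadl_capacity <- iadl_capacity(records)
  out$drs <- drs(records)
  out$cps <- cps(records)
  out$chess <- chess(records)
  out$pain <- pain_scale(records$pain_frequency, records$pain_intensity)
  out$maple <- maple(records, out$adl_hierarchy, out$cps, out$iadl_capacity)
  no_fs <- records$instrument == "CHA" &
    !(records$functional_supplement_completed %in% TRUE)
  out$maple[no_fs] <- NA_integer_
  out$informal_hours_total <- records$informal_hours_weekday +
    records$informal_hours_weekend
  out$cps_ge3 <- cutoff_indicator(out$cps, 3)
  out$drs_ge3 <- cutoff_indicator(out$drs, 3)
  out$maple_ge3 <- cutoff_indicator(out$maple, 3)
  out$adlh_ge3 <- cutoff_indicator(out$adl_hierarchy, 3)
  out$iadl_cap_ge3 <- cutoff_indicator(out$iadl_capacity, 3)
  out$iadl_perf_ge3 <- cutoff_indicator(out$iadl_performance, 3)
  out
}
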