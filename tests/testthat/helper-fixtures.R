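# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

dict <- raiqc::default_item_dictionary()

# One-row (or n-row) item tibble with every dictionary item at its floor,
# selectively overridden: full_items(adl_eating = 4, cog_comatose = 1).
full_items <- function(..., .n = 1) {
  vals <- stats::setNames(rep(list(0L), nrow(dict)), dict$item)
  over <- list(...)
  for (nm in names(over)) vals[[nm]] <- over[[nm]]
  tibble::as_tibble(lapply(vals, function(v) rep(v, length.out = .n)))
}

# Minimal assessment record rows around a set of item values.
make_records <- function(person_id, assessment_date, ...,
                         hospital_version = FALSE, instrument = "RAI-HC",
                         functional_supplement_completed = NA,
                         informal_hours_weekday = 0, informal_hours_weekend = 0) {
  n <- max(length(person_id), length(assessment_date))
  base <- tibble::tibble(
    person_id = rep(person_id, length.out = n),
    assessment_date = as.Date(rep(assessment_date, length.out = n)),
    jurisdiction = "ON",
    instrument = rep(instrument, length.out = n),
    hospital_version = rep(hospital_version, length.out = n),
    functional_supplement_completed = rep(functional_supplement_completed,
                                          length.out = n),
    sex = "F", marital_status = "not_married", age_years = 80L,
    dementia = FALSE, heart_failure = FALSE,
    svc_pt = FALSE, svc_ot = FALSE, svc_nursing = FALSE, svc_psw = FALSE,
    informal_hours_weekday = rep(informal_hours_weekday, length.out = n),
    informal_hours_weekend = rep(informal_hours_weekend, length.out = n),
    rug_category = NA_character_, cmi = NA_real_
  )
  dplyr::bind_cols(base, full_items(..., .n = n))
}

# Drop the bookkeeping attributes so record tibbles compare on content.
strip_attrs <- function(df) {
  for (a in c("autopop_labels", "exclusions", "row_errors")) attr(df, a) <- NULL
  df
}

# Small scored synthetic selection used by several metric tests.
scored_selection <- function(n = 2000, years = 2010, seed = 1, ...) {
  cfg <- raiqc::synth_config(n_persons = n, years = years, seed = seed,
                             missing_id_fraction = 0,
                             hospital_version_fraction = 0,
                             reassessment_prob = 0, ...)
  rec <- raiqc::generate_cohort(cfg)
  raiqc::score_assessments(raiqc::select_annual(
    raiqc::filter_eligible(rec, quiet = TRUE)))
}
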