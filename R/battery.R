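# Indicator batteries: the fixed collection of correlations and alpha
# values computed on one cohort, compared across cohorts via R-squared.

#' Default individual-item pairs for the Spearman section of the battery
#'
#' Twelve item pairs spanning the ADL, IADL, mood, cognition, pain and
#' health domains; configurable because the full set of item-level tests is
#' a reporting choice, not part of any scale definition.
#'
#' @return List of length-2 character vectors of item codes.
#' @export
default_spearman_pairs <- function() {
  list(c("adl_bed_mobility", "adl_transfer"),
       c("adl_locomotion", "adl_dressing"),
       c("adl_eating", "adl_toilet_use"),
       c("adl_hygiene", "adl_bathing"),
       c("iadl_meal_prep_perf", "iadl_housework_perf"),
       c("iadl_phone_perf", "cog_decision_making"),
       c("mood_sad_expression", "mood_crying"),
       c("mood_negative_statements", "mood_anxious_complaints"),
       c("pain_frequency", "pain_intensity"),
       c("cog_short_term_memory", "cog_decision_making"),
       c("sym_dyspnea", "sym_edema"),
       c("falls", "adl_locomotion_outside"))
}

BATTERY_PEARSON_MEASURES <- c("adl_hierarchy", "iadl_performance",
                              "iadl_capacity", "cps", "maple",
                              "informal_hours_total")

#' Compute the indicator battery for one cohort
#'
#' A deterministic ordered battery of statistics on a scored annual
#' selection: all pairwise Pearson correlations among ADLH, IADL
#' performance, IADL capacity, CPS, MAPLe and total informal-care hours
#' (15 entries); Cronbach's alpha for IADL performance, ADL Long Form and
#' DRS (3 entries); and Spearman rank correlations for the configured
#' individual-item pairs. Undefined statistics are recorded as absent, with
#' reasons in the `"errors"` attribute.
#'
#' @param scored Scored annual selection (see [score_assessments()]).
#' @param spearman_pairs List of item-code pairs; see
#'   [default_spearman_pairs()].
#' @param dictionary Item dictionary.
#' @return Tibble (`indicator`, `kind`, `value`) of class
#'   `indicator_battery`.
#' @export
indicator_battery <- function(scored, spearman_pairs = default_spearman_pairs(),
                              dictionary = default_item_dictionary()) {
  entries <- list()
  errors <- list()
  add <- function(id, kind, expr) {
    val <- tryCatch(expr, raiqc_undefined_stat = function(e) {
      errors[[id]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(val)) {
      entries[[length(entries) + 1]] <<- tibble(indicator = id, kind = kind,
                                                value = val)
    }
  }
  meas <- BATTERY_PEARSON_MEASURES
  for (i in seq_along(meas)) {
    for (j in seq_along(meas)) {
      if (i < j) {
        id <- paste0("pearson:", meas[i], "~", meas[j])
        add(id, "pearson", pearson_r(scored[[meas[i]]], scored[[meas[j]]]))
      }
    }
  }
  alpha_scales <- list("iadl_performance" = list(items = IADL_PERF_ITEMS, max_code = 3),
                       "adl_long_form" = list(items = ADL_LF_ITEMS, max_code = 4),
                       "drs" = list(items = DRS_ITEMS, max_code = 3,
                                    recode = function(x) pmin(x, 2)))
  for (nm in names(alpha_scales)) {
    sc <- alpha_scales[[nm]]
    recode <- sc$recode %||% identity
    m <- vapply(sc$items, function(it) recode(item_codes(scored, it, sc$max_code)),
                numeric(nrow(scored)))
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    add(paste0("alpha:", nm), "alpha", cronbach_alpha(m))
  }
  for (pr in spearman_pairs) {
    bad <- setdiff(pr, dictionary$item)
    if (length(bad)) {
      abort(paste0("spearman pair names unknown item codes: ",
                   paste(bad, collapse = ", ")), class = "raiqc_schema_error")
    }
    id <- paste0("spearman:", pr[1], "~", pr[2])
    add(id, "spearman", spearman_rho(scored[[pr[1]]], scored[[pr[2]]]))
  }
  out <- if (length(entries)) bind_rows(entries) else
    tibble(indicator = character(), kind = character(), value = numeric())
  if (anyDuplicated(out$indicator)) {
    abort("indicator ids must be unique", class = "raiqc_schema_error")
  }
  class(out) <- c("indicator_battery", class(out))
  attr(out, "errors") <- errors
  out
}

#' Compare two indicator batteries
#'
#' Pairs the indicators computed in both cohorts and reports the coefficient
#' of determination (the squared Pearson correlation of the paired values) —
#' the single-number summary of whether the instruments' statistical
#' behaviour matches across the two cohorts.
#'
#' @param a,b Indicator batteries from [indicator_battery()].
#' @return List with `pairs` (tibble `indicator`, `kind`, `value_a`,
#'   `value_b`), `r_squared`, and `n_shared`; class `battery_comparison`.
#' @export
compare_batteries <- function(a, b) {
  shared <- dplyr::inner_join(
    tibble(indicator = a$indicator, kind = a$kind, value_a = a$value),
    tibble(indicator = b$indicator, value_b = b$value),
    by = "indicator")
  if (nrow(shared) < 3) {
    abort("battery comparison needs at least 3 shared defined indicators",
          class = "raiqc_comparison_error")
  }
  r2 <- pearson_r(shared$value_a, shared$value_b)^2
  structure(list(pairs = shared, r_squared = r2, n_shared = nrow(shared),
                 method = "squared Pearson correlation of paired indicator values"),
            class = "battery_comparison")
}

#' @export
print.battery_comparison <- function(x, ...) {
  cat(sprintf("Battery comparison over %d shared indicators: R^2 = %.3f\n",
              x$n_shared, x$r_squared))
  invisible(x)
}
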