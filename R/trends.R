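# Year-over-year trend tables: prevalence/means, convergent validity
# (Pearson r per year), reliability (Cronbach's alpha per year), and
# auto-population rates on within-year pairs.

new_trend_table <- function(metric, values, unit = "percent") {
  s <- trend_summary_stats(values$value)
  structure(list(metric = metric, unit = unit, values = values,
                 summary = s),
            class = "trend_table")
}

#' @export
print.trend_table <- function(x, ...) {
  cat("Trend table:", x$metric, paste0("(", x$unit, ")"), "\n")
  print(x$values, n = Inf)
  cat(sprintf("Mean (SD) of annual values: %.2f (%.2f)\n",
              x$summary[["mean"]], x$summary[["sd"]]))
  invisible(x)
}

#' @export
as.data.frame.trend_table <- function(x, ...) {
  df <- as.data.frame(x$values)
  df$metric <- x$metric
  df
}

#' Annual prevalence of a predicate
#'
#' Per calendar year, the percentage of records satisfying a predicate among
#' records for which the predicate is defined (non-`NA`). Years with no
#' defined records are omitted and logged. The summary row is the mean and
#' sample (n-1) SD of the annual percentages.
#'
#' @param selection Annually selected records (see [select_annual()]), with
#'   a `year` column.
#' @param predicate Function mapping the records tibble to a logical vector
#'   (`NA` where undefined), or the name of a logical column.
#' @param metric Label for the table.
#' @return A `trend_table` with values `year`, `value` (percent), `n`
#'   (defined denominator).
#' @export
annual_prevalence <- function(selection, predicate, metric = "prevalence") {
  p <- if (is.character(predicate)) selection[[predicate]] else predicate(selection)
  df <- tibble(year = selection$year, p = as.logical(p))
  res <- df %>%
    filter(!is.na(.data$p)) %>%
    group_by(.data$year) %>%
    summarise(value = 100 * mean(.data$p), n = n(), .groups = "drop")
  omitted <- setdiff(unique(df$year), res$year)
  if (length(omitted)) {
    inform(paste0("annual_prevalence(", metric, "): no defined records in year(s) ",
                  paste(sort(omitted), collapse = ", "), "; omitted"))
  }
  tab <- new_trend_table(metric, res, unit = "percent")
  attr(tab, "omitted_years") <- sort(omitted)
  tab
}

#' Annual mean of a numeric field
#'
#' Companion to [annual_prevalence()] for quantities reported as annual
#' means (informal-care hours, case-mix index).
#'
#' @inheritParams annual_prevalence
#' @param var Name of a numeric column (or a function of the records).
#' @return A `trend_table` in the variable's units.
#' @export
annual_mean <- function(selection, var, metric = var) {
  v <- if (is.character(var)) selection[[var]] else var(selection)
  df <- tibble(year = selection$year, v = as.numeric(v))
  res <- df %>%
    filter(!is.na(.data$v)) %>%
    group_by(.data$year) %>%
    summarise(value = mean(.data$v), n = n(), .groups = "drop")
  omitted <- setdiff(unique(df$year), res$year)
  if (length(omitted)) {
    inform(paste0("annual_mean(", metric, "): no defined records in year(s) ",
                  paste(sort(omitted), collapse = ", "), "; omitted"))
  }
  tab <- new_trend_table(if (is.character(metric)) metric else "mean", res,
                         unit = "mean")
  attr(tab, "omitted_years") <- sort(omitted)
  tab
}

# The five scale pairs whose correlations are tracked as convergent-validity
# indicators.
VALIDITY_PAIRS <- list(
  "ADLH & CPS" = c("adl_hierarchy", "cps"),
  "IADL (cap) & CPS" = c("iadl_capacity", "cps"),
  "IADL (perf) & CPS" = c("iadl_performance", "cps"),
  "Pain & DRS" = c("pain", "drs"),
  "CHESS & Pain" = c("chess", "pain")
)

# Apply a statistic per year, collecting undefined cells instead of failing.
per_year_stat <- function(years, fun) {
  res <- list()
  errors <- list()
  for (yr in sort(unique(years))) {
    val <- tryCatch(fun(yr), raiqc_undefined_stat = function(e) {
      errors[[as.character(yr)]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(val)) {
      res[[length(res) + 1]] <- tibble(year = yr, value = val$value, n = val$n)
    }
  }
  list(values = if (length(res)) bind_rows(res) else
         tibble(year = integer(), value = numeric(), n = integer()),
       errors = errors)
}

#' Convergent-validity trends
#'
#' Per calendar year, the Pearson correlation for each of the five scale
#' pairs (ADLH x CPS, IADL capacity x CPS, IADL performance x CPS, Pain x
#' DRS, CHESS x Pain) on the annually selected, scored records. Cells where
#' the correlation is undefined (for example, a scale that is entirely
#' missing) are absent, with the reason logged in the `"cell_errors"`
#' attribute.
#'
#' @param scored Scored annual selection (see [score_assessments()]), with a
#'   `year` column.
#' @return Named list of `trend_table`s, one per scale pair.
#' @export
validity_trends <- function(scored) {
  out <- list()
  for (label in names(VALIDITY_PAIRS)) {
    vars <- VALIDITY_PAIRS[[label]]
    res <- per_year_stat(scored$year, function(yr) {
      idx <- scored$year == yr
      x <- scored[[vars[1]]][idx]
      y <- scored[[vars[2]]][idx]
      list(value = pearson_r(x, y), n = sum(!(is.na(x) | is.na(y))))
    })
    tab <- new_trend_table(label, res$values, unit = "pearson_r")
    attr(tab, "cell_errors") <- res$errors
    out[[label]] <- tab
  }
  out
}

# Item sets and recodes for the four parallel-form scales tracked for
# internal consistency.
RELIABILITY_SCALES <- function(dictionary) {
  list(
    "IADL (perf)" = list(items = IADL_PERF_ITEMS, max_code = 3),
    "IADL (cap)" = list(items = IADL_CAP_ITEMS, max_code = 2),
    "DRS" = list(items = DRS_ITEMS, max_code = 3, recode = function(x) pmin(x, 2)),
    "ADL Long Form" = list(items = ADL_LF_ITEMS, max_code = 4)
  )
}

#' Reliability (internal consistency) trends
#'
#' Per calendar year, Cronbach's alpha for the four parallel-form scales:
#' IADL performance, IADL capacity, DRS (items capped at 2) and ADL Long
#' Form. Listwise-complete on each scale's items; undefined cells are
#' absent and logged. Negative alphas are flagged in the `"flagged"`
#' attribute.
#'
#' @param selection Annually selected records with item columns and `year`.
#' @param dictionary Item dictionary.
#' @return Named list of `trend_table`s, one per scale.
#' @export
reliability_trends <- function(selection, dictionary = default_item_dictionary()) {
  out <- list()
  for (label in names(RELIABILITY_SCALES(dictionary))) {
    sc <- RELIABILITY_SCALES(dictionary)[[label]]
    recode <- sc$recode %||% identity
    res <- per_year_stat(selection$year, function(yr) {
      idx <- selection$year == yr
      m <- vapply(sc$items,
                  function(nm) recode(item_codes(selection[idx, ], nm, sc$max_code)),
                  numeric(sum(idx)))
      if (!is.matrix(m)) m <- matrix(m, nrow = 1)
      list(value = cronbach_alpha(m), n = sum(stats::complete.cases(m)))
    })
    tab <- new_trend_table(label, res$values, unit = "cronbach_alpha")
    attr(tab, "cell_errors") <- res$errors
    attr(tab, "flagged") <- res$values$year[res$values$value < 0]
    out[[label]] <- tab
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Auto-population rates on within-year assessment pairs
#'
#' For each of the six indicator sets (summed informal-care hours, 9 ADL
#' items, 7 IADL performance items, 7 IADL capacity items, the 14 combined
#' IADL items, 9 mood items) and each year: the percentage of eligible pairs
#' whose values are identical at the first and second assessment. A pair is
#' eligible when every item in the set is non-missing at both time points
#' and the pair is not at the floor at both time points (zero summed hours,
#' complete independence, or no mood symptoms at both assessments — such
#' pairs cannot indicate carry-forward). For the informal-care set, weekday
#' and weekend hours are summed before comparison.
#'
#' @param records Cohort tibble the pairs index into.
#' @param pairs Within-year pairs from [pair_within_year()].
#' @param dictionary Item dictionary resolving the indicator sets.
#' @return Tibble with columns `set`, `year`, `rate` (percent),
#'   `n_eligible` (denominator), `n_identical`; class `autopop_report`.
#'   Attribute `"pairs_by_year"` gives the total pairs per year.
#' @export
autopopulation_rates <- function(records, pairs,
                                 dictionary = default_item_dictionary()) {
  sets <- default_indicator_sets(dictionary)
  years <- sort(unique(pairs$year))
  rows <- list()
  for (set_name in names(sets)) {
    fields <- sets[[set_name]]
    if (set_name == "informal_hours") {
      s1 <- rowSums(as.matrix(records[pairs$first_row, fields]))
      s2 <- rowSums(as.matrix(records[pairs$second_row, fields]))
      defined <- !(is.na(s1) | is.na(s2))
      floor_both <- defined & s1 == 0 & s2 == 0
      identical_vals <- defined & s1 == s2
    } else {
      m1 <- as.matrix(records[pairs$first_row, fields])
      m2 <- as.matrix(records[pairs$second_row, fields])
      defined <- stats::complete.cases(m1) & stats::complete.cases(m2)
      floor_both <- defined & rowSums(m1 != 0) == 0 & rowSums(m2 != 0) == 0
      identical_vals <- defined & rowSums(m1 != m2) == 0
    }
    eligible <- defined & !floor_both
    for (yr in years) {
      in_year <- pairs$year == yr
      denom <- sum(eligible & in_year)
      if (denom == 0) {
        inform(paste0("autopopulation_rates: set `", set_name, "`, year ", yr,
                      ": no eligible pairs; cell omitted"))
        next
      }
      numer <- sum(eligible & in_year & identical_vals)
      rows[[length(rows) + 1]] <- tibble(set = set_name, year = yr,
                                         rate = 100 * numer / denom,
                                         n_eligible = denom,
                                         n_identical = numer)
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(set = character(), year = integer(), rate = numeric(),
           n_eligible = integer(), n_identical = integer())
  class(out) <- c("autopop_report", class(out))
  attr(out, "pairs_by_year") <- table(pairs$year)
  out
}
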