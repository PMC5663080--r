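# Cohort data model: CSV ingestion, eligibility filtering, annual record
# selection (closest to July 1), and within-year pairing.

MANDATORY_COLUMNS <- c("person_id", "assessment_date", "jurisdiction",
                       "instrument", "hospital_version")
HOUR_COLUMNS <- c("informal_hours_weekday", "informal_hours_weekend")
LOGICAL_COLUMNS <- c("hospital_version", "functional_supplement_completed",
                     "dementia", "heart_failure",
                     "svc_pt", "svc_ot", "svc_nursing", "svc_psw")

#' Write a cohort to CSV
#'
#' One row per assessment, ISO-8601 dates, item columns named by item code,
#' empty cell for missing values.
#'
#' @param records Cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(records, path) {
  out <- records
  out$assessment_date <- format(out$assessment_date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort of assessment records from CSV
#'
#' Parses and validates one assessment per data row. Rows with an
#' unparseable date or an item code outside its dictionary range (and not a
#' declared special code) are dropped and reported: the returned tibble
#' carries a `"row_errors"` attribute with the offending row numbers and
#' messages, and a warning summarises the count. Null person identifiers are
#' preserved here (exclusion is [filter_eligible()]'s job).
#'
#' @param path CSV file path.
#' @param dictionary Item dictionary used to validate item columns.
#' @return Tibble of assessment records; attribute `"row_errors"` is a
#'   tibble (`row`, `message`), empty when the file is clean.
#' @export
read_assessments <- function(path, dictionary = default_item_dictionary()) {
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path), class = "raiqc_schema_error")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = "")
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_cols)) {
    abort(paste0("cohort file is missing mandatory columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "raiqc_schema_error")
  }
  raw <- tibble::as_tibble(raw)
  n <- nrow(raw)
  errors <- list()
  note <- function(rows, msg) {
    if (length(rows)) errors[[length(errors) + 1]] <<- tibble(row = rows, message = msg)
  }

  date <- as.Date(raw$assessment_date, format = "%Y-%m-%d", optional = TRUE)
  bad_date <- which(!is.na(raw$assessment_date) & is.na(date) |
                      is.na(raw$assessment_date))
  note(bad_date, "unparseable or missing assessment_date")

  bad_item <- rep(FALSE, n)
  item_cols <- intersect(dictionary$item, names(raw))
  parsed_items <- list()
  for (it in item_cols) {
    entry <- dictionary[dictionary$item == it, ]
    v <- suppressWarnings(as.integer(raw[[it]]))
    invalid <- !is.na(raw[[it]]) &
      (is.na(v) | !(v %in% c(entry$min_code:entry$max_code, entry$special_codes[[1]])))
    note(which(invalid), paste0("item ", it, ": value outside declared range"))
    bad_item <- bad_item | invalid
    parsed_items[[it]] <- v
  }

  out <- tibble(
    person_id = raw$person_id,
    assessment_date = date,
    jurisdiction = raw$jurisdiction,
    instrument = raw$instrument
  )
  for (cl in LOGICAL_COLUMNS) {
    out[[cl]] <- if (cl %in% names(raw)) as.logical(raw[[cl]]) else NA
  }
  out$sex <- if ("sex" %in% names(raw)) raw$sex else NA_character_
  out$marital_status <- if ("marital_status" %in% names(raw)) raw$marital_status else NA_character_
  out$age_years <- if ("age_years" %in% names(raw)) suppressWarnings(as.integer(raw$age_years)) else NA_integer_
  for (cl in HOUR_COLUMNS) {
    v <- if (cl %in% names(raw)) suppressWarnings(as.numeric(raw[[cl]])) else NA_real_
    neg <- which(!is.na(v) & v < 0)
    note(neg, paste0(cl, ": negative hours"))
    if (length(neg)) bad_item[neg] <- TRUE
    out[[cl]] <- v
  }
  out$rug_category <- if ("rug_category" %in% names(raw)) raw$rug_category else NA_character_
  out$cmi <- if ("cmi" %in% names(raw)) suppressWarnings(as.numeric(raw$cmi)) else NA_real_
  for (it in item_cols) out[[it]] <- parsed_items[[it]]

  # standard column order: metadata first, then items in dictionary order
  keep_rows <- setdiff(seq_len(n), unique(c(bad_date, which(bad_item))))
  out <- out[keep_rows, , drop = FALSE]
  row_errors <- if (length(errors)) {
    dplyr::arrange(bind_rows(errors), .data$row)
  } else {
    tibble(row = integer(), message = character())
  }
  if (nrow(row_errors)) {
    warn(paste0(length(unique(row_errors$row)), " of ", n,
                " rows dropped while reading ", path,
                " (see attr(., 'row_errors'))"))
  }
  attr(out, "row_errors") <- row_errors
  out
}

#' Filter records eligible for analysis
#'
#' Excludes hospital-version assessments and records without a person
#' identifier, preserving input order. Counts of each exclusion reason are
#' attached as the `"exclusions"` attribute (a record failing both rules is
#' attributed to both counters but excluded once).
#'
#' @param records Cohort tibble.
#' @param quiet Suppress the informational message.
#' @return Filtered tibble with attribute `"exclusions"`:
#'   `c(hospital_version =, missing_person_id =)`.
#' @export
filter_eligible <- function(records, quiet = FALSE) {
  hosp <- records$hospital_version %in% TRUE
  noid <- is.na(records$person_id)
  out <- records[!hosp & !noid, , drop = FALSE]
  excl <- c(hospital_version = sum(hosp), missing_person_id = sum(noid))
  if (!quiet) {
    inform(paste0("filter_eligible: retained ", nrow(out), " of ", nrow(records),
                  " records (excluded ", excl[["hospital_version"]],
                  " hospital-version, ", excl[["missing_person_id"]],
                  " missing-identifier)"))
  }
  attr(out, "exclusions") <- excl
  out
}

assessment_year <- function(date) as.integer(format(date, "%Y"))

#' Select the annual record per person: closest to July 1
#'
#' For each person and calendar year, retains the single assessment whose
#' date is closest (in whole days) to July 1 of that year. Ties are broken
#' by the earlier date, then by input order.
#'
#' @param records Eligible records (see [filter_eligible()]).
#' @return Tibble with one row per (person, year), plus a `year` column.
#' @export
select_annual <- function(records) {
  yr <- assessment_year(records$assessment_date)
  july1 <- as.Date(sprintf("%d-07-01", yr))
  dist <- abs(as.integer(records$assessment_date - july1))
  df <- records
  df$year <- yr
  df$.dist <- dist
  df$.pos <- seq_len(nrow(df))
  out <- df %>%
    arrange(.data$person_id, .data$year, .data$.dist, .data$assessment_date,
            .data$.pos) %>%
    group_by(.data$person_id, .data$year) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$.pos)
  out$.dist <- NULL
  out$.pos <- NULL
  out
}

#' Pair the first and second assessments within each person-year
#'
#' For every person-year with two or more assessments, emits one pair: the
#' two earliest assessments by date. Person-years with fewer than two
#' assessments emit nothing. Two assessments sharing an identical date are
#' ordered by input position (with a warning).
#'
#' @param records Eligible records (see [filter_eligible()]).
#' @return Tibble with columns `person_id`, `year`, `first_row`,
#'   `second_row` (row indices into `records`), `first_date`, `second_date`.
#' @export
pair_within_year <- function(records) {
  if (!nrow(records)) {
    return(tibble(person_id = character(), year = integer(),
                  first_row = integer(), second_row = integer(),
                  first_date = as.Date(character()),
                  second_date = as.Date(character())))
  }
  df <- tibble(person_id = records$person_id,
               year = assessment_year(records$assessment_date),
               date = records$assessment_date,
               row = seq_len(nrow(records)))
  df <- df %>%
    arrange(.data$person_id, .data$year, .data$date, .data$row) %>%
    group_by(.data$person_id, .data$year) %>%
    filter(n() >= 2) %>%
    slice(1:2) %>%
    mutate(which = row_number()) %>%
    ungroup()
  if (!nrow(df)) {
    return(tibble(person_id = character(), year = integer(),
                  first_row = integer(), second_row = integer(),
                  first_date = as.Date(character()),
                  second_date = as.Date(character())))
  }
  wide <- df %>%
    select("person_id", "year", "row", "date", "which") %>%
    tidyr::pivot_wider(names_from = "which", values_from = c("row", "date"))
  if (any(wide$date_1 == wide$date_2)) {
    warn(paste0(sum(wide$date_1 == wide$date_2),
                " within-year pair(s) share an identical date; ",
                "ordered by input position"))
  }
  tibble(person_id = wide$person_id, year = wide$year,
         first_row = wide$row_1, second_row = wide$row_2,
         first_date = wide$date_1, second_date = wide$date_2)
}
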