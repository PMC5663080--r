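#' Default latent correlation structure
#'
#' Correlations among the five latent health dimensions (`function`,
#' `cognition`, `mood`, `pain`, `instability`) used by the synthetic
#' generator. The values were calibrated once, by simulation, so that the
#' observed-scale associations land in the ranges reported for home-care
#' populations (ADL hierarchy x cognition around 0.4-0.45, pain x mood
#' around 0.15) and then frozen.
#'
#' @return A 5x5 symmetric positive-definite correlation matrix.
#' @export
default_latent_corr <- function() {
  m <- diag(5)
  dimnames(m) <- list(LATENT_DIMS, LATENT_DIMS)
  set_pair <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  set_pair("function", "cognition", 0.50)
  set_pair("function", "mood", 0.25)
  set_pair("function", "pain", 0.20)
  set_pair("function", "instability", 0.40)
  set_pair("cognition", "mood", 0.15)
  set_pair("cognition", "pain", 0.05)
  set_pair("cognition", "instability", 0.25)
  set_pair("mood", "pain", 0.15)
  set_pair("mood", "instability", 0.20)
  set_pair("pain", "instability", 0.15)
  m
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_persons Number of persons in the cohort.
#' @param years Inclusive vector of calendar years covered; every person gets
#'   one assessment per covered year.
#' @param latent_corr 5x5 correlation matrix over the latent dimensions
#'   (`function`, `cognition`, `mood`, `pain`, `instability`); must have a
#'   unit diagonal and be positive semi-definite.
#' @param drift_per_year Named per-dimension mean shift per calendar year, in
#'   latent SD units. Defaults mirror a population growing steadily more
#'   complex in function, cognition and mood.
#' @param reassessment_prob Probability that a person receives a second,
#'   strictly later assessment within the same calendar year.
#' @param autopop_fraction Fraction of within-year pairs whose second
#'   assessment is a verbatim copy of the first on the designated indicator
#'   sets (see [inject_autopopulation()]).
#' @param missing_id_fraction Fraction of records whose person identifier is
#'   blanked (a record-level defect).
#' @param hospital_version_fraction Fraction of records flagged as hospital
#'   versions of the assessment.
#' @param informal_hours_params List with `shape` and `scale` of the gamma
#'   draw for total weekly informal-care hours and `weekday_fraction`, the
#'   share allocated to weekdays.
#' @param jurisdiction,instrument Labels stamped on every record;
#'   `instrument` is `"RAI-HC"` or `"CHA"`.
#' @param supplement_prob For CHA cohorts, the probability that the
#'   functional supplement is completed; ignored for RAI-HC.
#' @param year_noise_sd SD of the independent latent perturbation applied to
#'   each person-year (on top of the persistent person effect and drift).
#' @param reassessment_step_sd SD of the independent Gaussian step between a
#'   first and second assessment in the same year.
#' @param seed Integer seed; mandatory, so every cohort is reproducible.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_persons = 1000,
                         years = 2003:2014,
                         latent_corr = default_latent_corr(),
                         drift_per_year = c("function" = 0.022, cognition = 0.020,
                                            mood = 0.030, pain = 0.000,
                                            instability = 0.020),
                         reassessment_prob = 0.30,
                         autopop_fraction = 0,
                         missing_id_fraction = 0.01,
                         hospital_version_fraction = 0.03,
                         informal_hours_params = list(shape = 1.3, scale = 15,
                                                      weekday_fraction = 0.72),
                         jurisdiction = "ON",
                         instrument = c("RAI-HC", "CHA"),
                         supplement_prob = 0.6,
                         year_noise_sd = 0.15,
                         reassessment_step_sd = 0.30,
                         seed) {
  if (missing(seed)) config_error("seed", "a seed is mandatory")
  instrument <- match.arg(instrument)
  cfg <- list(n_persons = n_persons, years = sort(unique(as.integer(years))),
              latent_corr = latent_corr, drift_per_year = drift_per_year,
              reassessment_prob = reassessment_prob,
              autopop_fraction = autopop_fraction,
              missing_id_fraction = missing_id_fraction,
              hospital_version_fraction = hospital_version_fraction,
              informal_hours_params = informal_hours_params,
              jurisdiction = jurisdiction, instrument = instrument,
              supplement_prob = supplement_prob,
              year_noise_sd = year_noise_sd,
              reassessment_step_sd = reassessment_step_sd,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

config_error <- function(field, msg) {
  abort(paste0("invalid synthetic-cohort configuration: field `", field, "`: ", msg),
        class = "raiqc_config_error")
}

validate_synth_config <- function(cfg) {
  if (!is.numeric(cfg$n_persons) || length(cfg$n_persons) != 1 ||
      is.na(cfg$n_persons) || cfg$n_persons < 1) {
    config_error("n_persons", "must be a positive count")
  }
  if (!length(cfg$years) || anyNA(cfg$years)) {
    config_error("years", "year range must be nonempty")
  }
  m <- cfg$latent_corr
  if (!is.matrix(m) || !identical(dim(m), c(5L, 5L)) ||
      max(abs(m - t(m))) > 1e-8 || max(abs(diag(m) - 1)) > 1e-8) {
    config_error("latent_corr", "must be a symmetric 5x5 matrix with unit diagonal")
  }
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-9) {
    config_error("latent_corr", "must be positive semi-definite")
  }
  for (field in c("reassessment_prob", "autopop_fraction", "missing_id_fraction",
                  "hospital_version_fraction", "supplement_prob")) {
    p <- cfg[[field]]
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      config_error(field, "must be a probability in [0, 1]")
    }
  }
  ih <- cfg$informal_hours_params
  if (!is.list(ih) || !all(c("shape", "scale", "weekday_fraction") %in% names(ih)) ||
      ih$shape <= 0 || ih$scale <= 0 || ih$weekday_fraction < 0 || ih$weekday_fraction > 1) {
    config_error("informal_hours_params",
                 "needs positive shape/scale and weekday_fraction in [0, 1]")
  }
  if (!is.numeric(cfg$drift_per_year) || length(cfg$drift_per_year) != 5) {
    config_error("drift_per_year", "must give one shift per latent dimension")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    config_error("seed", "must be a single integer")
  }
  cfg
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# MVN draws via eigen decomposition; tolerates semi-definite Sigma.
rmvn_eigen <- function(n, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(rnorm(n * ncol(sigma)), n, ncol(sigma))
  z %*% (t(e$vectors) * sqrt(lam))
}

# Discretize latent records onto each item's ordinal range via fixed
# standard-normal quantile thresholds. `z` is records x 5.
discretize_items <- function(z, dictionary, sigma) {
  out <- vector("list", nrow(dictionary))
  names(out) <- dictionary$item
  for (i in seq_len(nrow(dictionary))) {
    w <- dictionary$loadings[[i]]
    s <- dictionary$noise_sd[i]
    tot_sd <- sqrt(drop(t(w) %*% sigma %*% w) + s^2)
    raw <- (z %*% w + rnorm(nrow(z), sd = s)) / tot_sd
    cuts <- qnorm(cumsum(dictionary$probs[[i]]))
    cuts <- cuts[-length(cuts)]
    out[[i]] <- dictionary$min_code[i] + findInterval(raw, cuts)
  }
  tibble::as_tibble(out)
}

#' Generate a synthetic longitudinal assessment cohort
#'
#' Each person receives one assessment per covered calendar year (date drawn
#' uniformly within the year) and, with probability `reassessment_prob`, a
#' second strictly later assessment the same year whose latent state is the
#' first state plus an independent Gaussian step. Ordinal item codes are
#' produced by discretizing linear combinations of the person-year latent
#' state plus item noise at fixed standard-normal quantile thresholds, so
#' item marginals are set by the dictionary regardless of the correlation
#' structure. Demographic, diagnosis and service fields are tied to the
#' relevant latent dimension through monotone (logistic or log-linear)
#' links. Record-level defects — blanked person identifiers and
#' hospital-version flags — are injected at the configured rates.
#'
#' @param config A [synth_config()].
#' @param dictionary An item dictionary; see [read_item_dictionary()].
#' @return A tibble of assessment records (one row per assessment) in the
#'   cohort CSV schema, ordered by person, year and date. When
#'   `autopop_fraction > 0` the attribute `"autopop_labels"` carries the
#'   ground-truth injected pairs.
#' @export
generate_cohort <- function(config, dictionary = default_item_dictionary()) {
  config <- validate_synth_config(config)
  with_seed(config$seed, generate_cohort_impl(config, dictionary))
}

generate_cohort_impl <- function(config, dictionary) {
  n <- as.integer(config$n_persons)
  years <- config$years
  sigma <- config$latent_corr
  drift <- config$drift_per_year

  person_ids <- sprintf("P%07d", seq_len(n))
  base_z <- rmvn_eigen(n, sigma)

  blocks <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    z1 <- base_z +
      matrix(drift * (k - 1), n, 5, byrow = TRUE) +
      matrix(rnorm(n * 5, sd = config$year_noise_sd), n, 5)
    ndays <- as.integer(as.Date(sprintf("%d-12-31", yr)) -
                          as.Date(sprintf("%d-01-01", yr))) + 1L
    day1 <- sample.int(ndays - 1L, n, replace = TRUE)  # leave room for a reassessment
    reassess <- runif(n) < config$reassessment_prob
    block1 <- tibble(person_id = person_ids, year = yr, day = day1, visit = 1L)
    block1_z <- z1
    if (any(reassess)) {
      idx <- which(reassess)
      gap <- vapply(idx, function(i) sample.int(ndays - day1[i], 1L), integer(1))
      z2 <- z1[idx, , drop = FALSE] +
        matrix(rnorm(length(idx) * 5, sd = config$reassessment_step_sd),
               length(idx), 5)
      block2 <- tibble(person_id = person_ids[idx], year = yr,
                       day = day1[idx] + gap, visit = 2L)
      blocks[[k]] <- list(meta = bind_rows(block1, block2),
                          z = rbind(block1_z, z2))
    } else {
      blocks[[k]] <- list(meta = block1, z = block1_z)
    }
  }
  meta <- bind_rows(lapply(blocks, `[[`, "meta"))
  z <- do.call(rbind, lapply(blocks, `[[`, "z"))

  ord <- order(meta$person_id, meta$year, meta$visit)
  meta <- meta[ord, ]
  z <- z[ord, , drop = FALSE]
  nrec <- nrow(meta)

  items <- discretize_items(z, dictionary, sigma)
  # keep the pain items coherent: intensity 0 iff no pain frequency
  items$pain_intensity[items$pain_frequency == 0] <- 0L
  items$pain_intensity[items$pain_frequency > 0 & items$pain_intensity == 0] <- 1L

  ih <- config$informal_hours_params
  total_hours <- round(rgamma(nrec, shape = ih$shape,
                              scale = ih$scale * exp(0.35 * z[, 1])))
  wk <- round(total_hours * ih$weekday_fraction)

  age <- pmin(105L, pmax(18L, as.integer(round(77 + 8 * (0.5 * z[, 1] +
                                                           rnorm(nrec, sd = 0.9))))))
  plogis_ <- function(x) 1 / (1 + exp(-x))
  records <- tibble(
    person_id = meta$person_id,
    assessment_date = as.Date(sprintf("%d-01-01", meta$year)) + (meta$day - 1L),
    jurisdiction = config$jurisdiction,
    instrument = config$instrument,
    hospital_version = runif(nrec) < config$hospital_version_fraction,
    functional_supplement_completed =
      if (config$instrument == "CHA") runif(nrec) < config$supplement_prob else NA,
    sex = ifelse(runif(nrec) < 0.66, "F", "M"),
    marital_status = ifelse(runif(nrec) < 0.38, "married", "not_married"),
    age_years = age,
    dementia = runif(nrec) < plogis_(-2.2 + 1.5 * z[, 2]),
    heart_failure = runif(nrec) < plogis_(-2.1 + 0.8 * z[, 5]),
    svc_pt = runif(nrec) < plogis_(-2.3 + 0.4 * z[, 1]),
    svc_ot = runif(nrec) < plogis_(-2.4 + 0.4 * z[, 1]),
    svc_nursing = runif(nrec) < plogis_(-0.9 + 0.3 * z[, 5]),
    svc_psw = runif(nrec) < plogis_(0.8 + 0.5 * z[, 1]),
    informal_hours_weekday = wk,
    informal_hours_weekend = total_hours - wk,
    rug_category = cut(z[, 1], breaks = c(-Inf, 0.15, 1.97, Inf),
                       labels = c("Reduced Physical Function", "Clinically Complex",
                                  "Extensive Services")) |> as.character(),
    cmi = round(0.30 + 0.60 * exp(0.35 * z[, 1] + 0.10 * z[, 5]), 2)
  )
  records <- dplyr::bind_cols(records, items)

  # CHA records without the functional supplement lack its items
  if (config$instrument == "CHA") {
    no_fs <- !records$functional_supplement_completed
    fs_items <- dictionary$item[dictionary$fs_dependent]
    records[no_fs, fs_items] <- NA_integer_
  }

  if (config$autopop_fraction > 0) {
    records <- inject_autopopulation(records, config$autopop_fraction,
                                     seed = derive_seed(config$seed, 1L),
                                     dictionary = dictionary)
  }
  labels <- attr(records, "autopop_labels")

  blank <- runif(nrec) < config$missing_id_fraction
  records$person_id[blank] <- NA_character_

  attr(records, "autopop_labels") <- labels
  records
}

derive_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 7 + 1000003 * k) %% 2147483647)
}

#' Default indicator sets used for auto-population injection and detection
#'
#' Six sets: summed weekday+weekend informal-care hours, the 9 ADL items,
#' the 7 IADL performance items, the 7 IADL capacity items, the 14 combined
#' IADL items, and the 9 mood items.
#'
#' @param dictionary An item dictionary.
#' @return Named list; the `informal_hours` entry is the two hour fields,
#'   all others are item-code vectors.
#' @export
default_indicator_sets <- function(dictionary = default_item_dictionary()) {
  list(informal_hours = c("informal_hours_weekday", "informal_hours_weekend"),
       adl = item_set(dictionary, "adl9"),
       iadl_performance = item_set(dictionary, "iadl_perf7"),
       iadl_capacity = item_set(dictionary, "iadl_cap7"),
       iadl_both = item_set(dictionary, "iadl_both14"),
       mood = item_set(dictionary, "mood9"))
}

#' Inject auto-population (carry-forward) into within-year pairs
#'
#' For a Bernoulli(`fraction`) subset of the eligible within-year assessment
#' pairs, overwrites the second record's values on every field of each
#' designated indicator set with the first record's values — emulating an
#' assessor copying those sections forward instead of re-assessing them.
#'
#' @param records A cohort tibble (see [generate_cohort()]).
#' @param fraction Probability that a pair is overwritten.
#' @param indicator_sets Named list of field sets to copy; defaults to the
#'   five distinct sections underlying [default_indicator_sets()] (the
#'   combined IADL set is implied by its two halves).
#' @param seed Integer seed for the Bernoulli draw.
#' @param dictionary Item dictionary used to validate item codes.
#' @return The records, with attribute `"autopop_labels"`: a tibble of
#'   (`person_id`, `year`, `injected`) giving the ground truth for every
#'   within-year pair.
#' @export
inject_autopopulation <- function(records, fraction,
                                  indicator_sets = NULL,
                                  seed,
                                  dictionary = default_item_dictionary()) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    config_error("fraction", "must be a probability in [0, 1]")
  }
  if (is.null(indicator_sets)) {
    indicator_sets <- default_indicator_sets(dictionary)
    indicator_sets$iadl_both <- NULL
  }
  hour_fields <- c("informal_hours_weekday", "informal_hours_weekend")
  for (nm in names(indicator_sets)) {
    fields <- indicator_sets[[nm]]
    bad <- setdiff(fields, c(dictionary$item, hour_fields))
    if (length(bad)) {
      abort(paste0("indicator set `", nm, "` names unknown item codes: ",
                   paste(bad, collapse = ", ")),
            class = "raiqc_schema_error")
    }
  }
  elig_idx <- which(!records$hospital_version & !is.na(records$person_id))
  pairs <- pair_within_year(records[elig_idx, ])
  pairs$first_row <- elig_idx[pairs$first_row]
  pairs$second_row <- elig_idx[pairs$second_row]
  labels <- tibble(person_id = pairs$person_id, year = pairs$year,
                   injected = FALSE)
  if (nrow(labels) && fraction > 0) {
    labels$injected <- with_seed(seed, runif(nrow(labels)) < fraction)
    copy_fields <- unique(unlist(indicator_sets))
    to <- pairs$second_row[labels$injected]
    from <- pairs$first_row[labels$injected]
    records[to, copy_fields] <- records[from, copy_fields]
  }
  attr(records, "autopop_labels") <- labels
  records
}
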