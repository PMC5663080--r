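# Orchestration: file-level pipeline stages and the full report bundle.
# Each stage reads/writes the cohort CSV dialect, so the full pipeline is
# exactly the chain of its subcommands.

#' Read a run configuration file (JSON or YAML)
#'
#' The configuration names one or two cohorts, each with exactly one of
#' `input` (a cohort CSV path) or `synth` (arguments for [synth_config()]),
#' and a mandatory top-level `seed`.
#'
#' @param path Configuration file; `.json` (always supported) or
#'   `.yaml`/`.yml` (requires the yaml package).
#' @return Validated run-config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("run config not found: ", path), class = "raiqc_config_error")
  }
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML config requires the yaml package", class = "raiqc_config_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$seed)) config_error("seed", "a seed is mandatory")
  if (is.null(cfg$cohorts) || !length(cfg$cohorts)) {
    config_error("cohorts", "at least one cohort must be configured")
  }
  if (is.null(names(cfg$cohorts)) || any(!nzchar(names(cfg$cohorts)))) {
    config_error("cohorts", "cohorts must be named")
  }
  for (nm in names(cfg$cohorts)) {
    co <- cfg$cohorts[[nm]]
    has_input <- !is.null(co$input)
    has_synth <- !is.null(co$synth)
    if (has_input == has_synth) {
      config_error(paste0("cohorts$", nm),
                   "exactly one of `input` or `synth` must be given")
    }
  }
  cfg
}

resolve_synth <- function(synth, seed) {
  if (inherits(synth, "synth_config")) return(synth)
  args <- synth
  if (!is.null(args$latent_corr)) {
    args$latent_corr <- matrix(unlist(args$latent_corr), 5, 5)
  }
  if (!is.null(args$drift_per_year)) {
    args$drift_per_year <- unlist(args$drift_per_year)
  }
  if (!is.null(args$years)) args$years <- do.call(seq, as.list(range(unlist(args$years))))
  if (is.null(args$seed)) args$seed <- seed
  do.call(synth_config, args)
}

#' @rdname pipeline_stages
#' @export
pipeline_simulate <- function(synth, path, dictionary = default_item_dictionary()) {
  records <- generate_cohort(resolve_synth(synth, seed = NULL), dictionary)
  write_assessments(records, path)
}

#' @rdname pipeline_stages
#' @export
pipeline_score <- function(in_csv, out_csv, dictionary = default_item_dictionary()) {
  records <- read_assessments(in_csv, dictionary)
  write_assessments(score_assessments(records, dictionary), out_csv)
}

# Filter, select annually, and score a cohort file.
prepare_selection <- function(in_csv, dictionary) {
  records <- read_assessments(in_csv, dictionary)
  eligible <- filter_eligible(records)
  scored <- score_assessments(select_annual(eligible), dictionary)
  list(records = records, eligible = eligible, scored = scored,
       exclusions = attr(eligible, "exclusions"))
}

# Serialize a family of trend tables as years-by-metrics CSV with the
# summary (mean, SD) rows last.
write_trend_family <- function(tables, path) {
  years <- sort(unique(unlist(lapply(tables, function(t) t$values$year))))
  out <- tibble(year = as.character(years))
  for (t in tables) {
    v <- setNames(t$values$value, t$values$year)
    out[[t$metric]] <- unname(v[out$year])
  }
  summary_rows <- tibble(year = c("mean", "sd"))
  for (t in tables) {
    summary_rows[[t$metric]] <- unname(t$summary[c("mean", "sd")])
  }
  write.csv(bind_rows(out, summary_rows), path, row.names = FALSE, na = "")
  invisible(path)
}

standard_trend_tables <- function(scored) {
  list(
    demographics = list(
      annual_prevalence(scored, function(d) d$sex == "F", "Female (%)"),
      annual_prevalence(scored, function(d) d$marital_status == "married", "Married (%)"),
      annual_prevalence(scored, function(d) d$age_years < 65, "Under 65 (%)"),
      annual_prevalence(scored, function(d) d$age_years > 85, "Over 85 (%)"),
      annual_prevalence(scored, "dementia", "Dementia (%)"),
      annual_prevalence(scored, "heart_failure", "Heart Failure (%)")
    ),
    clinical = list(
      annual_prevalence(scored, "cps_ge3", "CPS >= 3 (%)"),
      annual_prevalence(scored, "drs_ge3", "DRS >= 3 (%)"),
      annual_prevalence(scored, "maple_ge3", "MAPLe >= 3 (%)"),
      annual_prevalence(scored, "adlh_ge3", "ADLH >= 3 (%)"),
      annual_prevalence(scored, "iadl_cap_ge3", "IADL (cap) >= 3 (%)"),
      annual_prevalence(scored, "iadl_perf_ge3", "IADL (perf) >= 3 (%)")
    ),
    service = list(
      annual_mean(scored, "informal_hours_total", "Mean Total Informal Hours of Care"),
      annual_prevalence(scored, "svc_pt", "Any PT (%)"),
      annual_prevalence(scored, "svc_ot", "Any OT (%)"),
      annual_prevalence(scored, "svc_nursing", "Any Nursing (%)"),
      annual_prevalence(scored, "svc_psw", "Any PSW (%)")
    ),
    resource = list(
      annual_prevalence(scored,
                        function(d) d$rug_category == "Reduced Physical Function",
                        "RUG-III/HC Reduced Physical Function (%)"),
      annual_prevalence(scored,
                        function(d) d$rug_category == "Extensive Services",
                        "RUG-III/HC Extensive Services (%)"),
      annual_mean(scored, "cmi", "Mean CMI")
    )
  )
}

#' File-level pipeline stages
#'
#' Each stage reads the cohort CSV dialect and writes CSV artifacts, so the
#' full pipeline ([run_pipeline()]) is exactly the chain of these
#' subcommands.
#'
#' @param synth A [synth_config()] or an argument list for it.
#' @param path,in_csv,out_csv,out_dir File locations.
#' @param dictionary Item dictionary.
#' @param battery_a,battery_b Battery CSVs written by `pipeline_battery`.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
pipeline_trends <- function(in_csv, out_dir, dictionary = default_item_dictionary()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prep <- prepare_selection(in_csv, dictionary)
  fams <- standard_trend_tables(prep$scored)
  for (fam in names(fams)) {
    write_trend_family(fams[[fam]], file.path(out_dir, paste0(fam, ".csv")))
  }
  invisible(out_dir)
}

#' @rdname pipeline_stages
#' @export
pipeline_validity <- function(in_csv, out_csv, dictionary = default_item_dictionary()) {
  prep <- prepare_selection(in_csv, dictionary)
  write_trend_family(validity_trends(prep$scored), out_csv)
}

#' @rdname pipeline_stages
#' @export
pipeline_reliability <- function(in_csv, out_csv, dictionary = default_item_dictionary()) {
  prep <- prepare_selection(in_csv, dictionary)
  write_trend_family(reliability_trends(prep$scored, dictionary), out_csv)
}

#' @rdname pipeline_stages
#' @export
pipeline_autopop <- function(in_csv, out_csv, dictionary = default_item_dictionary()) {
  records <- read_assessments(in_csv, dictionary)
  eligible <- filter_eligible(records)
  pairs <- pair_within_year(eligible)
  if (!nrow(pairs)) {
    inform("auto-population analysis skipped: no within-year reassessment pairs")
    return(invisible(NULL))
  }
  report <- autopopulation_rates(eligible, pairs, dictionary)
  write.csv(as.data.frame(report), out_csv, row.names = FALSE)
  invisible(out_csv)
}

#' @rdname pipeline_stages
#' @export
pipeline_battery <- function(in_csv, out_csv, dictionary = default_item_dictionary()) {
  prep <- prepare_selection(in_csv, dictionary)
  battery <- indicator_battery(prep$scored, dictionary = dictionary)
  write.csv(as.data.frame(battery), out_csv, row.names = FALSE)
  invisible(out_csv)
}

#' @rdname pipeline_stages
#' @export
pipeline_compare <- function(battery_a, battery_b, out_csv) {
  read_battery <- function(p) {
    b <- tibble::as_tibble(read.csv(p, stringsAsFactors = FALSE))
    class(b) <- c("indicator_battery", class(b))
    b
  }
  cmp <- compare_batteries(read_battery(battery_a), read_battery(battery_b))
  write.csv(cmp$pairs, out_csv, row.names = FALSE)
  attr(out_csv, "r_squared") <- cmp$r_squared
  invisible(structure(out_csv, r_squared = cmp$r_squared))
}

#' Run the full data-quality pipeline
#'
#' Executes, per configured cohort: simulation (or ingestion), eligibility
#' filtering, annual selection, scale scoring, the four standard trend-table
#' families, convergent-validity and reliability trends, auto-population
#' rates (skipped with a logged notice when the cohort has no within-year
#' reassessment pairs), and the indicator battery. With two cohorts, their
#' batteries are compared and the R-squared recorded in the manifest. All
#' artifacts are CSV; a JSON manifest with the configuration, seed and
#' config hash is written last, so a bundle without a manifest is
#' incomplete.
#'
#' @param config Run-config list (see [read_run_config()]) or a path to one.
#' @param out_dir Output directory (created if needed).
#' @param dictionary Item dictionary.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, dictionary = default_item_dictionary()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)),
            class = "raiqc_pipeline_error")
    })
  }
  battery_files <- character()
  cohort_info <- list()
  for (nm in names(config$cohorts)) {
    co <- config$cohorts[[nm]]
    cdir <- file.path(out_dir, nm)
    dir.create(cdir, showWarnings = FALSE)
    cohort_csv <- file.path(cdir, "cohort.csv")
    if (!is.null(co$synth)) {
      stage(paste0(nm, "/simulate"), {
        synth <- resolve_synth(co$synth, seed = config$seed)
        pipeline_simulate(synth, cohort_csv, dictionary)
      })
    } else {
      stage(paste0(nm, "/ingest"), file.copy(co$input, cohort_csv, overwrite = TRUE))
    }
    stage(paste0(nm, "/score"),
          pipeline_score(cohort_csv, file.path(cdir, "scored.csv"), dictionary))
    stage(paste0(nm, "/trends"), pipeline_trends(cohort_csv, cdir, dictionary))
    stage(paste0(nm, "/validity"),
          pipeline_validity(cohort_csv, file.path(cdir, "validity.csv"), dictionary))
    stage(paste0(nm, "/reliability"),
          pipeline_reliability(cohort_csv, file.path(cdir, "reliability.csv"),
                               dictionary))
    autopop_out <- stage(paste0(nm, "/autopop"),
                         pipeline_autopop(cohort_csv,
                                          file.path(cdir, "autopopulation.csv"),
                                          dictionary))
    bfile <- file.path(cdir, "battery.csv")
    stage(paste0(nm, "/battery"), pipeline_battery(cohort_csv, bfile, dictionary))
    battery_files[nm] <- bfile
    cohort_info[[nm]] <- list(autopopulation = !is.null(autopop_out))
  }
  r_squared <- NULL
  if (length(battery_files) == 2) {
    cmp <- stage("compare",
                 pipeline_compare(battery_files[[1]], battery_files[[2]],
                                  file.path(out_dir, "comparison.csv")))
    r_squared <- attr(cmp, "r_squared")
  }
  manifest <- list(
    package = "raiqc",
    version = as.character(utils::packageVersion("raiqc")),
    seed = config$seed,
    config = config,
    config_hash = config_hash(config),
    cohorts = cohort_info,
    battery_r_squared = r_squared,
    conventions = list(correlation_deletion = "pairwise",
                       alpha_deletion = "listwise",
                       r_squared = "squared Pearson correlation of paired indicator values",
                       annual_sd = "sample (n-1)")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
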