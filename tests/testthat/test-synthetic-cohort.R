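test_that("invalid configurations are rejected naming the offending field", {
  expect_error(synth_config(n_persons = 0, seed = 1),
               "n_persons", class = "raiqc_config_error")
  expect_error(synth_config(reassessment_prob = 1.2, seed = 1),
               "reassessment_prob", class = "raiqc_config_error")
  expect_error(synth_config(years = integer(), seed = 1),
               "years", class = "raiqc_config_error")
  bad <- default_latent_corr()
  bad[1, 2] <- bad[2, 1] <- 2  # not a correlation
  expect_error(synth_config(latent_corr = bad, seed = 1),
               "latent_corr", class = "raiqc_config_error")
  expect_error(synth_config(n_persons = 10), class = "raiqc_config_error")
})

test_that("generation is deterministic given the seed", {
  cfg <- synth_config(n_persons = 60, years = 2010:2011, autopop_fraction = 0.3,
                      seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
})

test_that("every generated code respects the dictionary; dates sit inside years", {
  cfg <- synth_config(n_persons = 400, years = 2008:2010, reassessment_prob = 0.5,
                      seed = 9)
  rec <- generate_cohort(cfg)
  for (i in seq_len(nrow(dict))) {
    v <- rec[[dict$item[i]]]
    v <- v[!is.na(v)]
    expect_true(all(v %in% c(dict$min_code[i]:dict$max_code[i],
                             dict$special_codes[[i]])),
                label = paste("codes in range for", dict$item[i]))
  }
  yr <- as.integer(format(rec$assessment_date, "%Y"))
  expect_true(all(yr %in% 2008:2010))
  # each person-year: one or two assessments, second strictly later
  pairs <- pair_within_year(filter_eligible(rec, quiet = TRUE))
  expect_true(all(pairs$first_date < pairs$second_date))
})

test_that("defect rates are injected as configured", {
  cfg <- synth_config(n_persons = 4000, years = 2010, reassessment_prob = 0,
                      missing_id_fraction = 0.05, hospital_version_fraction = 0.1,
                      seed = 3)
  rec <- generate_cohort(cfg)
  expect_gt(mean(is.na(rec$person_id)), 0.03)
  expect_lt(mean(is.na(rec$person_id)), 0.07)
  expect_gt(mean(rec$hospital_version), 0.08)
  expect_lt(mean(rec$hospital_version), 0.12)
})

test_that("raising the function-cognition correlation raises the observed ADLHxCPS r", {
  base <- diag(5)
  lo <- hi <- base
  hi[1, 2] <- hi[2, 1] <- 0.8
  r_obs <- function(m) {
    cfg <- synth_config(n_persons = 20000, years = 2010, reassessment_prob = 0,
                        missing_id_fraction = 0, hospital_version_fraction = 0,
                        latent_corr = m, drift_per_year = rep(0, 5), seed = 21)
    sc <- score_assessments(select_annual(filter_eligible(generate_cohort(cfg),
                                                          quiet = TRUE)))
    pearson_r(sc$adl_hierarchy, sc$cps)
  }
  expect_lt(r_obs(lo), r_obs(hi))
})

test_that("positive drift in function yields a nondecreasing %ADLH>=3 year series in expectation", {
  drift <- c(0.06, 0, 0, 0, 0)
  series <- sapply(1:10, function(s) {
    cfg <- synth_config(n_persons = 1500, years = 2003:2008, reassessment_prob = 0,
                        missing_id_fraction = 0, hospital_version_fraction = 0,
                        drift_per_year = drift, seed = 100 + s)
    sc <- score_assessments(select_annual(filter_eligible(generate_cohort(cfg),
                                                          quiet = TRUE)))
    tab <- annual_prevalence(sc, "adlh_ge3", "ADLH >= 3 (%)")
    tab$values$value[order(tab$values$year)]
  })
  avg <- rowMeans(series)
  expect_true(all(diff(avg) > -0.5))  # nondecreasing up to sampling jitter
  expect_gt(avg[6], avg[1])
})

test_that("auto-population injection honours fraction extremes and labels", {
  cfg <- synth_config(n_persons = 300, years = 2010, reassessment_prob = 1,
                      missing_id_fraction = 0, hospital_version_fraction = 0,
                      seed = 8)
  rec <- generate_cohort(cfg)
  sets <- default_indicator_sets(dict)

  none <- inject_autopopulation(rec, 0, seed = 1)
  expect_identical(strip_attrs(none), strip_attrs(rec))
  expect_true(all(!attr(none, "autopop_labels")$injected))

  all_in <- inject_autopopulation(rec, 1, seed = 1)
  labels <- attr(all_in, "autopop_labels")
  expect_true(all(labels$injected))
  pairs <- pair_within_year(filter_eligible(all_in, quiet = TRUE))
  items <- unique(unlist(sets[setdiff(names(sets), "informal_hours")]))
  m1 <- as.matrix(all_in[pairs$first_row, items])
  m2 <- as.matrix(all_in[pairs$second_row, items])
  expect_true(all(m1 == m2))
  expect_true(all(all_in$informal_hours_weekday[pairs$first_row] ==
                    all_in$informal_hours_weekday[pairs$second_row]))
})

test_that("injected share matches the Bernoulli fraction within binomial bounds", {
  cfg <- synth_config(n_persons = 5000, years = 2010, reassessment_prob = 1,
                      missing_id_fraction = 0, hospital_version_fraction = 0,
                      seed = 13)
  rec <- generate_cohort(cfg)
  lab <- attr(inject_autopopulation(rec, 0.3, seed = 99), "autopop_labels")
  n <- nrow(lab)
  expect_gte(n, 4500)
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.3) / n
  expect_gte(mean(lab$injected), bounds[1])
  expect_lte(mean(lab$injected), bounds[2])
})

test_that("unknown item codes in indicator sets raise a schema error", {
  cfg <- synth_config(n_persons = 50, years = 2010, reassessment_prob = 1,
                      missing_id_fraction = 0, hospital_version_fraction = 0,
                      seed = 2)
  rec <- generate_cohort(cfg)
  expect_error(inject_autopopulation(rec, 0.5, indicator_sets = list(x = "no_such_item"),
                                     seed = 1),
               class = "raiqc_schema_error")
})
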