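test_that("sum scales hit their floors, ceilings and hand-computed sums", {
  zeros <- full_items()
  expect_equal(adl_long_form(zeros), 0L)
  expect_equal(iadl_performance(zeros), 0L)
  expect_equal(iadl_capacity(zeros), 0L)
  expect_equal(drs(zeros), 0L)

  adl_max <- full_items(adl_bed_mobility = 4, adl_transfer = 4, adl_locomotion = 4,
                        adl_dressing = 4, adl_eating = 4, adl_toilet_use = 4,
                        adl_hygiene = 4)
  expect_equal(adl_long_form(adl_max), 28L)
  expect_equal(iadl_performance(full_items(iadl_meal_prep_perf = 3,
                                           iadl_housework_perf = 3,
                                           iadl_phone_perf = 3)), 9L)
  expect_equal(iadl_capacity(full_items(iadl_meal_prep_cap = 2,
                                        iadl_housework_cap = 1,
                                        iadl_phone_cap = 0)), 3L)
  drs_max <- full_items(mood_negative_statements = 3, mood_anger = 2,
                        mood_unrealistic_fears = 2, mood_health_complaints = 3,
                        mood_anxious_complaints = 2, mood_sad_expression = 2,
                        mood_crying = 2)
  expect_equal(drs(drs_max), 14L)  # items cap at 2 before summing

  hand <- full_items(adl_bed_mobility = 1, adl_transfer = 2, adl_locomotion = 0,
                     adl_dressing = 3, adl_eating = 0, adl_toilet_use = 1,
                     adl_hygiene = 1)
  expect_equal(adl_long_form(hand), 8L)
  expect_equal(drs(full_items(mood_negative_statements = 2, mood_unrealistic_fears = 1,
                              mood_anxious_complaints = 1)), 4L)
})

test_that("special code 8 recodes to maximal dependence; bad codes error by item name", {
  eight <- full_items(adl_dressing = 8)
  expect_equal(adl_long_form(eight), 4L)
  expect_error(adl_long_form(full_items(adl_dressing = 5)), "adl_dressing",
               class = "raiqc_scoring_error")
  expect_error(iadl_performance(full_items(iadl_phone_perf = -1)), "iadl_phone_perf",
               class = "raiqc_scoring_error")
})

test_that("missing items null the scale rather than guessing", {
  x <- full_items(.n = 2)
  x$adl_eating[2] <- NA_integer_
  out <- adl_long_form(x)
  expect_equal(out[1], 0L)
  expect_true(is.na(out[2]))
})

test_that("pain scale obeys its fixed extremes and is monotone and total", {
  expect_equal(pain_scale(0L, 0L), 0L)
  expect_equal(pain_scale(0L, 3L), 0L)  # no pain floors the scale
  expect_equal(pain_scale(2L, 3L), 3L)  # daily severe pain
  grid <- expand.grid(f = 0:2, i = 0:3)
  v <- pain_scale(grid$f, grid$i)
  expect_false(anyNA(v))
  expect_true(all(v %in% 0:3))
  # nondecreasing in both arguments
  for (f in 0:2) expect_true(all(diff(pain_scale(rep(f, 4), 0:3)) >= 0))
  for (i in 0:3) expect_true(all(diff(pain_scale(0:2, rep(i, 3))) >= 0))
  expect_error(pain_scale(5L, 0L), class = "raiqc_scoring_error")
})

test_that("hierarchical scales hit floors and ceilings", {
  intact <- full_items()
  expect_equal(cps(intact), 0L)
  expect_equal(adl_hierarchy(intact), 0L)
  expect_equal(chess(intact), 0L)

  worst <- full_items(cog_short_term_memory = 1, cog_decision_making = 3,
                      cog_making_self_understood = 3, cog_comatose = 1,
                      adl_hygiene = 4, adl_toilet_use = 4, adl_locomotion = 4,
                      adl_eating = 4,
                      sym_vomiting = 1, sym_dehydration = 1,
                      sym_insufficient_fluid = 1, sym_weight_loss = 1,
                      sym_dyspnea = 1, sym_edema = 1, decline_decision = 1,
                      decline_adl = 1, end_stage_disease = 1)
  expect_equal(cps(worst), 6L)
  expect_equal(adl_hierarchy(worst), 6L)
  expect_equal(chess(worst), 5L)
})

test_that("CPS mid-severity fixtures match the hand-traced tree", {
  # two impairments, none severe -> 2
  expect_equal(cps(full_items(cog_short_term_memory = 1, cog_decision_making = 1)), 2L)
  # one impairment -> 1
  expect_equal(cps(full_items(cog_making_self_understood = 1)), 1L)
  # two impairments, one severe -> 3
  expect_equal(cps(full_items(cog_decision_making = 2,
                              cog_making_self_understood = 1)), 3L)
  # both severe -> 4
  expect_equal(cps(full_items(cog_decision_making = 2,
                              cog_making_self_understood = 2)), 4L)
  # severely impaired decisions -> 5, or 6 with total eating dependence
  expect_equal(cps(full_items(cog_decision_making = 3, adl_eating = 2)), 5L)
  expect_equal(cps(full_items(cog_decision_making = 3, adl_eating = 4)), 6L)
})

test_that("ADL hierarchy mid-severity fixtures match the hand-traced tree", {
  expect_equal(adl_hierarchy(full_items(adl_hygiene = 1)), 1L)
  expect_equal(adl_hierarchy(full_items(adl_toilet_use = 2, adl_hygiene = 1)), 2L)
  expect_equal(adl_hierarchy(full_items(adl_hygiene = 3, adl_locomotion = 2)), 3L)
  expect_equal(adl_hierarchy(full_items(adl_locomotion = 4, adl_hygiene = 3)), 4L)
  expect_equal(adl_hierarchy(full_items(adl_eating = 3)), 5L)
})

test_that("CHESS counts symptoms (capped) plus declines and end-stage disease", {
  expect_equal(chess(full_items(sym_dyspnea = 1)), 1L)
  expect_equal(chess(full_items(sym_dyspnea = 1, sym_edema = 1, sym_vomiting = 1)), 2L)
  expect_equal(chess(full_items(sym_dyspnea = 1, decline_adl = 1)), 2L)
  expect_equal(chess(full_items(sym_dyspnea = 1, sym_edema = 1,
                                decline_adl = 1, decline_decision = 1)), 4L)
})

test_that("MAPLe levels follow the documented drivers", {
  lvl <- function(items, adlh = 0L, cps_score = 0L, iadl_cap = 0L) {
    maple(items, adlh, cps_score, iadl_cap)
  }
  expect_equal(lvl(full_items()), 1L)
  expect_equal(lvl(full_items(), iadl_cap = 1L), 2L)
  expect_equal(lvl(full_items(falls = 1)), 3L)
  expect_equal(lvl(full_items(), adlh = 1L), 3L)
  expect_equal(lvl(full_items(beh_behaviour_symptoms = 1)), 4L)
  expect_equal(lvl(full_items(), adlh = 3L, cps_score = 1L), 4L)
  expect_equal(lvl(full_items(beh_wandering = 1)), 5L)
  expect_equal(lvl(full_items(), adlh = 3L, cps_score = 3L), 5L)
})

test_that("random valid item codings stay inside every declared range", {
  set.seed(77)
  for (rep in 1:20) {
    items <- tibble::as_tibble(lapply(stats::setNames(seq_len(nrow(dict)), dict$item),
      function(i) sample(dict$min_code[i]:dict$max_code[i], 25, replace = TRUE)))
    expect_true(all(adl_long_form(items) %in% 0:28))
    expect_true(all(iadl_performance(items) %in% 0:9))
    expect_true(all(iadl_capacity(items) %in% 0:6))
    expect_true(all(drs(items) %in% 0:14))
    expect_true(all(cps(items) %in% 0:6))
    expect_true(all(adl_hierarchy(items) %in% 0:6))
    expect_true(all(chess(items) %in% 0:5))
    expect_true(all(pain_scale(items$pain_frequency, items$pain_intensity) %in% 0:3))
    expect_true(all(maple(items, adl_hierarchy(items), cps(items),
                          iadl_capacity(items)) %in% 1:5))
  }
})

test_that("sum scales are monotone in every constituent item", {
  set.seed(42)
  base <- full_items(adl_bed_mobility = 2, adl_transfer = 1, adl_dressing = 3,
                     mood_sad_expression = 1, iadl_meal_prep_perf = 2)
  for (it in item_set(dict, "adl_long_form")) {
    bumped <- base
    bumped[[it]] <- pmin(bumped[[it]] + 1L, 4L)
    expect_gte(adl_long_form(bumped), adl_long_form(base))
  }
  for (it in item_set(dict, "drs")) {
    bumped <- base
    bumped[[it]] <- pmin(bumped[[it]] + 1L, 3L)
    expect_gte(drs(bumped), drs(base))
  }
})

test_that("scoring a cohort gates supplement-dependent scores for CHA", {
  rec <- make_records(c("A", "B"), "2013-06-01", instrument = "CHA",
                      functional_supplement_completed = c(TRUE, FALSE))
  sc <- score_assessments(rec)
  expect_false(is.na(sc$maple[1]))
  expect_true(is.na(sc$maple[2]))
})
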