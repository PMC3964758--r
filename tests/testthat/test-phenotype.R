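activity_row <- function(individual_id = "p1", survey_wave = "2010",
                         age_at_survey = 30, activity_name = "running",
                         met_value = 8, years_participated = 2,
                         months_per_year = 10, times_per_week = 3,
                         minutes_per_session = 60, leisure_flag = TRUE,
                         injured_at_survey = FALSE) {
  data.frame(individual_id, survey_wave, age_at_survey, activity_name,
             met_value, years_participated, months_per_year, times_per_week,
             minutes_per_session, leisure_flag, injured_at_survey,
             stringsAsFactors = FALSE)
}

test_that("regularity filter enforces the 3-months and half-year rules", {
  recs <- rbind(
    activity_row(months_per_year = 2),                      # too few months
    activity_row(years_participated = 0.4),                 # too short
    activity_row(leisure_flag = FALSE),                     # transportation etc.
    activity_row(months_per_year = 3, years_participated = 0.5))
  kept <- filter_regular_leisure(recs)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$months_per_year, 3)
  # pass-through: retained record is unchanged and order preserved
  recs2 <- rbind(activity_row(activity_name = "soccer"),
                 activity_row(activity_name = "tennis"))
  expect_identical(filter_regular_leisure(recs2), recs2)
})

test_that("weekly MET hours follow the MET x frequency x duration product", {
  expect_equal(met_hours(activity_row(met_value = 8, times_per_week = 3,
                                      minutes_per_session = 60)), 24)
  expect_equal(met_hours(activity_row()[0, ]), 0)
  # two activities summing to 130 truncate at 120
  recs <- rbind(activity_row(met_value = 10, times_per_week = 6,
                             minutes_per_session = 60),   # 60
                activity_row(met_value = 7, times_per_week = 6,
                             minutes_per_session = 100))  # 70
  expect_equal(met_hours(recs), 120)
  expect_equal(met_hours(recs, cap = Inf), 130)
  expect_error(met_hours(activity_row(minutes_per_session = -5)),
               "validation error")
})

test_that("met_hours is monotone and homogeneous before the cap", {
  base <- activity_row(met_value = 6, times_per_week = 2,
                       minutes_per_session = 45)
  v0 <- met_hours(base)
  expect_equal(met_hours(transform(base, minutes_per_session = 90)), 2 * v0)
  expect_gte(met_hours(transform(base, met_value = 7)), v0)
  expect_gte(met_hours(transform(base, times_per_week = 3)), v0)
  # filtering is idempotent
  f1 <- filter_regular_leisure(base)
  expect_identical(filter_regular_leisure(f1), f1)
})

test_that("MET lookup is age-stratified and strict about unknowns", {
  tab <- load_met_table()
  expect_equal(met_lookup("squash", 12), tab$met_youth[tab$activity == "squash"])
  expect_equal(met_lookup("squash", 30), tab$met_adult[tab$activity == "squash"])
  # 17 vs 18 straddles the two compendia
  expect_equal(met_lookup("squash", 17), tab$met_youth[tab$activity == "squash"])
  expect_equal(met_lookup("squash", 18), tab$met_adult[tab$activity == "squash"])
  expect_error(met_lookup("quidditch", 25), "lookup error")
})

test_that("longitudinal merge prefers recent adult data and honours exclusions", {
  recs <- data.frame(
    individual_id = c("a", "a", "b", "c", "c", "c", "c"),
    survey_wave = c("2010", "1998", "2008", "1995", "2000", "2006", "2011"),
    age_at_survey = c(30, 18, 51, 10, 15, 21, 26),
    injured_at_survey = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    weekly_met_hours = c(12, 30, 5, 8, 20, 14, 2),
    stringsAsFactors = FALSE)
  out <- merge_longitudinal(recs)
  # a: most recent adult wave wins over the older one
  expect_equal(out$weekly_met_hours[out$individual_id == "a"], 12)
  expect_equal(out$source_wave[out$individual_id == "a"], "2010")
  # b: only record is above age 50 -> absent from output
  expect_false("b" %in% out$individual_id)
  # c: injured most recent wave dropped, earlier adult wave used
  expect_equal(out$weekly_met_hours[out$individual_id == "c"], 14)
  expect_equal(out$source_stratum[out$individual_id == "c"], "adult")
})

test_that("merge precedence matches a rule-by-rule oracle on random cases", {
  oracle_merge_one <- function(d) {
    d <- d[d$age_at_survey <= 50 & !d$injured_at_survey, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    stratum <- ifelse(d$age_at_survey >= 18, "adult",
                      ifelse(d$age_at_survey >= 13, "adolescent", "child"))
    for (s in c("adult", "adolescent", "child")) {
      sub <- d[stratum == s, , drop = FALSE]
      if (nrow(sub)) {
        sub <- sub[order(-as.numeric(sub$survey_wave), -sub$age_at_survey,
                         sub$survey_wave), , drop = FALSE]
        return(sub$weekly_met_hours[1])
      }
    }
  }
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    d <- data.frame(individual_id = "x",
                    survey_wave = as.character(sample(1990:2012, n)),
                    age_at_survey = sample(7:55, n, replace = TRUE),
                    injured_at_survey = sample(c(TRUE, FALSE), n, TRUE,
                                               prob = c(.2, .8)),
                    weekly_met_hours = round(runif(n, 0, 60), 1),
                    stringsAsFactors = FALSE)
    got <- merge_longitudinal(d)
    want <- oracle_merge_one(d)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$weekly_met_hours, want)
    }
  }
})

test_that("merge rejects duplicates and never demotes an adult record", {
  dup <- data.frame(individual_id = "a", survey_wave = c("2010", "2010"),
                    age_at_survey = 30, injured_at_survey = FALSE,
                    weekly_met_hours = 1, stringsAsFactors = FALSE)
  expect_error(merge_longitudinal(dup), "duplicate")
  recs <- data.frame(
    individual_id = rep(letters[1:6], each = 2),
    survey_wave = rep(c("2000", "2012"), 6),
    age_at_survey = c(20, 32, 8, 20, 30, 42, 10, 22, 15, 27, 16, 28),
    injured_at_survey = FALSE,
    weekly_met_hours = seq_len(12), stringsAsFactors = FALSE)
  out <- merge_longitudinal(recs)
  expect_lte(max(table(out$individual_id)), 1)
  expect_true(all(out$source_stratum == "adult"))
})

test_that("score_activities aggregates per individual and wave", {
  recs <- rbind(
    activity_row("p1", "2010", 30, "running", times_per_week = 3,
                 minutes_per_session = 60, met_value = NA),
    activity_row("p1", "2010", 30, "tennis", times_per_week = 1,
                 minutes_per_session = 90, met_value = NA),
    activity_row("p1", "2010", 30, "swimming", met_value = NA,
                 months_per_year = 1),   # irregular: filtered out
    activity_row("p2", "2010", 12, "soccer", times_per_week = 2,
                 minutes_per_session = 45, met_value = NA))
  recs$met_value <- NULL
  tab <- load_met_table()
  out <- score_activities(recs, tab)
  run_a <- tab$met_adult[tab$activity == "running"]
  ten_a <- tab$met_adult[tab$activity == "tennis"]
  soc_y <- tab$met_youth[tab$activity == "soccer"]
  expect_equal(out$weekly_met_hours[out$individual_id == "p1"],
               run_a * 3 + ten_a * 1.5)
  expect_equal(out$weekly_met_hours[out$individual_id == "p2"], soc_y * 1.5)
})
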