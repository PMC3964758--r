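#' Shipped MET lookup table
#'
#' Reads the packaged metabolic-equivalent (MET) lookup table: a curated
#' subset of roughly thirty common sports with separate youth and adult
#' values, following the convention of using a youth energy-expenditure
#' compendium for participants under 18 and an adult compendium from 18
#' onwards. The full compendia are out of scope; users can supply their own
#' CSV with the same columns (`activity`, `met_youth`, `met_adult`).
#'
#' @param path CSV path; defaults to the shipped table.
#' @return data frame with columns `activity`, `met_youth`, `met_adult`.
#' @export
load_met_table <- function(path = system.file("extdata", "met_values.csv",
                                              package = "twinmet")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("activity", "met_youth", "met_adult")
  if (!all(needed %in% names(tab)))
    stop("MET table needs columns: ", paste(needed, collapse = ", "))
  tab
}

#' Look up the MET value of an activity
#'
#' Returns the youth-table MET value for ages under 18 and the adult-table
#' value from 18 onwards. Unknown activities raise an error rather than
#' defaulting silently.
#'
#' @param activity_name character vector of activity names.
#' @param age numeric vector of ages at survey (recycled against
#'   `activity_name`).
#' @param met_table lookup table from [load_met_table()].
#' @return numeric MET values.
#' @export
met_lookup <- function(activity_name, age, met_table = load_met_table()) {
  idx <- match(activity_name, met_table$activity)
  if (anyNA(idx))
    stop("lookup error: unknown activity: ",
         paste(unique(activity_name[is.na(idx)]), collapse = ", "))
  n <- max(length(activity_name), length(age))
  idx <- rep_len(idx, n)
  age <- rep_len(age, n)
  ifelse(age < 18, met_table$met_youth[idx], met_table$met_adult[idx])
}

#' Filter to regular leisure-time exercise activities
#'
#' Keeps activity records that are leisure-time exercise (excluding
#' transportation, gardening, house cleaning and compulsory physical
#' education) and regular: practised at least 3 months a year and for at
#' least half a year. Irregular activities such as sailing camps or ski
#' holidays are thereby excluded. Order is preserved.
#'
#' @param records data frame of activity records with columns
#'   `leisure_flag`, `months_per_year`, `years_participated`.
#' @return the retained rows.
#' @export
filter_regular_leisure <- function(records) {
  needed <- c("leisure_flag", "months_per_year", "years_participated")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  keep <- records$leisure_flag &
    records$months_per_year >= 3 &
    records$years_participated >= 0.5
  records[which(keep), , drop = FALSE]
}

#' Weekly MET hours from filtered activity records
#'
#' The product of MET value, weekly frequency and session duration in
#' hours, summed over activities and truncated at `cap` MET hours
#' (default 120). Session duration is recorded in minutes and divided by
#' 60 so the score has units MET·hours/week.
#'
#' @param records filtered activity records with columns `met_value`,
#'   `times_per_week`, `minutes_per_session`.
#' @param cap truncation point in MET hours (default 120).
#' @return a single weekly MET-hours value in \eqn{[0, cap]}.
#' @export
met_hours <- function(records, cap = 120) {
  if (cap <= 0) stop("cap must be positive")
  if (nrow(records) == 0) return(0)
  needed <- c("met_value", "times_per_week", "minutes_per_session")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  v <- records[needed]
  if (any(unlist(v) < 0, na.rm = TRUE))
    stop("validation error: negative MET value, frequency or duration")
  raw <- sum(records$met_value * records$times_per_week *
               records$minutes_per_session / 60)
  min(cap, raw)
}

age_stratum <- function(age) {
  cut(age, breaks = c(-Inf, 13, 18, Inf), right = FALSE,
      labels = c("child", "adolescent", "adult"))
}

#' Score activities into per-wave weekly MET hours
#'
#' Applies [filter_regular_leisure()] and [met_hours()] per individual and
#' survey wave. When `met_value` is absent from the records it is looked
#' up from `met_table` by activity name and age. Individuals/waves whose
#' activities are all filtered out score 0 (they completed the survey and
#' reported no regular leisure exercise).
#'
#' @param records data frame of activity records (see [filter_regular_leisure()]
#'   and [met_hours()] for required columns, plus `individual_id`,
#'   `survey_wave`, `age_at_survey` and optionally `injured_at_survey`).
#' @param met_table lookup table used when `met_value` is absent.
#' @param cap truncation point in MET hours.
#' @return data frame with one row per individual and wave:
#'   `individual_id`, `survey_wave`, `age_at_survey`, `injured_at_survey`,
#'   `weekly_met_hours`.
#' @export
score_activities <- function(records, met_table = load_met_table(),
                             cap = 120) {
  if (!"met_value" %in% names(records))
    records$met_value <- met_lookup(records$activity_name,
                                    records$age_at_survey, met_table)
  if (!"injured_at_survey" %in% names(records))
    records$injured_at_survey <- FALSE
  kept <- filter_regular_leisure(records)
  key_all <- unique(records[c("individual_id", "survey_wave",
                              "age_at_survey", "injured_at_survey")])
  if (anyDuplicated(key_all[c("individual_id", "survey_wave")]))
    stop("validation error: inconsistent age/injury within (individual, wave)")
  groups <- split(kept, paste(kept$individual_id, kept$survey_wave, sep = "\r"))
  scored <- vapply(groups, met_hours, numeric(1), cap = cap)
  key <- paste(key_all$individual_id, key_all$survey_wave, sep = "\r")
  key_all$weekly_met_hours <- unname(ifelse(is.na(match(key, names(scored))),
                                            0, scored[match(key, names(scored))]))
  rownames(key_all) <- NULL
  key_all
}

#' Merge longitudinal phenotype records into one score per individual
#'
#' Combines repeated survey waves into a single weekly MET-hours score:
#' records taken above age 50 are set missing, records from waves at which
#' the participant was injured are dropped, and the remaining records are
#' chosen preferentially from the adult stratum (age 18+ at survey), then
#' adolescent (13-17), then child (<13), taking the most recent wave within
#' the chosen stratum. Recency is survey-wave order, ties broken by higher
#' age at survey, then lexical wave id. Individuals with no eligible record
#' are absent from the output.
#'
#' @param records data frame with columns `individual_id`, `survey_wave`,
#'   `age_at_survey`, `injured_at_survey`, `weekly_met_hours`.
#' @return data frame with one row per individual: `individual_id`,
#'   `weekly_met_hours`, `source_stratum`, `source_wave`.
#' @export
merge_longitudinal <- function(records) {
  needed <- c("individual_id", "survey_wave", "age_at_survey",
              "injured_at_survey", "weekly_met_hours")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(records[c("individual_id", "survey_wave")]))
    stop("validation error: duplicate (individual, wave) records")
  keep <- records$age_at_survey <= 50 & !records$injured_at_survey &
    !is.na(records$weekly_met_hours)
  records <- records[which(keep), , drop = FALSE]
  if (!nrow(records))
    return(data.frame(individual_id = character(0),
                      weekly_met_hours = numeric(0),
                      source_stratum = character(0),
                      source_wave = character(0), stringsAsFactors = FALSE))
  stratum <- age_stratum(records$age_at_survey)
  stratum_rank <- c(adult = 1L, adolescent = 2L, child = 3L)[as.character(stratum)]
  wave_num <- suppressWarnings(as.numeric(records$survey_wave))
  wave_key <- if (anyNA(wave_num)) xtfrm(as.character(records$survey_wave)) else wave_num
  ord <- order(records$individual_id, stratum_rank, -wave_key,
               -records$age_at_survey, as.character(records$survey_wave))
  first <- ord[!duplicated(records$individual_id[ord])]
  out <- data.frame(individual_id = records$individual_id[first],
                    weekly_met_hours = records$weekly_met_hours[first],
                    source_stratum = as.character(stratum)[first],
                    source_wave = as.character(records$survey_wave)[first],
                    stringsAsFactors = FALSE)
  out[order(out$individual_id), , drop = FALSE]
}
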