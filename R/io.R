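#' Read a FAM-like pedigree file
#'
#' Tab-separated with header columns `family_id`, `individual_id`,
#' `father_id`, `mother_id`, `sex`, `zygosity` and optionally `age` and
#' `sampled`; `"0"` (or empty) marks a missing parent, sex is 1 = male /
#' 2 = female. All malformed rows are reported together with their line
#' numbers.
#'
#' @param path file path.
#' @return a `twin_pedigree`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  required <- c("family_id", "individual_id", "father_id", "mother_id",
                "sex", "zygosity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("parse error: pedigree file missing columns: ",
         paste(missing_cols, collapse = ", "))
  line_no <- seq_len(nrow(df)) + 1L   # header is line 1
  problems <- character(0)
  df$sex <- suppressWarnings(as.integer(df$sex))
  bad_sex <- which(!(df$sex %in% c(1L, 2L)))
  if (length(bad_sex))
    problems <- c(problems, paste0("line ", line_no[bad_sex],
                                   ": sex must be 1 or 2"))
  bad_zyg <- which(!(df$zygosity %in% c("MZ", "DZ", "none")))
  if (length(bad_zyg))
    problems <- c(problems, paste0("line ", line_no[bad_zyg],
                                   ": zygosity must be MZ, DZ or none"))
  dup <- which(duplicated(df$individual_id))
  if (length(dup))
    problems <- c(problems, paste0("line ", line_no[dup],
                                   ": duplicate individual id ",
                                   df$individual_id[dup]))
  for (col in c("father_id", "mother_id")) {
    p <- df[[col]]
    bad <- which(!(p %in% c("0", "", NA)) & !(p %in% df$individual_id))
    if (length(bad))
      problems <- c(problems, paste0("line ", line_no[bad], ": unknown ",
                                     col, " \"", p[bad], "\""))
  }
  if (length(problems))
    stop("parse error in ", path, ":\n  ", paste(problems, collapse = "\n  "))
  if ("age" %in% names(df)) {
    df$age <- suppressWarnings(as.numeric(df$age))
  }
  if ("sampled" %in% names(df)) df$sampled <- df$sampled %in% c("TRUE", "1")
  new_pedigree(df)
}

#' Write a pedigree to a FAM-like TSV
#'
#' @param ped a `twin_pedigree`.
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, seed = NULL) {
  stopifnot(inherits(ped, "twin_pedigree"))
  out <- as.data.frame(ped)
  out$father_id[is.na(out$father_id)] <- "0"
  out$mother_id[is.na(out$mother_id)] <- "0"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("pedigree", seed), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype table
#'
#' Wide TSV: an `individual_id` column plus one column per variant holding
#' either 0/1/2 codes (or dosages) or allele pairs written `"A/G"`. `"NA"`
#' marks missing genotypes.
#'
#' @param path file path.
#' @param specs optional named list of [variant_spec()]s; columns with a
#'   spec and non-numeric entries are decoded from allele pairs via
#'   [code_snp()]/[code_vntr()].
#' @return data frame with `individual_id` and numeric code columns.
#' @export
read_genotypes <- function(path, specs = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = "NA", colClasses = "character")
  if (!"individual_id" %in% names(df))
    stop("parse error: genotype file needs an individual_id column")
  for (v in setdiff(names(df), "individual_id")) {
    col <- df[[v]]
    num <- suppressWarnings(as.numeric(col))
    if (!anyNA(num[!is.na(col)])) {
      if (any(num < 0 | num > 2, na.rm = TRUE))
        stop("parse error: codes outside [0, 2] in column ", v)
      df[[v]] <- num
    } else {
      if (is.null(specs) || is.null(specs[[v]]))
        stop("parse error: column ", v,
             " holds allele pairs but no variant spec was supplied")
      pairs <- do.call(rbind, strsplit(col, "/", fixed = TRUE))
      pairs[is.na(col), ] <- NA
      coder <- if (specs[[v]]$kind == "vntr") code_vntr else code_snp
      df[[v]] <- as.numeric(coder(pairs, specs[[v]]))
    }
  }
  df
}

#' Write a genotype table
#'
#' @param genotypes data frame with `individual_id` and code columns, or a
#'   named vector (written as one column `g`).
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, seed = NULL) {
  if (is.atomic(genotypes))
    genotypes <- data.frame(individual_id = names(genotypes),
                            g = as.vector(genotypes),
                            stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("genotypes", seed), con)
  utils::write.table(genotypes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an activity CSV
#'
#' One row per individual, activity and survey wave with the activity
#' record columns (`individual_id`, `survey_wave`, `age_at_survey`,
#' `activity_name`, `years_participated`, `months_per_year`,
#' `times_per_week`, `minutes_per_session`, `leisure_flag`, and optionally
#' `met_value` and `injured_at_survey`). Malformed rows are rejected with
#' line numbers.
#'
#' @param path file path.
#' @return data frame of activity records.
#' @export
read_activities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("individual_id", "survey_wave", "age_at_survey",
                "activity_name", "years_participated", "months_per_year",
                "times_per_week", "minutes_per_session", "leisure_flag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("parse error: activity file missing columns: ",
         paste(missing_cols, collapse = ", "))
  line_no <- seq_len(nrow(df)) + 1L
  problems <- character(0)
  for (col in c("years_participated", "months_per_year", "times_per_week",
                "minutes_per_session")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad))
      problems <- c(problems,
                    paste0("line ", line_no[bad], ": negative ", col))
  }
  bad_months <- which(!is.na(df$months_per_year) & df$months_per_year > 12)
  if (length(bad_months))
    problems <- c(problems, paste0("line ", line_no[bad_months],
                                   ": months_per_year above 12"))
  if ("met_value" %in% names(df)) {
    bad_met <- which(!is.na(df$met_value) & df$met_value < 1)
    if (length(bad_met))
      problems <- c(problems, paste0("line ", line_no[bad_met],
                                     ": met_value below 1"))
  }
  if (length(problems))
    stop("validation error in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  df$leisure_flag <- as.logical(df$leisure_flag)
  if ("injured_at_survey" %in% names(df))
    df$injured_at_survey <- as.logical(df$injured_at_survey)
  df
}

#' Write a tabular report with a self-describing header
#'
#' Writes a TSV preceded by comment lines recording the package version,
#' the seed and a hash of the configuration, so identical configurations
#' and seeds give byte-identical files.
#'
#' @param payload data frame.
#' @param path output path.
#' @param seed optional integer seed to record.
#' @param config optional configuration object; a stable hash of its
#'   deparsed form is recorded.
#' @return `path`, invisibly.
#' @export
write_report <- function(payload, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("report", seed, config), con)
  utils::write.table(payload, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

output_header <- function(kind, seed = NULL, config = NULL) {
  lines <- c(sprintf("# twinmet %s: %s",
                     as.character(utils::packageVersion("twinmet")), kind))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(config))
    lines <- c(lines, sprintf("# config_hash: %s", config_hash(config)))
  lines
}

# small stable polynomial hash of a deparsed object (no timestamps, so
# outputs are reproducible byte-for-byte)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ";"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
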