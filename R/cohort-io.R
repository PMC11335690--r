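## Cohort table: one row per subject per visit. This is the single data
## carrier for all statistics. Versioned header so files are self-describing.

COHORT_FORMAT_VERSION <- "glymkit-cohort-v1"

RPQ_N_ITEMS <- 22L
## Index of the "forgetfulness / poor memory" item within the 22 RPQ items.
RPQ_MEMORY_ITEM <- 9L
PSQI_N_COMPONENTS <- 7L

VALID_VISITS <- c("14Day", "6-12Mon", "control")

rpq_cols <- function() sprintf("rpq_%02d", seq_len(RPQ_N_ITEMS))

cohort_columns <- function() {
  c("subject_id", "group", "visit", "age", "sex", "education", "gcs",
    "ct_or_mri_positive", rpq_cols(), "rpq_total", "n_symptoms",
    "memory_problem", "psqi", "wm_epvs", "bg_epvs", "alps_index")
}

#' Validate a cohort table
#'
#' Checks the schema shared by [read_cohort_table()] and
#' [make_synthetic_cohort()]: required columns, unique (subject, visit) pairs,
#' known visit labels, numeric age, and RPQ item ratings on the 0-4 ordinal
#' scale.
#'
#' @param tab A data frame.
#' @return `tab`, with class `glym_cohort` prepended, invisibly valid.
#' @export
validate_cohort <- function(tab) {
  assert_that(is.data.frame(tab), "cohort must be a data frame")
  missing <- setdiff(cohort_columns(), names(tab))
  assert_that(length(missing) == 0, "cohort table missing columns: %s",
              paste(missing, collapse = ", "))
  key <- paste(tab$subject_id, tab$visit, sep = "\r")
  dup <- duplicated(key)
  assert_that(!any(dup), "duplicated (subject, visit) pair(s): %s",
              paste(unique(tab$subject_id[dup]), collapse = ", "))
  bad_visit <- setdiff(unique(tab$visit), VALID_VISITS)
  assert_that(length(bad_visit) == 0, "unknown visit label(s): %s",
              paste(bad_visit, collapse = ", "))
  assert_that(is.numeric(tab$age) && all(is.finite(tab$age)),
              "age must be numeric and non-missing")
  items <- as.matrix(tab[, rpq_cols()])
  ok <- is.na(items) | (items %in% 0:4)
  assert_that(all(ok), "RPQ item ratings must be integers in 0-4")
  if (!inherits(tab, "glym_cohort")) class(tab) <- c("glym_cohort", class(tab))
  tab
}

#' Read a cohort table from CSV
#'
#' The first line must carry the format version as a `# glymkit-cohort-v1`
#' comment; missing values are empty fields.
#'
#' @param path CSV path.
#' @return A validated cohort data frame (class `glym_cohort`).
#' @export
read_cohort_table <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  first <- readLines(path, n = 1L)
  assert_that(grepl(COHORT_FORMAT_VERSION, first, fixed = TRUE),
              "not a %s file: %s", COHORT_FORMAT_VERSION, path)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = "")
  tab$subject_id <- as.character(tab$subject_id)
  validate_cohort(tab)
}

#' Write a cohort table to CSV
#'
#' @param tab A cohort data frame (validated on the way out).
#' @param path Output CSV path.
#' @param overwrite Refuse to clobber unless `TRUE`.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(tab, path, overwrite = FALSE) {
  tab <- validate_cohort(tab)
  if (file.exists(path) && !overwrite) {
    stop_glym("file exists and overwrite = FALSE: %s", path)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", COHORT_FORMAT_VERSION), con)
  utils::write.csv(as.data.frame(tab)[, cohort_columns()], con,
                   row.names = FALSE, na = "")
  invisible(path)
}
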