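#' @keywords internal
"_PACKAGE"

# Column contract for a cohort data frame. Each entry: storage type used on
# read/write and whether missing values are permitted.
cohort_columns <- function() {
  list(
    patient_id                 = list(type = "character", na_ok = FALSE),
    diagnosis                  = list(type = "character", na_ok = FALSE),
    age                        = list(type = "numeric",   na_ok = FALSE),
    sex                        = list(type = "character", na_ok = FALSE),
    treatment                  = list(type = "character", na_ok = TRUE),
    csf_cxcl13                 = list(type = "numeric",   na_ok = FALSE),
    serum_cxcl13               = list(type = "numeric",   na_ok = TRUE),
    csf_albumin                = list(type = "numeric",   na_ok = TRUE),
    serum_albumin              = list(type = "numeric",   na_ok = TRUE),
    albumin_unit               = list(type = "character", na_ok = TRUE),
    tnc                        = list(type = "numeric",   na_ok = TRUE),
    converted_cdms             = list(type = "logical",   na_ok = FALSE),
    ocb_positive               = list(type = "logical",   na_ok = FALSE),
    n_attacks                  = list(type = "integer",   na_ok = FALSE),
    n_mris                     = list(type = "integer",   na_ok = FALSE),
    n_mris_with_new_lesions    = list(type = "integer",   na_ok = FALSE),
    n_new_or_enhancing_lesions = list(type = "integer",   na_ok = FALSE),
    followup_years             = list(type = "numeric",   na_ok = FALSE),
    study_eligible             = list(type = "logical",   na_ok = FALSE)
  )
}

#' Validate a patient cohort data frame
#'
#' Checks a cohort against the data contract used throughout the package:
#' one row per patient, the documented column set, and the record-level
#' invariants (positive concentrations, paired albumin measurements with a
#' single consistent unit, MRI count consistency, unique patient
#' identifiers, and at least five years of follow-up for study-eligible
#' records). Validation never coerces: a violating row raises an error
#' naming the row and column.
#'
#' @param cohort A data frame with one row per patient. See
#'   [read_cohort()] for the column dictionary.
#' @return The validated cohort, invisibly.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame")
  spec <- cohort_columns()
  missing_cols <- setdiff(names(spec), names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }

  fail <- function(rows, column, why) {
    stop(sprintf("invalid cohort: row %s, column '%s': %s",
                 paste(rows, collapse = ","), column, why), call. = FALSE)
  }
  bad <- function(x) which(x)[1]

  if (nrow(cohort) == 0L) return(invisible(cohort))

  for (col in names(spec)) {
    na_ok <- spec[[col]]$na_ok
    if (!na_ok && anyNA(cohort[[col]])) {
      fail(bad(is.na(cohort[[col]])), col, "missing value not permitted")
    }
  }

  if (anyDuplicated(cohort$patient_id)) {
    dup <- cohort$patient_id[duplicated(cohort$patient_id)][1]
    stop("invalid cohort: duplicate patient_id '", dup, "'", call. = FALSE)
  }
  if (!all(cohort$diagnosis %in% c("CIS", "RIS"))) {
    fail(bad(!cohort$diagnosis %in% c("CIS", "RIS")), "diagnosis",
         "must be 'CIS' or 'RIS'")
  }
  if (!all(cohort$sex %in% c("male", "female", "other"))) {
    fail(bad(!cohort$sex %in% c("male", "female", "other")), "sex",
         "must be 'male', 'female' or 'other'")
  }

  # concentrations: strictly positive where present
  for (col in c("csf_cxcl13", "serum_cxcl13", "csf_albumin",
                "serum_albumin")) {
    x <- cohort[[col]]
    if (any(!is.na(x) & x <= 0)) {
      fail(bad(!is.na(x) & x <= 0), col, "concentration must be > 0")
    }
  }
  if (any(!is.na(cohort$tnc) & cohort$tnc < 0)) {
    fail(bad(!is.na(cohort$tnc) & cohort$tnc < 0), "tnc", "must be >= 0")
  }

  # albumin pair: both present or both absent, with a unit tag when present
  csf_alb <- is.na(cohort$csf_albumin)
  ser_alb <- is.na(cohort$serum_albumin)
  if (any(csf_alb != ser_alb)) {
    fail(bad(csf_alb != ser_alb), "csf_albumin",
         "csf_albumin and serum_albumin must both be present or both absent")
  }
  has_alb <- !csf_alb
  if (any(has_alb & is.na(cohort$albumin_unit))) {
    fail(bad(has_alb & is.na(cohort$albumin_unit)), "albumin_unit",
         "unit declaration required when albumin is present")
  }
  units <- unique(cohort$albumin_unit[has_alb])
  if (length(units) > 1L) {
    stop("invalid cohort: albumin unit mismatch across records: ",
         paste(units, collapse = " vs "), call. = FALSE)
  }

  counts <- c("n_attacks", "n_mris", "n_mris_with_new_lesions",
              "n_new_or_enhancing_lesions")
  for (col in counts) {
    x <- cohort[[col]]
    if (any(x < 0 | x != round(x))) {
      fail(bad(x < 0 | x != round(x)), col, "must be a non-negative integer")
    }
  }
  over <- cohort$n_mris_with_new_lesions > cohort$n_mris
  if (any(over)) {
    fail(bad(over), "n_mris_with_new_lesions", "exceeds n_mris")
  }
  if (any(cohort$followup_years <= 0)) {
    fail(bad(cohort$followup_years <= 0), "followup_years", "must be > 0")
  }
  short <- cohort$study_eligible & cohort$followup_years < 5
  if (any(short)) {
    fail(bad(short), "followup_years",
         "study-eligible records require >= 5 years of follow-up")
  }
  invisible(cohort)
}

#' Read a patient cohort from CSV
#'
#' Reads the package's cohort dialect: comma-separated, UTF-8, dot decimal
#' separator, header row required, empty cell = missing. Columns:
#' `patient_id`, `diagnosis` (CIS/RIS), `age`, `sex` (male/female/other),
#' `treatment`, `csf_cxcl13` and `serum_cxcl13` (pg/mL; serum may be
#' missing), `csf_albumin`/`serum_albumin` (any consistent unit pair,
#' declared in `albumin_unit`), `tnc` (cells/uL), `converted_cdms`,
#' `ocb_positive`, `n_attacks`, `n_mris`, `n_mris_with_new_lesions`,
#' `n_new_or_enhancing_lesions`, `followup_years`, `study_eligible`.
#'
#' @param path Path to a cohort CSV file.
#' @return A validated cohort data frame.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  spec <- cohort_columns()
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "",
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(spec), names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- raw[names(spec)]
  for (col in names(spec)) {
    type <- spec[[col]]$type
    x <- out[[col]]
    out[[col]] <- switch(type,
      character = x,
      numeric = {
        v <- suppressWarnings(as.numeric(x))
        chk <- !is.na(x) & is.na(v)
        if (any(chk)) {
          stop(sprintf("malformed value in row %d, column '%s': '%s'",
                       which(chk)[1], col, x[which(chk)[1]]), call. = FALSE)
        }
        v
      },
      integer = {
        v <- suppressWarnings(as.integer(x))
        chk <- !is.na(x) & (is.na(v) | as.numeric(x) != v)
        if (any(chk)) {
          stop(sprintf("malformed value in row %d, column '%s': '%s'",
                       which(chk)[1], col, x[which(chk)[1]]), call. = FALSE)
        }
        v
      },
      logical = {
        v <- rep(NA, length(x))
        v[x %in% c("TRUE", "true", "1")] <- TRUE
        v[x %in% c("FALSE", "false", "0")] <- FALSE
        chk <- !is.na(x) & is.na(v)
        if (any(chk)) {
          stop(sprintf("malformed value in row %d, column '%s': '%s'",
                       which(chk)[1], col, x[which(chk)[1]]), call. = FALSE)
        }
        v
      })
  }
  validate_cohort(out)
  out
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: writes the documented dialect with missing
#' values as empty cells (never "0") and full-precision numerics, so that
#' `read_cohort(write_cohort(x))` reproduces `x` field for field.
#'
#' @param cohort A validated cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  spec <- cohort_columns()
  out <- cohort[names(spec)]
  for (col in names(spec)) {
    x <- out[[col]]
    out[[col]] <- switch(spec[[col]]$type,
      numeric = ifelse(is.na(x), NA_character_, sprintf("%.17g", x)),
      integer = ifelse(is.na(x), NA_character_, as.character(x)),
      logical = ifelse(is.na(x), NA_character_,
                       ifelse(x, "TRUE", "FALSE")),
      as.character(x))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}
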