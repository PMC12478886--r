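#' Canonical microdata column names
#'
#' One row per diary day. `cohort_year` is optional on input and derived as
#' `year - age` when absent; when present it is cross-checked against that
#' identity.
#' @keywords internal
MICRODATA_COLUMNS <- c("age", "year", "cohort_year", "gender", "minutes_alone",
                       "weight", "day_of_week", "holiday")

DAY_LEVELS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
GENDER_LEVELS <- c("female", "male")

#' Read and validate person-day microdata
#'
#' Reads delimited text with a header into a validated microdata table.
#' Rows violating the record invariants (cohort identity `cohort_year ==
#' year - age`, outcome in \[0, 1440\] minutes, positive survey weight,
#' recognizable gender/day/holiday codes, or any missing required field) are
#' dropped and itemized in the attached validation report; valid rows are
#' returned in their original order with values untouched.
#'
#' @param path Path to a delimited text file with a header row. Column names
#'   are matched case-insensitively against `age`, `year`, `cohort_year`
#'   (optional), `gender`, `minutes_alone`, `weight`, `day_of_week`,
#'   `holiday`.
#' @param dialect Field delimiter: `"comma"` (default) or `"tab"`.
#' @return A `data.frame` of class `apc_microdata` with the canonical
#'   columns, plus a `validation` attribute: a list with `n_read`, `n_valid`,
#'   `n_rejected`, and a `rejections` data.frame (row index + reason).
#' @seealso [filter_records()], [write_microdata()], [validate_microdata()]
#' @export
read_microdata <- function(path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("microdata file not found: ", path)
  }
  sep <- if (dialect == "comma") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  names(raw) <- tolower(trimws(names(raw)))
  required <- setdiff(MICRODATA_COLUMNS, "cohort_year")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("microdata schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_microdata(raw)
}

#' Validate a raw microdata data.frame
#'
#' Applies the record invariants to an already-parsed data.frame and returns
#' the surviving rows as an `apc_microdata` table with a validation report.
#' Used by [read_microdata()] and usable directly on in-memory data.
#'
#' @param raw A data.frame with the canonical columns (`cohort_year`
#'   optional).
#' @return An `apc_microdata` data.frame; see [read_microdata()].
#' @export
validate_microdata <- function(raw) {
  n <- nrow(raw)
  reasons <- character(0)
  rows <- integer(0)
  flag <- function(idx, why) {
    rows <<- c(rows, idx)
    reasons <<- c(reasons, why)
  }

  age <- suppressWarnings(as.numeric(raw$age))
  year <- suppressWarnings(as.numeric(raw$year))
  minutes <- suppressWarnings(as.numeric(raw$minutes_alone))
  weight <- suppressWarnings(as.numeric(raw$weight))
  gender <- tolower(trimws(as.character(raw$gender)))
  dow <- normalize_day(raw$day_of_week)
  holiday <- normalize_logical(raw$holiday)

  bad_age <- is.na(age) | age != round(age)
  bad_year <- is.na(year) | year != round(year)
  bad_minutes <- is.na(minutes) | minutes < 0 | minutes > 1440
  bad_weight <- is.na(weight) | weight <= 0
  bad_gender <- !(gender %in% GENDER_LEVELS)
  bad_dow <- is.na(dow)
  bad_holiday <- is.na(holiday)

  if ("cohort_year" %in% names(raw) && !all(is.na(raw$cohort_year))) {
    cohort <- suppressWarnings(as.numeric(raw$cohort_year))
    bad_cohort <- is.na(cohort) | (!bad_age & !bad_year & cohort != year - age)
  } else {
    cohort <- ifelse(bad_age | bad_year, NA_real_, year - age)
    bad_cohort <- rep(FALSE, n)
  }

  for (i in seq_len(n)) {
    if (bad_age[i]) flag(i, "age missing or non-integer")
    else if (bad_year[i]) flag(i, "year missing or non-integer")
    else if (bad_cohort[i]) {
      flag(i, sprintf("cohort identity violated: %s - %s = %s != %s",
                      year[i], age[i], year[i] - age[i], raw$cohort_year[i]))
    }
    else if (bad_minutes[i]) flag(i, "minutes_alone missing or outside [0, 1440]")
    else if (bad_weight[i]) flag(i, "weight missing or non-positive")
    else if (bad_gender[i]) flag(i, "gender not one of {female, male}")
    else if (bad_dow[i]) flag(i, "day_of_week unrecognized")
    else if (bad_holiday[i]) flag(i, "holiday not interpretable as logical")
  }

  keep <- setdiff(seq_len(n), rows)
  tab <- data.frame(
    age = as.integer(age[keep]),
    year = as.integer(year[keep]),
    cohort_year = as.integer(cohort[keep]),
    gender = gender[keep],
    minutes_alone = minutes[keep],
    weight = weight[keep],
    day_of_week = dow[keep],
    holiday = holiday[keep],
    stringsAsFactors = FALSE
  )
  report <- list(
    n_read = n,
    n_valid = length(keep),
    n_rejected = length(rows),
    rejections = data.frame(row = rows, reason = reasons,
                            stringsAsFactors = FALSE)
  )
  as_apc_microdata(tab, validation = report)
}

as_apc_microdata <- function(df, validation = NULL) {
  rownames(df) <- NULL
  class(df) <- c("apc_microdata", "data.frame")
  if (!is.null(validation)) attr(df, "validation") <- validation
  df
}

normalize_day <- function(x) {
  x <- trimws(as.character(x))
  full <- c(monday = "Mon", tuesday = "Tue", wednesday = "Wed",
            thursday = "Thu", friday = "Fri", saturday = "Sat",
            sunday = "Sun")
  out <- ifelse(x %in% DAY_LEVELS, x, unname(full[tolower(x)]))
  abbr3 <- substr(tolower(x), 1, 3)
  idx <- is.na(out) & abbr3 %in% tolower(DAY_LEVELS)
  out[idx] <- DAY_LEVELS[match(abbr3[idx], tolower(DAY_LEVELS))]
  out
}

normalize_logical <- function(x) {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[s %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Filter specification for microdata
#'
#' Closed-interval and categorical filters applied before analysis. Defaults
#' reproduce the primary analytic sample definition: ages 15-79 and diary
#' years 2003-2022, all days, both genders. Weekday/weekend and pre-pandemic
#' sensitivity analyses are expressed through `day_subset` and `year_range`.
#'
#' @param age_range Integer vector of length 2, closed interval.
#' @param year_range Integer vector of length 2, closed interval.
#' @param day_subset Optional character vector of day abbreviations
#'   (`"Mon"`..`"Sun"`) to retain; `NULL` keeps all days.
#' @param gender Optional single gender (`"female"` or `"male"`) to retain.
#' @return An object of class `apc_filter`.
#' @export
filter_spec <- function(age_range = c(15L, 79L), year_range = c(2003L, 2022L),
                        day_subset = NULL, gender = NULL) {
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2],
            length(year_range) == 2, year_range[1] <= year_range[2])
  if (!is.null(day_subset)) {
    day_subset <- unique(as.character(day_subset))
    if (length(day_subset) == 0 || !all(day_subset %in% DAY_LEVELS)) {
      stop("day_subset must be a non-empty subset of ",
           paste(DAY_LEVELS, collapse = ", "))
    }
  }
  if (!is.null(gender)) {
    gender <- match.arg(gender, GENDER_LEVELS)
  }
  structure(list(age_range = as.integer(age_range),
                 year_range = as.integer(year_range),
                 day_subset = day_subset, gender = gender),
            class = "apc_filter")
}

#' Filter microdata records
#'
#' Retains records satisfying every clause of a [filter_spec()] (all
#' intervals closed). Idempotent; an empty result is a warning, not an
#' error, so callers can report the retention count before downstream
#' stages refuse to fit.
#'
#' @param table An `apc_microdata` table.
#' @param spec An `apc_filter`, default [filter_spec()].
#' @return The filtered `apc_microdata` table, with a `retention` attribute
#'   recording counts before and after.
#' @export
filter_records <- function(table, spec = filter_spec()) {
  stopifnot(inherits(spec, "apc_filter"))
  keep <- table$age >= spec$age_range[1] & table$age <= spec$age_range[2] &
    table$year >= spec$year_range[1] & table$year <= spec$year_range[2]
  if (!is.null(spec$day_subset)) {
    keep <- keep & table$day_of_week %in% spec$day_subset
  }
  if (!is.null(spec$gender)) {
    keep <- keep & table$gender == spec$gender
  }
  out <- as_apc_microdata(table[keep, , drop = FALSE])
  attr(out, "retention") <- list(n_before = nrow(table), n_after = sum(keep))
  if (sum(keep) == 0) warning("filter_records: no records retained")
  out
}

#' Write microdata to delimited text
#'
#' Inverse of [read_microdata()]: writing then reading yields a
#' value-identical table.
#'
#' @param table An `apc_microdata` table.
#' @param path Output file path.
#' @param dialect `"comma"` (default) or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(table, path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "comma") "," else "\t"
  df <- as.data.frame(table)[, MICRODATA_COLUMNS]
  df$holiday <- ifelse(df$holiday, "true", "false")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.apc_microdata <- function(x, ...) {
  v <- attr(x, "validation")
  cat(sprintf("<apc_microdata> %d records, years %s-%s, ages %s-%s\n",
              nrow(x), min(x$year), max(x$year), min(x$age), max(x$age)))
  if (!is.null(v)) {
    cat(sprintf("  validation: %d read, %d valid, %d rejected\n",
                v$n_read, v$n_valid, v$n_rejected))
  }
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}
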