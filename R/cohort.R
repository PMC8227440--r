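#' @importFrom rlang abort warn inform .data :=
#' @importFrom dplyr %>%
NULL

# Valid EDSS values: 0 and the 0.5-grid from 1.0 to 10.0.  The scale has no
# 0.5 step; a permissive flag admits it for registries that record one.
edss_is_valid <- function(edss, allow_half_point = FALSE) {
  twice <- edss * 2
  on_grid <- is.finite(edss) & abs(twice - round(twice)) < 1e-8 &
    edss >= 0 & edss <= 10
  if (!allow_half_point) {
    on_grid & abs(edss - 0.5) > 1e-8
  } else {
    on_grid
  }
}

#' Validate EDSS scores
#'
#' Checks that scores lie on the EDSS 0.5-point grid in \[0, 10\].  The value
#' 0.5 does not exist on the scale and is rejected unless
#' `allow_half_point = TRUE`.
#'
#' @param edss Numeric vector of EDSS scores.
#' @param allow_half_point Accept the (non-standard) value 0.5.
#' @return Invisibly, `edss`; errors on the first invalid value.
#' @export
validate_edss <- function(edss, allow_half_point = FALSE) {
  bad <- which(!edss_is_valid(edss, allow_half_point))
  if (length(bad)) {
    abort(
      sprintf(
        "Invalid EDSS value(s) %s at position(s) %s: EDSS must be 0 or a multiple of 0.5 in [1, 10]%s.",
        paste(utils::head(edss[bad], 5), collapse = ", "),
        paste(utils::head(bad, 5), collapse = ", "),
        if (allow_half_point) "" else " (0.5 is not a step on the scale)"
      ),
      class = "msclassify_edss_error"
    )
  }
  invisible(edss)
}

check_columns <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(
      sprintf(
        "Table '%s' is missing required column(s): %s.",
        table, paste(missing, collapse = ", ")
      ),
      class = "msclassify_schema_error"
    )
  }
  invisible(df)
}

parse_date_column <- function(x, column, table) {
  if (inherits(x, "Date")) return(x)
  out <- structure(rep(NA_real_, length(x)), class = "Date")
  chr <- as.character(x)
  parsed <- as.Date(chr, format = "%Y-%m-%d")
  bad <- which(!is.na(chr) & chr != "" & is.na(parsed))
  if (length(bad)) {
    abort(
      sprintf(
        "Table '%s', column '%s': unparseable date '%s' at row %d (expected ISO-8601).",
        table, column, chr[bad[1]], bad[1]
      ),
      class = "msclassify_parse_error"
    )
  }
  out[!is.na(chr) & chr != ""] <- parsed[!is.na(chr) & chr != ""]
  out
}

# Some registries record only the *year* of SP transition; a bare year is
# canonicalised to July 1 of that year (mid-year convention) and counted
# as imputed.
parse_sp_date <- function(x) {
  if (inherits(x, "Date")) return(list(date = x, n_imputed = 0L))
  chr <- trimws(as.character(x))
  chr[is.na(chr) | chr == ""] <- NA_character_
  is_year <- !is.na(chr) & grepl("^\\d{4}$", chr)
  out <- structure(rep(NA_real_, length(chr)), class = "Date")
  if (any(is_year)) {
    out[is_year] <- as.Date(paste0(chr[is_year], "-07-01"))
  }
  rest <- !is.na(chr) & !is_year
  if (any(rest)) {
    parsed <- as.Date(chr[rest], format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      abort(
        sprintf(
          "Column 'sp_date': unparseable value '%s' (expected ISO-8601 date or bare year).",
          chr[rest][which(is.na(parsed))[1]]
        ),
        class = "msclassify_parse_error"
      )
    }
    out[rest] <- parsed
  }
  list(date = out, n_imputed = sum(is_year))
}

#' Assemble and validate a clinical cohort
#'
#' Bundles the three long-format tables of an MS registry extract — patients,
#' EDSS visits and relapses — into a validated `ms_cohort` object.  Validation
#' enforces the domain invariants: dates in order (onset after birth, SP
#' transition after onset, visits after birth, relapses after onset), EDSS
#' scores on the 0.5-grid, an SP date present exactly for SP-labelled
#' patients, and referential integrity of every visit and relapse.  Visits
#' are sorted by patient and date; same-day duplicates are collapsed to a
#' single visit (by default keeping the maximum EDSS of the day, conservative
#' toward progression).
#'
#' @param patients Data frame with columns `patient_id`, `sex`
#'   (`"female"`/`"male"`), `birth_date`, `onset_date`, `assigned_phenotype`
#'   (`"RR"`/`"SP"`), `sp_date` (date, bare year, or `NA`).
#' @param visits Data frame with columns `patient_id`, `visit_date`, `edss`
#'   and optionally `pyramidal_fs`.
#' @param relapses Optional data frame with columns `patient_id`,
#'   `relapse_date`.
#' @param allow_half_point Accept EDSS 0.5 (off by default).
#' @param duplicate_policy How to collapse same-day duplicate visits:
#'   `"max"` (default), `"min"`, or `"error"`.
#' @return An `ms_cohort`: a list of tibbles `patients`, `visits`, `relapses`.
#' @examples
#' pts <- tibble::tibble(
#'   patient_id = "P1", sex = "female",
#'   birth_date = as.Date("1970-01-01"), onset_date = as.Date("2000-06-15"),
#'   assigned_phenotype = "RR", sp_date = as.Date(NA)
#' )
#' vis <- tibble::tibble(
#'   patient_id = "P1",
#'   visit_date = as.Date(c("2005-01-01", "2010-01-01")),
#'   edss = c(1.0, 2.0)
#' )
#' cohort(pts, vis)
#' @export
cohort <- function(patients, visits, relapses = NULL,
                   allow_half_point = FALSE,
                   duplicate_policy = c("max", "min", "error")) {
  duplicate_policy <- match.arg(duplicate_policy)

  check_columns(patients, c("patient_id", "sex", "birth_date", "onset_date",
                            "assigned_phenotype"), "patients")
  check_columns(visits, c("patient_id", "visit_date", "edss"), "visits")

  patients <- tibble::as_tibble(patients)
  patients$patient_id <- as.character(patients$patient_id)
  patients$birth_date <- parse_date_column(patients$birth_date, "birth_date", "patients")
  patients$onset_date <- parse_date_column(patients$onset_date, "onset_date", "patients")
  if (!"sp_date" %in% names(patients)) patients$sp_date <- as.Date(NA)
  sp <- parse_sp_date(patients$sp_date)
  patients$sp_date <- sp$date
  if (sp$n_imputed > 0) {
    inform(sprintf(
      "%d SP transition date(s) given as a bare year; imputed to July 1 (mid-year convention).",
      sp$n_imputed
    ))
  }

  if (anyDuplicated(patients$patient_id)) {
    abort("Duplicate patient_id in patients table.",
          class = "msclassify_schema_error")
  }
  bad_sex <- which(!patients$sex %in% c("female", "male"))
  if (length(bad_sex)) {
    abort(sprintf("patients row %d: sex must be 'female' or 'male' (got '%s').",
                  bad_sex[1], patients$sex[bad_sex[1]]),
          class = "msclassify_schema_error")
  }
  bad_ph <- which(!patients$assigned_phenotype %in% c("RR", "SP"))
  if (length(bad_ph)) {
    abort(sprintf("patients row %d: assigned_phenotype must be 'RR' or 'SP' (got '%s').",
                  bad_ph[1], patients$assigned_phenotype[bad_ph[1]]),
          class = "msclassify_schema_error")
  }
  bad <- which(patients$onset_date < patients$birth_date)
  if (length(bad)) {
    abort(sprintf("patients row %d: onset_date precedes birth_date.", bad[1]),
          class = "msclassify_invariant_error")
  }
  sp_mismatch <- which(xor(patients$assigned_phenotype == "SP",
                           !is.na(patients$sp_date)))
  if (length(sp_mismatch)) {
    abort(sprintf(
      "patients row %d: sp_date must be present if and only if assigned_phenotype is 'SP'.",
      sp_mismatch[1]
    ), class = "msclassify_invariant_error")
  }
  bad <- which(!is.na(patients$sp_date) & patients$sp_date < patients$onset_date)
  if (length(bad)) {
    abort(sprintf("patients row %d: sp_date precedes onset_date.", bad[1]),
          class = "msclassify_invariant_error")
  }

  visits <- tibble::as_tibble(visits)
  visits$patient_id <- as.character(visits$patient_id)
  visits$visit_date <- parse_date_column(visits$visit_date, "visit_date", "visits")
  visits$edss <- as.numeric(visits$edss)
  bad_edss <- which(is.na(visits$edss) | !edss_is_valid(visits$edss, allow_half_point))
  if (length(bad_edss)) {
    abort(sprintf(
      "visits row %d: invalid EDSS value '%s' (must be 0 or a 0.5-multiple in [1, 10]%s).",
      bad_edss[1], visits$edss[bad_edss[1]],
      if (allow_half_point) "" else "; 0.5 is not a step on the scale"
    ), class = "msclassify_edss_error")
  }
  orphan <- which(!visits$patient_id %in% patients$patient_id)
  if (length(orphan)) {
    abort(sprintf("visits row %d: patient_id '%s' not found in patients table.",
                  orphan[1], visits$patient_id[orphan[1]]),
          class = "msclassify_referential_error")
  }
  birth_lookup <- stats::setNames(patients$birth_date, patients$patient_id)
  bad <- which(visits$visit_date < birth_lookup[visits$patient_id])
  if (length(bad)) {
    abort(sprintf("visits row %d: visit_date precedes the patient's birth_date.", bad[1]),
          class = "msclassify_invariant_error")
  }

  # Same-day duplicates: collapse to one visit per (patient, date).
  dup_key <- paste(visits$patient_id, visits$visit_date)
  if (anyDuplicated(dup_key)) {
    if (duplicate_policy == "error") {
      abort(sprintf("Duplicate same-day visit for patient '%s' on %s.",
                    visits$patient_id[duplicated(dup_key)][1],
                    visits$visit_date[duplicated(dup_key)][1]),
            class = "msclassify_invariant_error")
    }
    agg <- if (duplicate_policy == "max") max else min
    visits <- visits %>%
      dplyr::group_by(.data$patient_id, .data$visit_date) %>%
      dplyr::summarise(
        dplyr::across(dplyr::any_of("pyramidal_fs"), ~ agg(.x)),
        edss = agg(.data$edss),
        .groups = "drop"
      )
  }
  visits <- dplyr::arrange(visits, .data$patient_id, .data$visit_date)
  visits <- visits[, c("patient_id", "visit_date", "edss",
                       intersect("pyramidal_fs", names(visits)))]

  if (is.null(relapses)) {
    relapses <- tibble::tibble(patient_id = character(),
                               relapse_date = as.Date(character()))
  } else {
    check_columns(relapses, c("patient_id", "relapse_date"), "relapses")
    relapses <- tibble::as_tibble(relapses)
    relapses$patient_id <- as.character(relapses$patient_id)
    relapses$relapse_date <- parse_date_column(relapses$relapse_date,
                                               "relapse_date", "relapses")
    orphan <- which(!relapses$patient_id %in% patients$patient_id)
    if (length(orphan)) {
      abort(sprintf("relapses row %d: patient_id '%s' not found in patients table.",
                    orphan[1], relapses$patient_id[orphan[1]]),
            class = "msclassify_referential_error")
    }
    onset_lookup <- stats::setNames(patients$onset_date, patients$patient_id)
    bad <- which(relapses$relapse_date < onset_lookup[relapses$patient_id])
    if (length(bad)) {
      abort(sprintf("relapses row %d: relapse_date precedes the patient's onset_date.",
                    bad[1]),
            class = "msclassify_invariant_error")
    }
    relapses <- dplyr::arrange(relapses, .data$patient_id, .data$relapse_date)
  }

  structure(
    list(patients = patients, visits = visits, relapses = relapses),
    class = "ms_cohort"
  )
}

#' @export
print.ms_cohort <- function(x, ...) {
  n_sp <- sum(x$patients$assigned_phenotype == "SP")
  cat(sprintf(
    "<ms_cohort> %d patients (%d RR, %d SP), %d visits, %d relapses\n",
    nrow(x$patients), nrow(x$patients) - n_sp, n_sp,
    nrow(x$visits), nrow(x$relapses)
  ))
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' Reads the three standard tables (`patients.csv`, `visits.csv`,
#' `relapses.csv`) and validates them with [cohort()].  Dates must be
#' ISO-8601; `sp_date` may also be a bare year, which is imputed to July 1.
#'
#' @param patients_path,visits_path Paths to the patient and visit CSVs.
#' @param relapses_path Optional path to the relapse CSV.
#' @inheritParams cohort
#' @return An `ms_cohort`.
#' @export
read_cohort <- function(patients_path, visits_path, relapses_path = NULL,
                        allow_half_point = FALSE,
                        duplicate_policy = "max") {
  for (p in c(patients_path, visits_path, relapses_path)) {
    if (!file.exists(p)) {
      abort(sprintf("Input file not found: %s", p),
            class = "msclassify_io_error")
    }
  }
  patients <- readr::read_csv(patients_path, col_types = readr::cols(
    patient_id = readr::col_character(),
    sex = readr::col_character(),
    birth_date = readr::col_character(),
    onset_date = readr::col_character(),
    assigned_phenotype = readr::col_character(),
    .default = readr::col_character()
  ))
  visits <- readr::read_csv(visits_path, col_types = readr::cols(
    patient_id = readr::col_character(),
    visit_date = readr::col_character(),
    edss = readr::col_double(),
    .default = readr::col_double()
  ))
  relapses <- if (!is.null(relapses_path)) {
    readr::read_csv(relapses_path, col_types = readr::cols(
      patient_id = readr::col_character(),
      relapse_date = readr::col_character()
    ))
  }
  cohort(patients, visits, relapses,
         allow_half_point = allow_half_point,
         duplicate_policy = duplicate_policy)
}

#' Write a cohort to CSV files
#'
#' Writes `patients.csv`, `visits.csv` and `relapses.csv` into `dir` in the
#' canonical (validated, sorted) form, so that
#' `read_cohort()` then `write_cohort()` is a fixed point.
#'
#' @param x An `ms_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "ms_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "visits.csv", "relapses.csv"))
  readr::write_csv(x$patients, paths[1], na = "")
  readr::write_csv(x$visits, paths[2], na = "")
  readr::write_csv(x$relapses, paths[3], na = "")
  invisible(paths)
}

#' Age in years between two dates
#'
#' Ages are computed with the 365.25-day year.
#'
#' @param birth_date,date Date vectors (recycled).
#' @return Numeric vector of ages in years.
#' @examples
#' age_at(as.Date("1960-01-01"), as.Date("2020-01-01"))
#' @export
age_at <- function(birth_date, date) {
  birth_date <- as.Date(birth_date)
  date <- as.Date(date)
  if (any(date < birth_date, na.rm = TRUE)) {
    abort("age_at(): date precedes birth_date.",
          class = "msclassify_domain_error")
  }
  as.numeric(date - birth_date) / 365.25
}

#' Latest EDSS assessment per patient
#'
#' Returns each patient's most recent visit together with the age at that
#' visit — the two inputs of the cross-sectional classifier.  Patients
#' without any visit are dropped (use the returned `patient_id`s to detect
#' them).
#'
#' @param x An `ms_cohort`.
#' @return A tibble with columns `patient_id`, `visit_date`, `edss`, `age`,
#'   `assigned_phenotype`.
#' @export
latest_assessments <- function(x) {
  stopifnot(inherits(x, "ms_cohort"))
  if (nrow(x$visits) == 0) {
    return(tibble::tibble(
      patient_id = character(), visit_date = as.Date(character()),
      edss = numeric(), age = numeric(), assigned_phenotype = character()
    ))
  }
  last <- x$visits %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::slice_max(.data$visit_date, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  last %>%
    dplyr::inner_join(
      dplyr::select(x$patients, "patient_id", "birth_date", "assigned_phenotype"),
      by = "patient_id"
    ) %>%
    dplyr::mutate(age = age_at(.data$birth_date, .data$visit_date)) %>%
    dplyr::select("patient_id", "visit_date", "edss", "age", "assigned_phenotype")
}
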