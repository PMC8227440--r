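#' Configuration for the adapted MSBase SP-conversion algorithm
#'
#' The detector flags conversion to secondary progressive MS from
#' longitudinal EDSS records: a relapse-free EDSS increase of at least one
#' point from baseline (half a point when the baseline EDSS is 6 or more),
#' reaching an EDSS of at least 4, confirmed at a later relapse-free visit at
#' least three months on.  The pyramidal functional-system criterion of the
#' original algorithm is ignored by default (treated as satisfied), because
#' most registries do not record FS sub-scores; enable
#' `require_pyramidal_fs` only when a `pyramidal_fs` column is present.
#'
#' @param min_increase_below6 Required EDSS increase when the baseline EDSS
#'   is below 6 (points; default 1.0).
#' @param min_increase_at6plus Required increase when the baseline EDSS is 6
#'   or more (default 0.5).
#' @param edss_floor Minimum EDSS the event visit must reach (default 4.0).
#' @param confirmation_days Minimum days between the event visit and the
#'   confirming visit (default 91, i.e. three months).
#' @param relapse_window_days A visit is "relapse-free" when no relapse falls
#'   within this many days before or after it (default 30).
#' @param baseline How the reference EDSS is tracked: `"roving"` (default) —
#'   the lowest EDSS at any relapse-free visit so far — or `"fixed"` — the
#'   first relapse-free visit.
#' @param require_pyramidal_fs Enforce a pyramidal FS score of at least
#'   `fs_threshold` at the event and confirming visits (default `FALSE`).
#' @param fs_threshold Pyramidal FS cut-off (default 2).
#' @return A list of class `msbase_config`.
#' @export
msbase_config <- function(min_increase_below6 = 1.0,
                          min_increase_at6plus = 0.5,
                          edss_floor = 4.0,
                          confirmation_days = 91L,
                          relapse_window_days = 30L,
                          baseline = c("roving", "fixed"),
                          require_pyramidal_fs = FALSE,
                          fs_threshold = 2L) {
  baseline <- match.arg(baseline)
  if (min_increase_below6 <= 0 || min_increase_at6plus <= 0 ||
      edss_floor <= 0 || confirmation_days < 1) {
    abort("msbase_config(): thresholds must be positive and confirmation_days >= 1.",
          class = "msclassify_domain_error")
  }
  structure(
    list(
      min_increase_below6 = min_increase_below6,
      min_increase_at6plus = min_increase_at6plus,
      edss_floor = edss_floor,
      confirmation_days = as.integer(confirmation_days),
      relapse_window_days = as.integer(relapse_window_days),
      baseline = baseline,
      require_pyramidal_fs = require_pyramidal_fs,
      fs_threshold = fs_threshold
    ),
    class = "msbase_config"
  )
}

#' Detect conversion to SP from one patient's visit history
#'
#' Scans the visits chronologically.  The baseline is the lowest EDSS at a
#' relapse-free visit seen so far (roving baseline; configurable to the
#' first relapse-free visit).  A candidate event is the first relapse-free
#' visit whose EDSS exceeds the baseline by the required band increase
#' (1.0 point below baseline EDSS 6; 0.5 at or above) *and* reaches the
#' EDSS 4 floor.  The event is confirmed when a later relapse-free visit at
#' least `confirmation_days` after it still sits at or above the progressed
#' level (baseline + required increase) and every intervening relapse-free
#' visit stayed at or above that level.  The earliest confirmable event
#' wins; the conversion date is the event date.
#'
#' @param visits Data frame of one patient's visits (`visit_date`, `edss`,
#'   optionally `pyramidal_fs`), sorted by date.
#' @param relapses Optional data frame (or vector of dates) of the patient's
#'   relapse onset dates.
#' @param config An [msbase_config()].
#' @return A one-row tibble: `converted`, `conversion_date`,
#'   `baseline_date`, `baseline_edss`, `event_date`, `event_edss`,
#'   `confirm_date`, `confirm_edss`.
#' @examples
#' v <- tibble::tibble(
#'   visit_date = as.Date("2010-01-01") + c(0, 365, 487),
#'   edss = c(3.0, 4.5, 4.5)
#' )
#' detect_conversion(v)
#' @export
detect_conversion <- function(visits, relapses = NULL,
                              config = msbase_config()) {
  stopifnot(inherits(config, "msbase_config"))
  if (is.null(visits) || nrow(visits) == 0) {
    return(empty_progression_call())
  }
  check_columns(visits, c("visit_date", "edss"), "visits")
  dates <- as.Date(visits$visit_date)
  if (is.unsorted(as.numeric(dates), strictly = FALSE)) {
    abort("detect_conversion(): visits must be sorted by date.",
          class = "msclassify_contract_error")
  }
  edss <- visits$edss
  n <- length(edss)

  relapse_dates <- if (is.null(relapses)) {
    as.Date(character())
  } else if (is.data.frame(relapses)) {
    as.Date(relapses$relapse_date)
  } else {
    as.Date(relapses)
  }
  relapse_free <- vapply(seq_len(n), function(i) {
    !any(abs(as.numeric(dates[i] - relapse_dates)) <= config$relapse_window_days)
  }, logical(1))

  fs_ok <- rep(TRUE, n)
  if (isTRUE(config$require_pyramidal_fs)) {
    if (!"pyramidal_fs" %in% names(visits) || all(is.na(visits$pyramidal_fs))) {
      warn(paste(
        "require_pyramidal_fs is TRUE but no pyramidal FS scores are present:",
        "no visit can qualify and no conversion will ever be detected."
      ))
      fs_ok <- rep(FALSE, n)
    } else {
      fs_ok <- !is.na(visits$pyramidal_fs) &
        visits$pyramidal_fs >= config$fs_threshold
    }
  }

  mk_call <- function(b, i, j) {
    tibble::tibble(
      converted = TRUE,
      conversion_date = dates[i],
      baseline_date = dates[b], baseline_edss = edss[b],
      event_date = dates[i], event_edss = edss[i],
      confirm_date = dates[j], confirm_edss = edss[j]
    )
  }

  baseline_idx <- NA_integer_
  for (i in seq_len(n)) {
    if (!relapse_free[i]) next
    if (!is.na(baseline_idx)) {
      b_edss <- edss[baseline_idx]
      required <- if (b_edss < 6) config$min_increase_below6 else config$min_increase_at6plus
      level <- b_edss + required
      if (edss[i] - b_edss >= required - 1e-9 &&
          edss[i] >= config$edss_floor - 1e-9 &&
          fs_ok[i]) {
        # look for a confirming visit
        sustained <- TRUE
        for (j in seq_len(n)[-seq_len(i)]) {
          if (!relapse_free[j]) next
          if (edss[j] < level - 1e-9) { sustained <- FALSE; break }
          if (as.numeric(dates[j] - dates[i]) >= config$confirmation_days &&
              fs_ok[j] && sustained) {
            return(mk_call(baseline_idx, i, j))
          }
        }
      }
    }
    # rove (or fix) the baseline using relapse-free visits only
    if (is.na(baseline_idx)) {
      baseline_idx <- i
    } else if (config$baseline == "roving" && edss[i] < edss[baseline_idx]) {
      baseline_idx <- i
    }
  }
  empty_progression_call()
}

empty_progression_call <- function() {
  tibble::tibble(
    converted = FALSE,
    conversion_date = as.Date(NA),
    baseline_date = as.Date(NA), baseline_edss = NA_real_,
    event_date = as.Date(NA), event_edss = NA_real_,
    confirm_date = as.Date(NA), confirm_edss = NA_real_
  )
}

#' Label every patient in a cohort with the adapted MSBase algorithm
#'
#' Runs [detect_conversion()] per patient; a patient is labelled SP when a
#' confirmed conversion is detected by their latest visit, RR otherwise.
#' Patients with fewer than two visits carry no longitudinal information and
#' are labelled RR with `no_longitudinal_data = TRUE`.
#'
#' @param x An `ms_cohort`.
#' @param config An [msbase_config()].
#' @return A tibble with one row per patient: `patient_id`, `label`,
#'   `converted`, `conversion_date`, `baseline_edss`, `event_edss`,
#'   `no_longitudinal_data`.
#' @export
classify_msbase <- function(x, config = msbase_config()) {
  stopifnot(inherits(x, "ms_cohort"))
  visit_split <- split(x$visits, x$visits$patient_id)
  relapse_split <- split(x$relapses, x$relapses$patient_id)
  res <- purrr::map_dfr(x$patients$patient_id, function(pid) {
    v <- visit_split[[pid]]
    nv <- if (is.null(v)) 0L else nrow(v)
    if (nv < 2L) {
      out <- empty_progression_call()
      out$no_longitudinal_data <- TRUE
    } else {
      out <- detect_conversion(v, relapse_split[[pid]], config)
      out$no_longitudinal_data <- FALSE
    }
    out$patient_id <- pid
    out
  })
  res %>%
    dplyr::mutate(label = ifelse(.data$converted, "SP", "RR")) %>%
    dplyr::select("patient_id", "label", "converted", "conversion_date",
                  "baseline_edss", "event_edss", "no_longitudinal_data")
}
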