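#' The published nine-leaf rule table
#'
#' The final pruned decision tree, flattened to its nine terminal rules.
#' Each rule is a set of EDSS values (exact membership on the 0.5-grid) and a
#' half-open age band `[age_min, age_max)`, with the terminal probability of
#' SPMS and the implied label (SP when the probability exceeds 0.5).  The
#' printed age bands "<56", "56-64" and ">=64" are read as \[0, 56), \[56, 64)
#' and \[64, Inf): the only disjoint reading; likewise "<45"/">=45" split at
#' exactly 45.
#'
#' @return A tibble with one row per terminal rule: `rule_id`, `edss_rule`,
#'   `age_rule`, `age_min`, `age_max`, `sp_probability`, `label`.
#' @export
sp_rules <- function() {
  tibble::tibble(
    rule_id = 1:9,
    edss_rule = c("<3", "3, 3.5 or 4", "3 or 3.5", "4", "3", "3.5 or 4",
                  "4.5, 5, 5.5 or 6", "4.5, 5, 5.5 or 6", ">6"),
    age_rule = c("any", "<56", "56-64", "56-64", ">=64", ">=64",
                 "<45", ">=45", "any"),
    age_min = c(0, 0, 56, 56, 64, 64, 0, 45, 0),
    age_max = c(Inf, 56, 64, 64, Inf, Inf, 45, Inf, Inf),
    sp_probability = c(0.04, 0.18, 0.39, 0.53, 0.48, 0.61, 0.38, 0.76, 0.93),
    label = c("RR", "RR", "RR", "SP", "RR", "SP", "RR", "SP", "SP")
  )
}

# Rule id for (edss, age) pairs; inputs already validated.  EDSS membership
# is exact on the 0.5-grid; age bands are half-open [min, max).
match_rule <- function(edss, age) {
  e2 <- as.integer(round(edss * 2)) # EDSS in half-points, exact arithmetic
  dplyr::case_when(
    e2 < 6                          ~ 1L, # EDSS < 3
    e2 > 12                         ~ 9L, # EDSS > 6
    e2 %in% c(6L, 7L, 8L) & age < 56 ~ 2L, # 3, 3.5, 4 and age < 56
    e2 %in% c(6L, 7L) & age < 64     ~ 3L, # 3, 3.5 and 56 <= age < 64
    e2 == 8L & age < 64              ~ 4L, # 4 and 56 <= age < 64
    e2 == 6L                         ~ 5L, # 3 and age >= 64
    e2 %in% c(7L, 8L)                ~ 6L, # 3.5, 4 and age >= 64
    age < 45                         ~ 7L, # 4.5-6 and age < 45
    TRUE                             ~ 8L  # 4.5-6 and age >= 45
  )
}

#' Classify MS phenotype from the latest EDSS score and age
#'
#' Applies the published nine-rule decision tree: given a patient's most
#' recent EDSS score and their age at that assessment, returns the terminal
#' probability of secondary progressive MS and the corresponding label
#' (SP when the probability exceeds 0.5, otherwise RR).  The classifier is a
#' deterministic lookup: exactly one rule matches any valid input.
#'
#' @param edss Numeric vector of EDSS scores (0 or 0.5-multiples in \[1, 10\]).
#' @param age Numeric vector of ages in years at the EDSS assessment
#'   (recycled against `edss`).
#' @param floor_age Truncate ages to whole years before applying the age
#'   bands, mimicking registries that store integer ages.  Off by default:
#'   bands apply to the real-valued age.
#' @return A tibble with columns `edss`, `age`, `rule_id`, `label`,
#'   `sp_probability`.
#' @examples
#' classify_ms(edss = c(1.5, 7.0, 4.0), age = c(70, 30, 60))
#' @export
classify_ms <- function(edss, age, floor_age = FALSE) {
  validate_edss(edss)
  if (any(!is.finite(age)) || any(age < 0)) {
    abort("classify_ms(): age must be finite and non-negative.",
          class = "msclassify_domain_error")
  }
  n <- max(length(edss), length(age))
  edss <- rep_len(edss, n)
  age <- rep_len(age, n)
  band_age <- if (floor_age) floor(age) else age
  rid <- match_rule(edss, band_age)
  rules <- sp_rules()
  tibble::tibble(
    edss = edss,
    age = age,
    rule_id = rid,
    label = rules$label[rid],
    sp_probability = rules$sp_probability[rid]
  )
}

#' Classify every patient in a cohort from their latest assessment
#'
#' Looks up each patient's most recent EDSS visit and age at that visit, and
#' applies [classify_ms()].  Patients without any recorded visit cannot be
#' classified; they are excluded with a warning giving the count.
#'
#' @param x An `ms_cohort`.
#' @param floor_age Passed to [classify_ms()].
#' @return A tibble with one row per classifiable patient: `patient_id`,
#'   `visit_date`, `edss`, `age`, `rule_id`, `label`, `sp_probability`.
#' @export
classify_cohort <- function(x, floor_age = FALSE) {
  stopifnot(inherits(x, "ms_cohort"))
  latest <- latest_assessments(x)
  n_missing <- nrow(x$patients) - nrow(latest)
  if (n_missing > 0) {
    warn(sprintf("%d patient(s) without visits excluded from classification.",
                 n_missing))
  }
  if (nrow(latest) == 0) {
    return(tibble::tibble(
      patient_id = character(), visit_date = as.Date(character()),
      edss = numeric(), age = numeric(), rule_id = integer(),
      label = character(), sp_probability = numeric()
    ))
  }
  res <- classify_ms(latest$edss, latest$age, floor_age = floor_age)
  dplyr::bind_cols(
    dplyr::select(latest, "patient_id", "visit_date"),
    res
  )
}
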