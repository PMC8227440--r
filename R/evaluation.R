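wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

wald_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Diagnostic-accuracy metrics for a two-class labelling
#'
#' Computes accuracy, sensitivity, specificity, positive predictive value
#' and negative predictive value of `predicted` against `reference`, with
#' 95% binomial confidence intervals (Wilson score by default).  The
#' positive class defaults to RR, the convention used when benchmarking the
#' phenotype classifiers.  Metrics with a zero denominator are reported as
#' `NA` with a reason.
#'
#' @param predicted,reference Equal-length vectors of labels (`"RR"`/`"SP"`
#'   or any two classes containing `positive`).
#' @param positive The positive class (default `"RR"`).
#' @param ci_method `"wilson"` (default) or `"wald"`.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `ms_confusion`: counts (`tp`, `fp`, `fn`,
#'   `tn`) plus a metric tibble; `tidy()` returns the tibble, `glance()` a
#'   one-row summary.
#' @examples
#' confusion_metrics(c("RR", "RR", "SP"), c("RR", "SP", "SP"))
#' @export
confusion_metrics <- function(predicted, reference, positive = "RR",
                              ci_method = c("wilson", "wald"), conf = 0.95) {
  ci_method <- match.arg(ci_method)
  predicted <- as.character(predicted)
  reference <- as.character(reference)
  if (length(predicted) == 0) {
    abort("confusion_metrics(): empty input.", class = "msclassify_domain_error")
  }
  if (length(predicted) != length(reference)) {
    abort("confusion_metrics(): predicted and reference differ in length.",
          class = "msclassify_domain_error")
  }
  tp <- sum(predicted == positive & reference == positive)
  fp <- sum(predicted == positive & reference != positive)
  fn <- sum(predicted != positive & reference == positive)
  tn <- sum(predicted != positive & reference != positive)

  ci_fun <- if (ci_method == "wilson") wilson_ci else wald_ci
  row <- function(metric, num, den, reason) {
    if (den == 0) {
      tibble::tibble(metric = metric, estimate = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_,
                     numerator = num, denominator = den,
                     note = reason)
    } else {
      ci <- ci_fun(num, den, conf)
      tibble::tibble(metric = metric, estimate = num / den,
                     conf.low = ci[1], conf.high = ci[2],
                     numerator = num, denominator = den,
                     note = NA_character_)
    }
  }
  metrics <- dplyr::bind_rows(
    row("accuracy", tp + tn, tp + fp + fn + tn, "no observations"),
    row("sensitivity", tp, tp + fn, "no positive-class reference labels"),
    row("specificity", tn, tn + fp, "no negative-class reference labels"),
    row("ppv", tp, tp + fp, "no positive predictions"),
    row("npv", tn, tn + fn, "no negative predictions")
  )
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         positive = positive, ci_method = ci_method, conf = conf,
         metrics = metrics),
    class = "ms_confusion"
  )
}

#' @export
print.ms_confusion <- function(x, ...) {
  cat(sprintf("<ms_confusion> positive class: %s (tp %d, fp %d, fn %d, tn %d)\n",
              x$positive, x$tp, x$fp, x$fn, x$tn))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.ms_confusion <- function(x, ...) x$metrics

#' @export
glance.ms_confusion <- function(x, ...) {
  est <- stats::setNames(x$metrics$estimate, x$metrics$metric)
  tibble::tibble(
    n = x$tp + x$fp + x$fn + x$tn,
    accuracy = est[["accuracy"]], sensitivity = est[["sensitivity"]],
    specificity = est[["specificity"]], ppv = est[["ppv"]], npv = est[["npv"]],
    positive = x$positive, ci_method = x$ci_method
  )
}

#' Kaplan-Meier curve of time to SP conversion
#'
#' Product-limit estimate of the survivor function (probability of not yet
#' having converted), with Greenwood variance and log-transformed 95%
#' confidence band, and the median time with its confidence interval.
#' The median is the smallest time at which the estimated survival drops to
#' 0.5 or below; when the curve never reaches 0.5 it is reported as `NA`
#' (not reached).
#'
#' @param time Event or censoring times (years, non-negative).
#' @param event Logical (or 0/1): `TRUE` when conversion was observed,
#'   `FALSE` when censored.
#' @param conf_type Confidence-band transform passed to
#'   [survival::survfit()] (default `"log"`).
#' @return An object of class `ms_km`: a step-function tibble plus median
#'   summary; `tidy()` returns the curve, `glance()` the medians and counts.
#' @examples
#' km_curve(c(1, 2, 3, 4, 5), c(TRUE, TRUE, TRUE, TRUE, TRUE))
#' @export
km_curve <- function(time, event, conf_type = "log") {
  if (any(time < 0, na.rm = TRUE)) {
    abort("km_curve(): times must be non-negative.",
          class = "msclassify_domain_error")
  }
  event <- as.integer(as.logical(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = conf_type)
  steps <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    estimate = fit$surv,
    std_error = fit$std.err,
    conf.low = fit$lower,
    conf.high = fit$upper
  )
  q <- stats::quantile(fit, probs = 0.5)
  med <- unname(if (is.list(q)) q$quantile else q)
  med_ci <- if (is.list(q)) c(unname(q$lower), unname(q$upper)) else c(NA, NA)
  structure(
    list(
      steps = steps,
      median = med, median_low = med_ci[1], median_high = med_ci[2],
      n = length(time), n_events = sum(event), n_censored = sum(1 - event),
      survfit = fit
    ),
    class = "ms_km"
  )
}

#' @export
print.ms_km <- function(x, ...) {
  cat(sprintf(
    "<ms_km> %d subjects, %d events, %d censored; median %s (95%% CI %s-%s)\n",
    x$n, x$n_events, x$n_censored,
    ifelse(is.na(x$median), "not reached", format(x$median, digits = 4)),
    format(x$median_low, digits = 4), format(x$median_high, digits = 4)
  ))
  invisible(x)
}

#' @export
tidy.ms_km <- function(x, ...) x$steps

#' @export
glance.ms_km <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, n_censored = x$n_censored,
    median = x$median, median_conf.low = x$median_low,
    median_conf.high = x$median_high
  )
}

#' Profile patients by (reference, predicted) classification cell
#'
#' Summarises the concordant and discordant cells of a classification
#' against the clinically assigned phenotype: mean (SD) age at the latest
#' visit, percent female, mean (SD) onset age, median \[IQR\] disease
#' duration, median \[IQR\] latest EDSS — the column set used to
#' characterise misclassified patients.  Empty cells are omitted.
#'
#' @param x An `ms_cohort`.
#' @param predicted A tibble with columns `patient_id` and `label`
#'   (e.g. the output of [classify_cohort()] or [classify_msbase()]).
#' @return A tibble with one row per non-empty (reference, predicted) cell.
#' @export
misclassification_profile <- function(x, predicted) {
  stopifnot(inherits(x, "ms_cohort"))
  check_columns(predicted, c("patient_id", "label"), "predicted")
  latest <- latest_assessments(x)
  df <- latest %>%
    dplyr::inner_join(
      dplyr::select(x$patients, "patient_id", "sex", "birth_date", "onset_date"),
      by = "patient_id"
    ) %>%
    dplyr::inner_join(
      dplyr::select(predicted, "patient_id", predicted_label = "label"),
      by = "patient_id"
    ) %>%
    dplyr::mutate(
      duration = as.numeric(.data$visit_date - .data$onset_date) / 365.25,
      onset_age = age_at(.data$birth_date, .data$onset_date)
    )
  df %>%
    dplyr::group_by(reference = .data$assigned_phenotype,
                    predicted = .data$predicted_label) %>%
    dplyr::summarise(
      n = dplyr::n(),
      concordant = unique(.data$assigned_phenotype == .data$predicted_label),
      age_last_mean = mean(.data$age),
      age_last_sd = stats::sd(.data$age),
      female_pct = 100 * mean(.data$sex == "female"),
      onset_age_mean = mean(.data$onset_age),
      onset_age_sd = stats::sd(.data$onset_age),
      duration_median = stats::median(.data$duration),
      duration_q1 = unname(stats::quantile(.data$duration, 0.25)),
      duration_q3 = unname(stats::quantile(.data$duration, 0.75)),
      edss_median = stats::median(.data$edss),
      edss_q1 = unname(stats::quantile(.data$edss, 0.25)),
      edss_q3 = unname(stats::quantile(.data$edss, 0.75)),
      .groups = "drop"
    )
}

# Per-patient event table for one labelling method: SP status and, for SP,
# the date attached to the conversion; RR patients are censored at their
# last visit.
method_events <- function(x, method, config, floor_age) {
  latest <- latest_assessments(x)
  base <- dplyr::select(x$patients, "patient_id", "birth_date", "onset_date")
  if (method == "clinical") {
    ev <- x$patients %>%
      dplyr::transmute(
        patient_id = .data$patient_id,
        event = .data$assigned_phenotype == "SP",
        event_date = .data$sp_date
      )
  } else if (method == "tree") {
    # the tree gives a status, not a date: use the earliest visit at which
    # the classifier returns SP
    vis <- x$visits %>%
      dplyr::inner_join(dplyr::select(x$patients, "patient_id", "birth_date"),
                        by = "patient_id") %>%
      dplyr::mutate(age = age_at(.data$birth_date, .data$visit_date))
    cls <- classify_ms(vis$edss, vis$age, floor_age = floor_age)
    vis$pred <- cls$label
    ev <- vis %>%
      dplyr::filter(.data$pred == "SP") %>%
      dplyr::group_by(.data$patient_id) %>%
      dplyr::summarise(event_date = min(.data$visit_date), .groups = "drop") %>%
      dplyr::mutate(event = TRUE)
    ev <- dplyr::left_join(
      tibble::tibble(patient_id = x$patients$patient_id), ev,
      by = "patient_id"
    ) %>%
      dplyr::mutate(event = !is.na(.data$event))
  } else if (method == "msbase") {
    calls <- classify_msbase(x, config)
    ev <- calls %>%
      dplyr::transmute(
        patient_id = .data$patient_id,
        event = .data$converted,
        event_date = .data$conversion_date
      )
  } else {
    abort(sprintf("Unknown labelling method '%s'.", method),
          class = "msclassify_domain_error")
  }
  ev %>%
    dplyr::inner_join(base, by = "patient_id") %>%
    dplyr::inner_join(dplyr::select(latest, "patient_id",
                                    last_visit = "visit_date"),
                      by = "patient_id") %>%
    dplyr::mutate(
      end_date = dplyr::if_else(.data$event, as.Date(.data$event_date),
                                .data$last_visit),
      time_from_birth = age_at(.data$birth_date, .data$end_date),
      time_from_onset = pmax(
        as.numeric(.data$end_date - .data$onset_date) / 365.25, 0
      )
    )
}

#' Compare time to SP conversion across labelling methods
#'
#' Builds Kaplan-Meier curves of time to secondary progression — from birth
#' (i.e. age at conversion) and from symptom onset — for each requested
#' labelling method: the clinical (neurologist-assigned) label, the
#' cross-sectional decision tree, and the longitudinal MSBase detector.
#' Patients not labelled SP by a method are censored at their last visit.
#' For the decision tree, which returns a status rather than a date, the
#' event date is the earliest visit at which the classifier returns SP.
#'
#' @param x An `ms_cohort`.
#' @param methods Subset of `c("clinical", "tree", "msbase")`.
#' @param config [msbase_config()] for the MSBase labeller.
#' @param floor_age Passed to [classify_ms()] for the tree labeller.
#' @return An object of class `ms_tts` with a `summary` tibble (method,
#'   origin, median and 95% CI, event/censor counts) and a named list of
#'   `ms_km` curves.
#' @export
compare_time_to_sp <- function(x, methods = c("clinical", "tree", "msbase"),
                               config = msbase_config(), floor_age = FALSE) {
  stopifnot(inherits(x, "ms_cohort"))
  methods <- match.arg(methods, several.ok = TRUE)
  curves <- list()
  rows <- list()
  for (m in methods) {
    ev <- method_events(x, m, config, floor_age)
    for (origin in c("birth", "onset")) {
      tvar <- if (origin == "birth") ev$time_from_birth else ev$time_from_onset
      km <- km_curve(tvar, ev$event)
      curves[[paste(m, origin, sep = "_")]] <- km
      rows[[paste(m, origin)]] <- tibble::tibble(
        method = m, origin = origin,
        median = km$median, conf.low = km$median_low,
        conf.high = km$median_high,
        n_events = km$n_events, n_censored = km$n_censored
      )
    }
  }
  structure(
    list(summary = dplyr::bind_rows(rows), curves = curves),
    class = "ms_tts"
  )
}

#' @export
print.ms_tts <- function(x, ...) {
  cat("<ms_tts> median time to SP by labelling method\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ms_tts <- function(x, ...) {
  purrr::imap_dfr(x$curves, function(km, nm) {
    parts <- strsplit(nm, "_")[[1]]
    dplyr::mutate(tidy(km),
                  method = parts[1], origin = parts[2],
                  .before = 1)
  })
}

#' @export
glance.ms_tts <- function(x, ...) x$summary
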