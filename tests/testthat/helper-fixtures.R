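# Small in-code fixtures shared across test files.

toy_patients <- function() {
  tibble::tibble(
    patient_id = c("P1", "P2"),
    sex = c("female", "male"),
    birth_date = as.Date(c("1970-01-01", "1960-06-15")),
    onset_date = as.Date(c("2000-06-15", "1990-03-01")),
    assigned_phenotype = c("RR", "SP"),
    sp_date = as.Date(c(NA, "2010-05-20"))
  )
}

toy_visits <- function() {
  tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P2"),
    visit_date = as.Date(c("2010-01-01", "2018-03-05", "2000-01-01", "2015-06-01")),
    edss = c(2.0, 5.5, 3.0, 6.5)
  )
}

toy_cohort <- function() {
  cohort(toy_patients(), toy_visits())
}

# EDSS visit series builder: months (from an arbitrary origin) and scores.
visit_series <- function(months, edss, origin = as.Date("2010-01-01")) {
  tibble::tibble(
    visit_date = origin + round(months * 30.4375),
    edss = edss
  )
}

# Brute-force confusion counts: naive element-by-element loop, kept
# independent of the package implementation.
brute_confusion <- function(predicted, reference, positive) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(predicted)) {
    if (predicted[i] == positive && reference[i] == positive) tp <- tp + 1L
    else if (predicted[i] == positive) fp <- fp + 1L
    else if (reference[i] == positive) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / length(predicted),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

# All valid EDSS scores.
valid_edss_grid <- function() setdiff(seq(0, 10, by = 0.5), 0.5)
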