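test_that("confusion metrics match the hand-computed example", {
  predicted <- c("RR", "RR", "RR", rep("SP", 7))
  reference <- c("RR", "RR", "SP", "RR", rep("SP", 6))
  cm <- confusion_metrics(predicted, reference, positive = "RR")
  expect_equal(cm$tp, 2); expect_equal(cm$fp, 1)
  expect_equal(cm$fn, 1); expect_equal(cm$tn, 6)
  est <- setNames(cm$metrics$estimate, cm$metrics$metric)
  expect_equal(unname(est["accuracy"]), 0.8)
  expect_equal(unname(est["sensitivity"]), 2 / 3)
  expect_equal(unname(est["specificity"]), 6 / 7)
  expect_equal(unname(est["ppv"]), 2 / 3)
  expect_equal(unname(est["npv"]), 6 / 7)
  # CIs contain their point estimates
  ok <- !is.na(cm$metrics$estimate)
  expect_true(all(cm$metrics$conf.low[ok] <= cm$metrics$estimate[ok]))
  expect_true(all(cm$metrics$conf.high[ok] >= cm$metrics$estimate[ok]))
})

test_that("perfect and inverted predictions hit the boundary values", {
  ref <- rep(c("RR", "SP"), 10)
  perfect <- confusion_metrics(ref, ref)
  expect_true(all(perfect$metrics$estimate == 1))
  inverted <- confusion_metrics(ifelse(ref == "RR", "SP", "RR"), ref)
  expect_equal(inverted$metrics$estimate[inverted$metrics$metric == "accuracy"], 0)
})

test_that("confusion metrics agree with brute-force counting", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    pred <- sample(c("RR", "SP"), n, TRUE)
    ref <- sample(c("RR", "SP"), n, TRUE)
    bf <- brute_confusion(pred, ref, "RR")
    cm <- confusion_metrics(pred, ref, positive = "RR")
    expect_equal(cm$tp, bf$tp); expect_equal(cm$fp, bf$fp)
    expect_equal(cm$fn, bf$fn); expect_equal(cm$tn, bf$tn)
    est <- setNames(cm$metrics$estimate, cm$metrics$metric)
    for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
      expect_equal(unname(est[m]), bf[[m]])
    }
  }
})

test_that("swapping the positive class swaps the paired metrics exactly", {
  set.seed(9)
  pred <- sample(c("RR", "SP"), 200, TRUE, prob = c(0.6, 0.4))
  ref <- sample(c("RR", "SP"), 200, TRUE, prob = c(0.7, 0.3))
  a <- glance(confusion_metrics(pred, ref, positive = "RR"))
  b <- glance(confusion_metrics(pred, ref, positive = "SP"))
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  expect_equal(a$ppv, b$npv)
  expect_equal(a$npv, b$ppv)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("degenerate metric denominators are reported as missing", {
  cm <- confusion_metrics(c("SP", "SP"), c("SP", "SP"), positive = "RR")
  sens <- cm$metrics[cm$metrics$metric == "sensitivity", ]
  expect_true(is.na(sens$estimate))
  expect_match(sens$note, "reference")
  expect_error(confusion_metrics(character(), character()),
               class = "msclassify_domain_error")
})

test_that("the product-limit curve matches hand-computed survival", {
  # no censoring: steps 0.8, 0.6, 0.4, 0.2, 0 and median 3
  km <- km_curve(1:5, rep(TRUE, 5))
  expect_equal(tidy(km)$estimate, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)
  # censoring shrinks later risk sets: {1, 2+, 3, 3+} has four at risk at
  # t=1 and two at t=3, so S = 3/4 after t=1 and (3/4)*(1/2) = 3/8 after t=3
  km2 <- km_curve(c(1, 2, 3, 3), c(TRUE, FALSE, TRUE, FALSE))
  d2 <- tidy(km2)
  expect_equal(d2$estimate[d2$time == 1], 3 / 4)
  expect_equal(d2$estimate[d2$time == 3], 3 / 8)
  # with {1, 2+, 3} the last subject is alone at risk, so S drops to 0
  d3 <- tidy(km_curve(c(1, 2, 3), c(TRUE, FALSE, TRUE)))
  expect_equal(d3$estimate[d3$time == 1], 2 / 3)
  expect_equal(d3$estimate[d3$time == 3], 0)
  # all censored: flat at 1, median not reached
  km3 <- km_curve(c(2, 4, 6), c(FALSE, FALSE, FALSE))
  expect_true(all(tidy(km3)$estimate == 1))
  expect_true(is.na(km3$median))
})

test_that("the empirical survivor function is recovered when uncensored", {
  set.seed(21)
  t <- round(rexp(300, 0.1), 2)
  km <- km_curve(t, rep(TRUE, 300))
  d <- tidy(km)
  ecdf_surv <- 1 - ecdf(t)(d$time)
  expect_equal(d$estimate, ecdf_surv, tolerance = 1e-10)
})

test_that("misclassification profiling summarises each cell", {
  # all concordant: no discordant rows
  co <- toy_cohort()
  pred <- tibble::tibble(patient_id = c("P1", "P2"), label = c("RR", "SP"))
  prof <- misclassification_profile(co, pred)
  expect_equal(nrow(prof), 2)
  expect_true(all(prof$concordant))
  # one misclassified RR -> SP: that cell's mean age is the patient's age
  pred2 <- tibble::tibble(patient_id = c("P1", "P2"), label = c("SP", "SP"))
  prof2 <- misclassification_profile(co, pred2)
  cell <- prof2[prof2$reference == "RR" & prof2$predicted == "SP", ]
  expect_equal(cell$n, 1)
  la <- latest_assessments(co)
  expect_equal(cell$age_last_mean, la$age[la$patient_id == "P1"])
})

test_that("misclassified RR patients carry higher EDSS than concordant RR", {
  co <- simulate_cohort(n_patients = 1500, seed = 23)
  pred <- dplyr::select(classify_cohort(co), "patient_id", "label")
  prof <- misclassification_profile(co, pred)
  conc <- prof[prof$reference == "RR" & prof$predicted == "RR", ]
  misc <- prof[prof$reference == "RR" & prof$predicted == "SP", ]
  expect_gt(misc$n, 0)
  expect_gt(misc$edss_median, conc$edss_median)
})

test_that("time-to-SP comparison censors non-converters and orders methods", {
  co <- simulate_cohort(n_patients = 800, seed = 29)
  tts <- compare_time_to_sp(co)
  s <- tts$summary
  expect_setequal(unique(s$method), c("clinical", "tree", "msbase"))
  expect_setequal(unique(s$origin), c("birth", "onset"))
  # birth-origin medians exceed onset-origin medians (age at onset > 0)
  for (m in unique(s$method)) {
    expect_gt(s$median[s$method == m & s$origin == "birth"],
              s$median[s$method == m & s$origin == "onset"])
  }
  # a cohort with no SP transitions: all medians not reached
  co_rr <- simulate_cohort(n_patients = 60, seed = 5, sp_median_years = Inf)
  tts_rr <- compare_time_to_sp(co_rr, methods = "clinical")
  expect_true(all(is.na(tts_rr$summary$median)))
})
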