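test_that("a confirmed one-point increase reaching EDSS 4 converts", {
  v <- visit_series(c(0, 12, 16), c(3.0, 4.5, 4.5))
  call <- detect_conversion(v)
  expect_true(call$converted)
  expect_equal(call$conversion_date, v$visit_date[2])
  expect_equal(call$baseline_edss, 3.0)
  expect_equal(call$event_edss, 4.5)
  expect_equal(call$confirm_date, v$visit_date[3])
})

test_that("the EDSS 4 floor blocks conversion below it", {
  v <- visit_series(c(0, 12, 24, 36), c(1.0, 2.0, 3.0, 3.5))
  expect_false(detect_conversion(v)$converted)
})

test_that("a relapse near the event visit invalidates it", {
  v <- visit_series(c(0, 12, 16), c(3.0, 4.5, 3.0))
  relapse <- tibble::tibble(relapse_date = v$visit_date[2] - 10)
  call <- detect_conversion(v, relapse)
  expect_false(call$converted)
  # the same series without the relapse does convert at month 12 and is
  # then broken by the unsustained month-16 score
  expect_false(detect_conversion(v)$converted)
})

test_that("baselines at EDSS 6 or more need only a half-point increase", {
  v <- visit_series(c(0, 6, 10), c(6.0, 6.5, 6.5))
  call <- detect_conversion(v)
  expect_true(call$converted)
  expect_equal(call$conversion_date, v$visit_date[2])
  # below 6 the same half-point increase is not enough
  v2 <- visit_series(c(0, 6, 10), c(5.0, 5.5, 5.5))
  expect_false(detect_conversion(v2)$converted)
})

test_that("confirmation requires the progressed level to be sustained", {
  # an intervening relapse-free dip below the progressed level breaks it
  v <- visit_series(c(0, 12, 14, 16), c(3.0, 4.5, 3.5, 4.5))
  expect_false(detect_conversion(v)$converted)
  # a dip at a relapse-associated visit is ignored
  v2 <- v
  relapse <- tibble::tibble(relapse_date = v2$visit_date[3] - 5)
  expect_true(detect_conversion(v2, relapse)$converted)
})

test_that("the confirmation visit must be at least three months later", {
  v <- visit_series(c(0, 12, 14), c(3.0, 4.5, 4.5))
  expect_false(detect_conversion(v)$converted) # 2-month gap only
  v$visit_date[3] <- v$visit_date[2] + 91
  expect_true(detect_conversion(v)$converted)
  v$visit_date[3] <- v$visit_date[2] + 90
  expect_false(detect_conversion(v)$converted)
})

test_that("the roving baseline resets to lower relapse-free scores", {
  # fixed-baseline mode measures from the first visit; roving from the dip
  v <- visit_series(c(0, 12, 24, 36, 40), c(4.0, 3.0, 4.0, 4.0, 4.0))
  expect_true(detect_conversion(v)$converted) # 3.0 -> 4.0 sustained
  cfg_fixed <- msbase_config(baseline = "fixed")
  expect_false(detect_conversion(v, config = cfg_fixed)$converted)
})

test_that("appending later visits never withdraws a conversion", {
  set.seed(31)
  co <- simulate_cohort(n_patients = 120, seed = 31)
  ids <- unique(co$visits$patient_id)
  for (pid in ids[1:60]) {
    v <- co$visits[co$visits$patient_id == pid, ]
    r <- co$relapses[co$relapses$patient_id == pid, ]
    if (nrow(v) < 3) next
    prefix <- detect_conversion(v[1:(nrow(v) - 1), ], r)
    full <- detect_conversion(v, r)
    if (prefix$converted) {
      expect_true(full$converted)
      expect_equal(full$conversion_date, prefix$conversion_date)
    }
  }
})

test_that("raising the required increase never adds conversions", {
  co <- simulate_cohort(n_patients = 150, seed = 17)
  n_conv <- vapply(c(1.0, 1.5, 2.0), function(inc) {
    sum(classify_msbase(co, msbase_config(min_increase_below6 = inc))$converted)
  }, numeric(1))
  expect_true(all(diff(n_conv) <= 0))
})

test_that("single-visit patients are RR with a no-longitudinal-data flag", {
  p <- toy_patients()[1, ]
  v <- toy_visits()[1, ]
  res <- classify_msbase(cohort(p, v))
  expect_equal(res$label, "RR")
  expect_true(res$no_longitudinal_data)
  # flat low-EDSS patients are all RR
  co <- cohort(toy_patients(),
               tidyr::expand_grid(patient_id = c("P1", "P2"),
                                  visit_date = as.Date("2012-01-01") +
                                    c(0, 200, 400)) %>%
                 dplyr::mutate(edss = 2.0))
  expect_true(all(classify_msbase(co)$label == "RR"))
})

test_that("requiring pyramidal FS without FS data warns and blocks conversion", {
  v <- visit_series(c(0, 12, 16), c(3.0, 4.5, 4.5))
  cfg <- msbase_config(require_pyramidal_fs = TRUE)
  expect_warning(call <- detect_conversion(v, config = cfg), "pyramidal")
  expect_false(call$converted)
  # with FS scores present and above threshold the gate opens
  v$pyramidal_fs <- c(1L, 2L, 3L)
  expect_true(detect_conversion(v, config = cfg)$converted)
})

test_that("unsorted visits violate the contract", {
  v <- visit_series(c(12, 0), c(4.5, 3.0))
  expect_error(detect_conversion(v), class = "msclassify_contract_error")
})
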