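test_that("weight normalization divides absolute rates by body weight", {
  expect_equal(weight_normalize(16, 80), 0.2)
  expect_equal(weight_normalize(0, 70), 0)
  expect_equal(weight_normalize(24, 79), 0.3038, tolerance = 1e-4)
  expect_error(weight_normalize(10, NA), "weight")
  expect_error(weight_normalize(10, 0), "weight")
  expect_error(weight_normalize(-5, 70), "invalid")
})

test_that("outlier exclusion removes implausible rates and counts them", {
  ev <- make_events(c(0, 10, 20), 10, c(0.2, 0.4, 7))
  res <- exclude_outlier_rates(ev, 5)
  expect_equal(res$events$rate, c(0.2, 0.4))
  expect_equal(res$excluded, 1)
  res2 <- exclude_outlier_rates(make_events(0, 10, 0.2), 5)
  expect_equal(res2$excluded, 0)
  res3 <- exclude_outlier_rates(make_events(c(0, 10), 10, c(6, 8)), 5)
  expect_equal(nrow(res3$events), 0)
  expect_equal(res3$excluded, 2)
})

test_that("stable peak keeps sustained rates and skips transient spikes", {
  # trivially stable single segment
  expect_equal(stable_peak_dose(make_events(0, 60, 0.3), 0), 0.3)
  # a 2-min excursion to 1.5 fails the 5-min rule; fall back to 0.3
  ev <- make_events(c(0, 60, 62), c(60, 2, 60), c(0.3, 1.5, 0.3))
  expect_equal(stable_peak_dose(ev, 0), 0.3)
  # adjacent segments within 10% of 0.5 combine into a 9-min stable window
  ev2 <- make_events(c(0, 3, 6), 3, c(0.5, 0.48, 0.5))
  expect_equal(stable_peak_dose(ev2, 0), 0.5)
})

test_that("stable peak handles gaps, windows and degenerate streams", {
  # a pump-off gap breaks the stability interval: two 3-min halves of a
  # 6-min plateau separated by a gap do not qualify
  ev <- make_events(c(0, 10), 3, c(0.4, 0.4))
  expect_true(is.na(stable_peak_dose(ev, 0)))
  # events outside the 24-h window are ignored
  ev2 <- make_events(c(0, 25 * 60), c(30, 60), c(0.2, 0.9))
  expect_equal(stable_peak_dose(ev2, 0), 0.2)
  # empty stream -> missing
  expect_true(is.na(stable_peak_dose(make_events(numeric(0), numeric(0),
                                                 numeric(0)), 0)))
  # all-zero rates -> missing
  expect_true(is.na(stable_peak_dose(make_events(0, 60, 0), 0)))
  # malformed streams are data-integrity errors
  expect_error(stable_peak_dose(make_events(0, -5, 0.3), 0), "end <= start")
  expect_error(stable_peak_dose(make_events(c(0, 5), c(10, 10), c(0.3, 0.3)),
                                0), "overlapping")
})

test_that("stable peak is invariant to splitting segments at identical rate", {
  set.seed(31)
  for (k in 1:15) {
    ev <- random_stream(k + 400)
    # split every segment into two halves with the same rate
    half <- (ev$end - ev$start) / 2
    split_ev <- rbind(
      make_events(ev$start, half, ev$rate),
      make_events(ev$start + half, half, ev$rate))
    expect_equal(stable_peak_dose(split_ev, 0), stable_peak_dose(ev, 0),
                 info = paste("stream", k))
  }
})

test_that("stable peak never exceeds the maximum observed rate", {
  for (k in 1:25) {
    ev <- random_stream(k + 900)
    peak <- stable_peak_dose(ev, 0)
    if (!is.na(peak)) expect_lte(peak, max(ev$rate))
  }
})

test_that("stable peak agrees with the brute-force interval scanner", {
  for (k in 1:60) {
    ev <- random_stream(k)
    expect_identical(stable_peak_dose(ev, 0), brute_force_peak(ev, 0),
                     info = paste("stream", k))
  }
})

test_that("diagnosis dose is the rate started nearest shock onset", {
  ev <- make_events(c(-10, 30), c(20, 30), c(0.05, 0.2))
  expect_equal(diagnosis_dose(ev, 0), 0.05)
  expect_equal(diagnosis_dose(make_events(0, 30, 0.1), 0), 0.1)
  # exact tie broken toward the earlier event
  ev2 <- make_events(c(-5, 5), c(4, 30), c(0.08, 0.12))
  expect_equal(diagnosis_dose(ev2, 0), 0.08)
  expect_true(is.na(diagnosis_dose(make_events(numeric(0), numeric(0),
                                               numeric(0)), 0)))
})

test_that("peak NE-equivalent sums concurrent weighted drug rates", {
  ev <- data.frame(
    drug = c("norepinephrine", "vasopressin"),
    start = c(0, 30), end = c(60, 90), rate = c(0.2, 0.02),
    unit = c("ug/kg/min", "U/min"))
  # overlap on [30, 60): 0.2 + 2.5 * 0.02 = 0.25
  expect_equal(peak_ne_equivalent(ev, 0), 0.25)
  # NE alone equals its own rate
  expect_equal(peak_ne_equivalent(ev[1, ], 0), 0.2)
  expect_error(peak_ne_equivalent(transform(ev, unit = "ug/kg/min"), 0),
               "unit mismatch")
})

test_that("extractor recovers the latent peak on spike-free generator output", {
  sim <- generate_cohort(cohort_config(n_patients = 150, spike_rate = 0,
                                       outlier_rate = 0, seed = 13))
  scr <- apply_screen(sim$tables)
  truth <- sim$truth[match(scr$cohort$patient_id, sim$truth$patient_id), ]
  expect_equal(nrow(scr$cohort), 150)
  expect_identical(scr$cohort$peak_dose_24h, truth$base_peak_dose)
})

test_that("extractor recovers the latent peak through weight normalization", {
  sim <- generate_cohort(cohort_config(n_patients = 80, spike_rate = 0,
                                       outlier_rate = 0, seed = 17,
                                       rate_unit = "ug/min"))
  expect_true(all(sim$tables$infusion_events$rate_unit[
    sim$tables$infusion_events$drug == "norepinephrine"] == "ug/min"))
  scr <- apply_screen(sim$tables)
  truth <- sim$truth[match(scr$cohort$patient_id, sim$truth$patient_id), ]
  expect_equal(scr$cohort$peak_dose_24h, truth$base_peak_dose,
               tolerance = 1e-12)
})

test_that("spikes and outliers do not disturb the extracted peak", {
  sim <- generate_cohort(cohort_config(n_patients = 150, spike_rate = 1.5,
                                       outlier_rate = 0.5, seed = 19))
  scr <- apply_screen(sim$tables)
  truth <- sim$truth[match(scr$cohort$patient_id, sim$truth$patient_id), ]
  expect_equal(scr$cohort$peak_dose_24h, truth$base_peak_dose,
               tolerance = 1e-12)
  expect_gt(sum(scr$cohort$outliers_excluded), 0)
})
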