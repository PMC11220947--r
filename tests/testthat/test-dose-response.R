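test_that("stacking yields one row per patient and formulation", {
  cohort <- tibble::tibble(patient_id = "P1", diagnosis_dose = 0.24,
                           peak_dose_24h = 0.24, death_28d = 1L)
  d <- stack_formulations(cohort, "diagnosis")
  expect_equal(nrow(d), 4)
  expect_setequal(round(d$dose_reported, 4), c(0.24, 0.2928, 0.4536, 0.48))
  # empty cohort -> empty design
  expect_equal(nrow(stack_formulations(cohort[0, ], "peak")), 0)
  # n patients -> 4n rows; base dose identical within patient
  co <- sim_cohort(50, -1, 2, seed = 3)
  d2 <- stack_formulations(co, "peak")
  expect_equal(nrow(d2), 200)
  ratio <- d2$dose_reported / d2$factor
  expect_lt(max(tapply(ratio, d2$patient_id, function(x) diff(range(x)))),
            1e-12)
  # missing doses drop the patient with a message
  co$peak_dose_24h[1] <- NA
  expect_message(d3 <- stack_formulations(co, "peak"), "omitted")
  expect_equal(nrow(d3), 196)
})

test_that("fitted slopes obey the rescaling identity beta_f * c_f = beta_base", {
  co <- sim_cohort(3000, -0.8, 2.25, seed = 5)
  fit <- fit_dose_response(stack_formulations(co, "peak"))
  est <- fit$estimates
  b0 <- est$beta[est$formulation == "base"]
  a0 <- est$alpha[est$formulation == "base"]
  expect_equal(est$beta * est$factor, rep(b0, 4), tolerance = 1e-8)
  expect_equal(est$alpha, rep(a0, 4), tolerance = 1e-8)
  # closed-form oracle for the expected slope
  for (f in est$formulation) {
    expect_equal(est$beta[est$formulation == f], expected_slope(b0, f),
                 tolerance = 1e-8)
  }
})

test_that("interaction and per-formulation parameterizations agree", {
  co <- sim_cohort(2000, -0.8, 2.25, seed = 8)
  design <- stack_formulations(co, "peak")
  sep <- fit_dose_response(design, "per_formulation")
  int <- fit_dose_response(design, "interaction")
  expect_equal(int$estimates$beta, sep$estimates$beta, tolerance = 1e-6)
  expect_equal(int$estimates$alpha, sep$estimates$alpha, tolerance = 1e-6)
  expect_equal(int$estimates$or, sep$estimates$or, tolerance = 1e-6)
})

test_that("the random-intercept variant fits and reports its variance", {
  co <- sim_cohort(150, -0.8, 2.25, seed = 12)
  fit <- suppressMessages(suppressWarnings(
    fit_dose_response(stack_formulations(co, "peak"),
                      "interaction_random_intercept")))
  expect_true(is.finite(fit$re_variance))
  expect_true(all(is.finite(fit$estimates$beta)))
  expect_true(all(fit$estimates$or > 0))
})

test_that("a null generator is recovered as OR ~ 1", {
  co <- sim_cohort(5000, qlogis(0.4), 0, seed = 21)
  fit <- fit_dose_response(stack_formulations(co, "peak"))
  for (f in fit$estimates$formulation) {
    b <- fit$estimates$beta[fit$estimates$formulation == f]
    se <- sqrt(fit$vcov[[f]][2, 2])
    expect_lt(abs(b), 3 * se)
  }
})

test_that("degenerate designs raise explicit fit failures", {
  co <- sim_cohort(100, 10, 0, seed = 2) # all deaths
  co$death_28d <- 1L
  expect_error(fit_dose_response(stack_formulations(co, "peak")),
               "single class")
})

test_that("analytic salt-scale odds ratios match the published reductions", {
  # tartrate: OR 9.4 -> 9.4^(1/2) = 3.066, a 67.4% reduction
  or_t <- exp(expected_slope(log(9.4), "tartrate"))
  expect_equal(or_t, 3.066, tolerance = 1e-3)
  expect_equal(percent_or_reduction(or_t, 9.4), 67.4, tolerance = 0.05)
  # hydrochloride: 9.4^(1/1.22) = 6.27, 33.2% lower
  or_h <- exp(expected_slope(log(9.4), "hydrochloride"))
  expect_equal(or_h, 6.27, tolerance = 1e-2)
  expect_equal(percent_or_reduction(or_h, 9.4), 33.2, tolerance = 0.05)
  # bitartrate: 65.2% lower
  expect_equal(percent_or_reduction(9.4^(1 / 1.89), 9.4), 65.2,
               tolerance = 0.05)
  # base is the identity; equal ORs give zero reduction
  expect_equal(expected_slope(1.7, "base"), 1.7)
  expect_equal(percent_or_reduction(2.5, 2.5), 0)
  expect_error(percent_or_reduction(-1, 9.4), "> 0")
})

test_that("predicted mortality follows the closed-form logistic", {
  fit <- fixed_fit(-0.8004057, 2.2504159)
  expect_equal(predict_mortality(fit, 1, "base")$p, 0.810, tolerance = 1e-3)
  # tartrate at reported 1.0 is base at 0.5
  expect_equal(predict_mortality(fit, 1, "tartrate")$p,
               plogis(-0.8004057 + 1.1252080), tolerance = 1e-6)
  expect_equal(predict_mortality(fit, 1, "tartrate")$p, 0.580,
               tolerance = 1e-3)
  expect_equal(predict_mortality(fit, 0, "base")$p, plogis(-0.8004057))
  expect_error(predict_mortality(fit, -0.1, "base"), "invalid")
})

test_that("prediction is equivariant under dose rescaling", {
  co <- sim_cohort(2000, -1.28, 2.87, seed = 9)
  fit <- fit_dose_response(stack_formulations(co, "peak"))
  reg <- ne_formulations()
  for (f in reg$formulation) {
    cf <- reg$factor[reg$formulation == f]
    for (d in c(0, 0.1, 0.25, 0.5, 1)) {
      expect_equal(predict_mortality(fit, d, f)$p,
                   predict_mortality(fit, d / cf, "base")$p,
                   tolerance = 1e-8)
    }
  }
})

test_that("delta-method intervals are inside [0, 1] and contain the estimate", {
  co <- sim_cohort(800, -0.8, 2.25, seed = 14)
  fit <- fit_dose_response(stack_formulations(co, "peak"))
  pr <- predict_mortality(fit, seq(0, 2, by = 0.25), "tartrate")
  expect_true(all(pr$lower >= 0 & pr$upper <= 1))
  expect_true(all(pr$lower <= pr$p & pr$p <= pr$upper))
  expect_true(all(pr$lower < pr$upper))
})

test_that("base/tartrate divergence grows with dose on the rising curve", {
  fit <- fixed_fit(-0.8004057, 2.2504159)
  d <- seq(0.02, 1, by = 0.02)
  gap <- predict_mortality(fit, d, "base")$p -
    predict_mortality(fit, d, "tartrate")$p
  rising <- predict_mortality(fit, d, "base")$p <= 0.85
  expect_true(all(diff(gap[rising]) > 0))
})

test_that("threshold tables render the published grid", {
  # flat fit: identical cells across thresholds
  flat <- fixed_fit(qlogis(0.4), 0)
  tt <- threshold_table(flat)
  expect_true(all(tt$percent == 40))
  # calibrated diagnosis-dose anchors reproduce the printed tartrate column
  att <- anchor_threshold_table(diagnosis_anchors())
  tart <- att[att$formulation == "tartrate", ]
  expect_equal(tart$percent[order(tart$threshold)], c(33, 37, 58))
  base25 <- att$percent[att$formulation == "base" & att$threshold == 0.25]
  expect_equal(base25, 44)
  # fitted-model threshold table agrees with the analytic one when the
  # coefficients are fixed to the calibration
  ab <- calibrate_logistic_from_anchors(diagnosis_anchors())
  tt2 <- threshold_table(fixed_fit(ab["alpha"], ab["beta"]))
  merged <- merge(tt2, att, by = c("threshold", "formulation"))
  expect_equal(merged$percent.x, merged$percent.y)
})

test_that("half-up rounding matches clinical table conventions", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5)), c(1, 2, 3))
  expect_equal(round_half_up(57.5), 58)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(0.445, 2), 0.45)
})

test_that("dose-response curves plot with threshold guides", {
  fit <- fixed_fit(-0.8, 2.25)
  p <- plot_dose_response(fit)
  expect_s3_class(p, "ggplot")
})
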