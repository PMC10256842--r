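# Validation-assay quantification: growth fits, dose-response, cell lengths.

test_that("logistic growth fit recovers noise-free parameters", {
  gc <- simulate_growth_curve(r = 0.6, lag = 2, K = 1, noise_sd = 0)
  fit <- fit_logistic_growth(gc)
  expect_equal(fit$r, 0.6, tolerance = 1e-6)
  expect_equal(fit$K, 1, tolerance = 1e-6)
  expect_equal(fit$lag, 2, tolerance = 0.2)
  expect_false(fit$flat)

  flat <- fit_logistic_growth(tibble::tibble(time = 0:10, od = rep(0.3, 11)))
  expect_equal(flat$r, 0)
  expect_true(is.na(flat$lag))
  expect_true(flat$flat)

  expect_error(
    fit_logistic_growth(tibble::tibble(time = c(0, 1, 1, 2, 3, 4), od = 1:6)),
    class = "metarescue_bad_time"
  )
})

test_that("growth-rate recovery stays accurate under measurement noise", {
  errs <- vapply(1:40, function(s) {
    gc <- simulate_growth_curve(r = 0.6, lag = 2, K = 1, noise_sd = 0.01, seed = s)
    abs(fit_logistic_growth(gc)$r - 0.6)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("percent activity is the linear two-point rescaling", {
  expect_equal(percent_activity(5e5, 5e5, 1e6), 100)
  expect_equal(percent_activity(1e6, 5e5, 1e6), 0)
  expect_equal(percent_activity(7.5e5, 5e5, 1e6), 50)
  expect_error(percent_activity(1, 2, 2), class = "metarescue_undefined_activity")
  # affine re-gaining of the luminometer cancels out
  s <- c(2e5, 4e5, 8e5)
  expect_equal(
    percent_activity(s, 1e5, 1e6),
    percent_activity(3 * s + 50, 3 * 1e5 + 50, 3 * 1e6 + 50)
  )
})

test_that("IC50 fit recovers noise-free curves exactly", {
  dr <- simulate_dose_response(ic50 = 40, hill = 1)
  fit <- fit_ic50(dr)
  expect_equal(fit$ic50, 40, tolerance = 1e-6 * 40)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-5)
  expect_equal(activity_at(fit, fit$ic50), 50, tolerance = 1e-6)

  # a gain change on all signals leaves the IC50 untouched
  dr2 <- dr
  dr2$signal <- dr2$signal * 2
  attr(dr2, "zero_inhibitor_signal") <- attr(dr, "zero_inhibitor_signal") * 2
  attr(dr2, "no_reaction_signal") <- attr(dr, "no_reaction_signal") * 2
  expect_equal(fit_ic50(dr2)$ic50, fit$ic50, tolerance = 1e-8)

  # steeper transition
  dr3 <- simulate_dose_response(ic50 = 25, hill = 2)
  fit3 <- fit_ic50(dr3)
  expect_equal(fit3$ic50, 25, tolerance = 1e-5 * 25)
  expect_equal(fit3$hill, 2, tolerance = 1e-4)

  # curves that never reach 50% cannot yield an IC50
  weak <- simulate_dose_response(ic50 = 1e5, concentrations = c(0, 1, 2, 4, 8))
  expect_error(fit_ic50(weak), class = "metarescue_no_transition")
})

test_that("IC50 estimates stay close to truth seed by seed under noise", {
  span <- 1e6 - 1e5
  est <- vapply(1:40, function(s) {
    dr <- simulate_dose_response(
      ic50 = 40, hill = 1, top_signal = 1e6, floor_signal = 1e5,
      noise_sd = 0.02 * span, seed = s
    )
    fit_ic50(dr)$ic50
  }, numeric(1))
  expect_lt(median(abs(est - 40) / 40), 0.1)
  expect_true(all(est > 25 & est < 60))
})

test_that("Cheng-Prusoff conversion matches its algebra and limits", {
  expect_equal(ki_cheng_prusoff(10, substrate_conc = 5, km = 5), 5)
  expect_equal(ki_cheng_prusoff(10, substrate_conc = 1e-9, km = 1), 10, tolerance = 1e-8)
  # the study's worked numbers: IC50 39.23 uM, [S] 18 uM, Km back-solved
  km <- 18 / (39.23 / 3.54 - 1)
  expect_equal(ki_cheng_prusoff(39.23, 18, km), 3.54, tolerance = 1e-10)
  expect_lt(ki_cheng_prusoff(39.23, 18, 1.7854), 39.23)
  # competitive direction: Ki falls as substrate rises
  kis <- vapply(c(1, 5, 18, 50), function(s) ki_cheng_prusoff(39.23, s, 1.7854), numeric(1))
  expect_true(all(diff(kis) < 0))
  expect_error(ki_cheng_prusoff(-1, 1, 1), "must all be")
})

test_that("cell-length comparison summarizes and tests as designed", {
  set.seed(10)
  a <- rlnorm(300, log(1.06), 0.35)
  cmp_same <- compare_cell_lengths(a, a)
  expect_equal(attr(cmp_same, "p_value"), 0.5, tolerance = 1e-3)
  expect_equal(cmp_same$median[1], cmp_same$median[2])

  # percentile summary equals direct sorted-order computation
  b <- rlnorm(300, log(2.41), 0.35)
  cmp <- compare_cell_lengths(a, b)
  expect_equal(cmp$p25[2], sort(b)[ceiling(0.25 * 300)], tolerance = 0.02)
  expect_equal(
    unlist(cmp[2, c("p10", "p25", "p75", "p90")]),
    quantile(b, c(0.1, 0.25, 0.75, 0.9)),
    ignore_attr = TRUE
  )

  # doubled median at n = 300 is overwhelmingly significant
  cl <- simulate_cell_lengths(median_a = 1.06, median_b = 2.12, n = 300, seed = 2)
  cmp2 <- compare_cell_lengths(
    cl$length[cl$condition == "control"],
    cl$length[cl$condition == "treated"]
  )
  expect_lt(attr(cmp2, "p_value"), 0.001)

  expect_error(compare_cell_lengths(numeric(0), a), "empty")
})

test_that("null cell-length comparisons are calibrated", {
  # under equal medians the one-sided p is approximately uniform: its
  # rejection rate at 5% stays near 5%
  ps <- vapply(1:200, function(s) {
    cl <- simulate_cell_lengths(median_a = 1, median_b = 1, n = 50, seed = s)
    attr(compare_cell_lengths(
      cl$length[cl$condition == "control"],
      cl$length[cl$condition == "treated"]
    ), "p_value")
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
  expect_lt(abs(mean(ps) - 0.5), 0.08)
})

test_that("fitted-object methods expose tidy summaries and plots", {
  gf <- fit_logistic_growth(simulate_growth_curve(r = 0.6, lag = 2, K = 1))
  expect_equal(tidy(gf)$estimate[1], 0.6, tolerance = 1e-6)
  expect_equal(glance(gf)$n, 31)
  fit <- fit_ic50(simulate_dose_response(ic50 = 40))
  expect_setequal(tidy(fit)$term, c("ic50", "hill", "top", "bottom"))
  expect_s3_class(autoplot(gf), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
})
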