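test_that("radius conversion follows the inverse fourth-power law", {
  expect_equal(radius_change_from_resistance(123, 123), 0)
  expect_equal(radius_change_from_resistance(1 / 16, 1), 100)
  expect_equal(radius_change_from_resistance(2.4414, 1), -20, tolerance = 1e-4)
  expect_error(radius_change_from_resistance(-1, 1), "positive")
})

test_that("protocol validation enforces levels and hold durations", {
  expect_error(protocol_spec(levels = 100), "two pressure levels")
  expect_error(protocol_spec(mode = "mr", hold_s = 5), "too short")
  expect_error(protocol_spec(mode = "mr+tgf", hold_s = 100), "too short")
  expect_s3_class(protocol_spec(), "protocol_spec")
})

test_that("a zero step yields zero percent changes", {
  m <- calibrated_model()
  res <- run_pressure_step(m, protocol_spec(mode = "mr",
                                            levels = c(100, 100)))
  expect_equal(res$pct_rbf, c(0, 0), tolerance = 0.1)
  expect_equal(res$pct_radius, c(0, 0), tolerance = 0.1)
  expect_equal(res$pct_rvr, c(0, 0), tolerance = 0.1)
})

test_that("uncontrolled step response is Ohmic; controllers buffer it in order", {
  m <- calibrated_model()
  p_vc <- m$calibration$achieved$p_vc
  res_none <- cached("step_none", run_pressure_step(
    m, protocol_spec(mode = "none", levels = c(100, 148), hold_s = 60)))
  # Ohmic oracle on the clamp waveform (mean = 0.8 x systolic level)
  pred <- 100 * ((0.8 * 148 - p_vc) / (0.8 * 100 - p_vc) - 1)
  expect_equal(res_none$pct_rbf[2], pred, tolerance = 0.05)
  res_mr <- cached("step_mr", run_pressure_step(
    m, protocol_spec(mode = "mr", levels = c(100, 148))))
  res_both <- cached("step_both", run_pressure_step(
    m, protocol_spec(mode = "mr+tgf", levels = c(100, 148))))
  # each added controller further buffers the flow rise
  expect_lt(abs(res_both$pct_rbf[2]), abs(res_mr$pct_rbf[2]))
  expect_lt(abs(res_mr$pct_rbf[2]), abs(res_none$pct_rbf[2]))
  # RVR consistency: reported resistance equals gradient over flow
  expect_equal(res_mr$rvr,
               (res_mr$p_renal - p_vc) / (res_mr$rbf_l_min / 60),
               tolerance = 0.01)
})

test_that("the myogenic band limits the flow rise to 1 + k (p1-p0)/p0", {
  m <- calibrated_model()
  res <- run_pressure_step(m, protocol_spec(mode = "mr", levels = c(80, 180)))
  expect_equal(res$rbf_l_min[2] / res$rbf_l_min[1], 1.625, tolerance = 0.05)
})

test_that("the autoregulatory curve reproduces the radius calibration", {
  m <- calibrated_model()
  cv <- autoregulatory_curve(m, p_grid = seq(60, 200, by = 5))
  expect_equal(cv$pct_radius[cv$p == 80], 0)
  expect_lt(abs(cv$pct_radius[cv$p == 180] - (-20)), 2)
  band <- cv[cv$p >= 80 & cv$p <= 180, ]
  expect_true(all(diff(band$pct_radius) <= 1e-9))
  # c_T is continuous at the breakpoints on a fine grid
  fine <- autoregulatory_curve(m, p_grid = seq(79, 181, by = 0.25))
  expect_lt(max(abs(diff(fine$c_t))), 1e-6)
  expect_error(autoregulatory_curve(m, p_grid = c(50, 100)), "within")
})

test_that("simulated radius decrease at 180 mmHg matches the k calibration", {
  m <- calibrated_model()
  rc <- cached("radius_change", mr_radius_change(m))
  expect_lt(abs(rc$pct_decrease - 20), 2)
})

test_that("deviation scoring applies the published grade bands", {
  m <- calibrated_model()
  res <- cached("step_mr", run_pressure_step(
    m, protocol_spec(mode = "mr", levels = c(100, 148))))
  ref <- data.frame(quantity = "pct_rbf", level = 148,
                    value = res$pct_rbf[2])
  out <- deviation_vs_reference(res, ref)
  expect_equal(out$deviation, 0)
  expect_equal(out$grade, "very good")
  expect_equal(grade_deviation(c(5, 15, 25, 35)),
               c("very good", "good", "fair", "poor"))
  expect_error(deviation_vs_reference(res,
    data.frame(quantity = "pct_gfr", level = 148, value = 1)),
    "unknown quantities")
  expect_error(deviation_vs_reference(res,
    data.frame(quantity = "pct_rbf", level = 999, value = 1)),
    "levels")
})

test_that("clamped and whole-body steps agree at matched renal pressures", {
  m <- calibrated_model()
  wb <- run_pressure_step(m, protocol_spec(mode = "mr", levels = c(100, 120),
                                           clamp = "whole_body",
                                           hold_s = 120))
  # match the clamp waveform to the achieved whole-body systolic and mean
  d1 <- cached("wb_sys_100", {
    d <- drive_to_map(m, 100); measure_steady(d$model, mode = "mr")
  })
  d2 <- cached("wb_sys_120", {
    d <- drive_to_map(m, 120); measure_steady(d$model, mode = "mr")
  })
  pf <- 2 * (d1$p_ar_sys - d1$p_ar) / d1$p_ar_sys
  cl <- run_pressure_step(m, protocol_spec(
    mode = "mr", levels = c(d1$p_ar_sys, d2$p_ar_sys), pulse_frac = pf,
    hold_s = 120))
  expect_lt(abs(cl$pct_rbf[2] - wb$pct_rbf[2]), 5)
})

test_that("a null perturbation leaves the sensitivity analysis at zero", {
  m <- calibrated_model()
  s0 <- sensitivity_analysis(m, "k", perturbations = 0,
                             protocol = protocol_spec(mode = "mr",
                                                      levels = c(100, 148)))
  expect_equal(s0$max_delta, 0)
})
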