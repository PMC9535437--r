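test_that("the delayed GFR signal is a pure transport delay", {
  dt <- 1e-3
  const <- generate_fixture_waveform("constant", duration = 40, dt = dt,
                                     value = 149)
  expect_equal(delayed_gfr(const, 18, dt), 149)
  # a step is seen only delta3 later
  w <- generate_fixture_waveform("step", duration = 40, dt = dt,
                                 from = 149, to = 200, at = 10)
  seen <- vapply(seq(25, 35, by = 0.01), function(t)
    delayed_gfr(w[seq_len(round(t / dt))], 18, dt), 0)
  t_grid <- seq(25, 35, by = 0.01)
  expect_equal(t_grid[min(which(seen > 149))], 10 + 18, tolerance = 0.02)
  # a ramp g(t) = t comes out as t - delta3
  r <- generate_fixture_waveform("ramp", duration = 40, dt = dt, from = 0,
                                 slope = 1)
  expect_equal(delayed_gfr(r, 18, dt), 40 - 18, tolerance = 2 * dt)
})

test_that("TGF activation is the clamped linear map around the operating point", {
  p <- tgf_params()
  expect_equal(tgf_activation(149, p), 0)
  expect_equal(tgf_activation(400, p), 333 - 149)   # saturated: 184
  expect_equal(tgf_activation(100, p), 144 - 149)   # thresholded: -5
  # continuous and non-decreasing across the whole range
  g <- seq(100, 400, by = 0.5)
  a <- tgf_activation(g, p)
  expect_true(all(diff(a) >= 0))
  expect_lt(max(abs(diff(a))), 0.51)
  expect_error(tgf_params(th_gfr = 200), "op_gfr")
})

test_that("the TGF filter relaxes exponentially with asymmetric rates", {
  p <- tgf_params()
  dt <- 1e-3
  relax <- function(a, t_end, dt. = dt, start = 0) {
    n <- round(t_end / dt.)
    dr <- numeric(n)
    dr[1] <- start
    for (i in 2:n) dr[i] <- tgf_update(dr[i - 1], a, dt., p)
    dr
  }
  expect_equal(tgf_update(17, 17, dt, p), 17, tolerance = 1e-12)
  t_grid <- seq(dt, 90, by = dt)
  up <- relax(30, 90)
  expect_lt(max(abs(up - 30 * (1 - exp(-t_grid / p$tau3)))), 0.05)
  # error halves when dt halves
  up2 <- relax(30, 90, dt. = dt / 2)
  t2 <- seq(dt / 2, 90, by = dt / 2)
  e1 <- max(abs(up - 30 * (1 - exp(-t_grid / p$tau3))))
  e2 <- max(abs(up2 - 30 * (1 - exp(-t2 / p$tau3))))
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.4)
  # constriction settles in ~3 tau3; dilation is slower (tau4)
  i95_up <- min(which(up >= 0.95 * 30)) * dt
  dn <- relax(-5, 160)
  i95_dn <- min(which(dn <= 0.95 * -5)) * dt
  expect_equal(i95_up, 3 * p$tau3, tolerance = 0.02)
  expect_equal(i95_dn, 3 * p$tau4, tolerance = 0.02)
})

test_that("the TGF state is bounded by the activation clamp", {
  p <- tgf_params()
  dt <- 0.01
  gfr <- 149 + 400 * (lcg(4000) - 0.3)   # wild but deterministic input
  dr <- 0
  lo <- p$th_gfr - p$op_gfr
  hi <- p$sa_gfr - p$op_gfr
  violations <- 0L
  for (i in seq_along(gfr)) {
    dr <- tgf_update(dr, tgf_activation(gfr[i], p), dt, p)
    if (dr < lo - 1e-9 || dr > hi + 1e-9) violations <- violations + 1L
  }
  expect_identical(violations, 0L)
})

test_that("steady-state TGF output is monotone in the imposed GFR", {
  p <- tgf_params()
  settle <- function(g) {
    a <- tgf_activation(g, p)
    dr <- 0
    for (i in 1:4000) dr <- tgf_update(dr, a, 0.05, p)
    dr
  }
  out <- vapply(seq(120, 360, by = 20), settle, 0)
  expect_true(all(diff(out) >= -1e-9))
  # zero at the operating point
  expect_equal(settle(149), 0)
})
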