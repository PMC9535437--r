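test_that("sensed pressure is the windowed maximum with onset delays", {
  dt <- 1e-3
  const <- generate_fixture_waveform("constant", duration = 3, dt = dt,
                                     value = 100)
  expect_equal(sensed_pressure(const, 0.3, 1.2, t = 3, dt = dt), 100)
  # a pulsatile wave senses its systolic peak once the window spans a beat
  pulse <- generate_fixture_waveform("pulse", duration = 3, dt = dt,
                                     low = 80, high = 120, bpm = 69)
  expect_equal(sensed_pressure(pulse, 0.3, 1.2, t = 3, dt = dt), 120,
               tolerance = 1e-6)
  expect_error(sensed_pressure(pulse[1:100], 0.3, 1.2, t = 0.1, dt = dt),
               "insufficient history")
})

test_that("an upward pressure step is sensed only after delta1", {
  dt <- 1e-3
  at <- 5
  w <- generate_fixture_waveform("step", duration = 10, dt = dt,
                                 from = 100, to = 150, at = at)
  sensed <- vapply(seq(4.5, 6, by = dt), function(t) {
    sensed_pressure(w[seq_len(round(t / dt))], 0.3, 1.2, t, dt)
  }, 0)
  t_grid <- seq(4.5, 6, by = dt)
  first_high <- t_grid[min(which(sensed > 100))]
  expect_equal(first_high, at + 0.3, tolerance = 2 * dt)
  # mirror-image: after a downward step, the old maximum persists for delta2
  w2 <- generate_fixture_waveform("step", duration = 10, dt = dt,
                                  from = 150, to = 100, at = at)
  sensed2 <- vapply(seq(4.5, 7, by = dt), function(t) {
    sensed_pressure(w2[seq_len(round(t / dt))], 0.3, 1.2, t, dt)
  }, 0)
  t_grid2 <- seq(4.5, 7, by = dt)
  last_high <- t_grid2[max(which(sensed2 > 100))]
  expect_equal(last_high, at + 1.2, tolerance = 2 * dt)
})

test_that("target conductance is piecewise, continuous and matches hand values", {
  p <- mr_pars_toy()
  eps <- 1e-9
  # continuity at both breakpoints
  expect_equal(target_conductance(80 - eps, 0, p),
               target_conductance(80 + eps, 0, p), tolerance = 1e-6)
  expect_equal(target_conductance(180 - eps, 0, p),
               target_conductance(180 + eps, 0, p), tolerance = 1e-6)
  # sub-band branch: q0 / (p0 - Pvc)
  expect_equal(target_conductance(70, 0, p), 0.018 / 80)
  # implied target flow at the top of the band: (1 + k) relative to q0
  flow_180 <- target_conductance(180, 0, p) * 180
  expect_equal(flow_180, 0.018 * (1 + 0.5 * 100 / 80))   # 1.625 q0
  expect_error(target_conductance(5, 10, p), "exceed")
})

test_that("afferent target subtracts the downstream network exactly", {
  p <- mr_pars_toy()
  # hand-computed: parallel(400, 300+100) = 200, plus 50 in series
  expect_equal(downstream_resistance(p), 250)
  expect_equal(afferent_target_resistance(1 / 1000, p), 750)
  # round trip: total AR->VC resistance with the afferent at R_T is c_T^-1
  c_t <- 1 / 1400
  r_t <- afferent_target_resistance(c_t, p)
  r_total <- r_t + 1 / (1 / p$r_gl_vr + 1 / (p$r_gl_tu + p$r_tu_vr)) +
    p$r_vr_vc
  expect_equal(r_total, 1 / c_t)
  # downstream negligible: afferent carries the whole target
  p2 <- mr_params(r_base = 1000, r_gl_vr = 1e-9, r_gl_tu = 1e-9,
                  r_tu_vr = 1e-9, r_vr_vc = 1e-9)
  expect_equal(afferent_target_resistance(1e-3, p2), 1000, tolerance = 1e-6)
  # a target below the floor clamps with a warning
  expect_warning(r <- afferent_target_resistance(1 / 260, p), "floor")
  expect_equal(r, 0.05 * 1000)
})

test_that("the myogenic filter relaxes exponentially with asymmetric rates", {
  p <- mr_pars_toy()
  dt <- 1e-3
  relax <- function(r_t, dt, t_end = 30) {
    n <- round(t_end / dt)
    dr <- numeric(n)
    for (i in 2:n)
      dr[i] <- mr_update(dr[i - 1], r_t, p$r_base + dr[i - 1], dt, p)
    dr
  }
  # fixed point: no change when the state already matches the demand
  expect_equal(mr_update(200, 1200, 1400, dt, p), 200, tolerance = 1e-9)
  # upward demand follows 1 - exp(-t/tau1) within O(dt)
  t_grid <- seq(dt, 30, by = dt)
  up <- relax(1500, dt)
  expect_lt(max(abs(up - 500 * (1 - exp(-t_grid / p$tau1)))), 0.5)
  # halving dt halves the discretisation error
  up2 <- relax(1500, dt / 2)
  t2 <- seq(dt / 2, 30, by = dt / 2)
  e1 <- max(abs(up - 500 * (1 - exp(-t_grid / p$tau1))))
  e2 <- max(abs(up2 - 500 * (1 - exp(-t2 / p$tau1))))
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.4)
  # after 5 tau the response is within 1% of the demand
  expect_lt(abs(up[round(5 * p$tau1 / dt)] - 500), 0.01 * 500)
  # constriction (tau1) reaches 90% faster than the mirror dilation (tau2)
  t90_up <- t_grid[min(which(up >= 0.9 * 500))]
  expect_equal(t90_up, p$tau1 * log(10), tolerance = 0.02)
  dn <- numeric(length(t_grid))
  dn[1] <- 500                     # start constricted, demand returns to base
  for (i in 2:length(dn))
    dn[i] <- mr_update(dn[i - 1], p$r_base, p$r_base + dn[i - 1], dt, p)
  t90_dn <- t_grid[min(which(dn <= 0.1 * 500))]
  expect_equal(t90_dn, p$tau2 * log(10), tolerance = 0.02)
  expect_gt(t90_dn, t90_up)
})

test_that("tau convention selects the constriction constant physiologically", {
  p_phys <- mr_pars_toy()
  p_lit <- mr_pars_toy(tau_convention = "literal")
  dt <- 1e-3
  # target above current resistance = constriction demanded
  up_phys <- mr_update(0, 1500, 1000, dt, p_phys)
  up_lit <- mr_update(0, 1500, 1000, dt, p_lit)
  expect_equal(up_phys, dt * 500 / p_phys$tau1)
  expect_equal(up_lit, dt * 500 / p_lit$tau2)   # literal reading flips it
})
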