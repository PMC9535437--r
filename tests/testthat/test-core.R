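test_that("compartment pressure is elastance times stressed volume", {
  expect_equal(compartment_pressure(compartment("X", 300, v0 = 0.1,
                                                volume = 0.1)), 0)
  expect_equal(compartment_pressure(compartment("X", 500, v0 = 0.09,
                                                volume = 0.10)), 5)
  # under-filled compartments are allowed to carry negative pressure
  expect_lt(compartment_pressure(compartment("X", 500, v0 = 0.10,
                                             volume = 0.09)), 0)
  expect_error(compartment("X", v0 = 0.1, volume = 0.1),
               "elastance")
  expect_error(
    compartment_pressure(compartment("H", v0 = 0, volume = 0.1,
                                     elastance_profile = list(ees = 2, ed = 1)),
                         t = 0),
    "period")
})

test_that("systole/diastole pressure ratio follows the elastance profile", {
  prof <- list(ees = 2800, ed = 50)
  co <- compartment("LV", v0 = 0.02, volume = 0.1,
                    elastance_profile = prof)
  period <- 0.87
  tgrid <- seq(0, period, by = 1e-3)
  p <- compartment_pressure(co, tgrid, period)
  expect_equal(max(p) / min(p), prof$ees / prof$ed, tolerance = 1e-3)
})

test_that("connector flow follows Ohm's law and valves block backflow", {
  expect_equal(connector_flow(50, 50, connector("X_Y", "X", "Y", 30)), 0)
  expect_equal(connector_flow(100, 0, connector("X_Y", "X", "Y", 50)), 2)
  vlv <- connector("X_Y", "X", "Y", 50, valve = TRUE)
  expect_equal(connector_flow(5, 20, vlv), 0)
  expect_equal(connector_flow(20, 5, vlv), 0.3)
  expect_error(connector("X_Y", "X", "Y", -1), "resistance")
})

test_that("volume balance sums inflows minus outflows", {
  expect_equal(volume_derivative(0.02, 0.02), 0)
  expect_equal(volume_derivative(0.03, c(0.01, 0.01)), 0.01)
})

test_that("two-compartment relaxation matches the analytic exponential", {
  err_at <- function(dt) {
    m <- two_compartment_model(dt)
    tr <- simulate_model(m, 2)
    tau <- 100 / (500 + 1000)
    p0 <- 500 * 0.1 - 1000 * 0.01
    pd_analytic <- p0 * exp(-tr$time / tau)
    max(abs((tr$P[, "A"] - tr$P[, "B"]) - pd_analytic))
  }
  e1 <- err_at(1e-3)
  e2 <- err_at(5e-4)
  expect_lt(e1, 0.2)            # O(dt) accuracy at 1 ms
  # halving dt halves the error (within 20%): first-order convergence
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.4)
  # equilibrium splits volume by elastance: pressures equalise
  m <- two_compartment_model()
  tr <- simulate_model(m, 2)
  expect_equal(unname(tr$P[nrow(tr$P), "A"]),
               unname(tr$P[nrow(tr$P), "B"]), tolerance = 1e-6)
})

test_that("an isolated compartment does not change state", {
  m <- build_model(list(compartment("A", 500, 0.05, 0.15),
                        compartment("B", 1000, 0.05, 0.06)),
                   list(connector("A_B", "A", "B", 1e12)),
                   heart_rate = 60, require_gestational = FALSE)
  tr <- simulate_model(m, 1)
  expect_equal(unname(tr$V[nrow(tr$V), "A"]), 0.15, tolerance = 1e-9)
})

test_that("closed-loop volume is conserved and valves never run backward", {
  m <- calibrated_model()
  tr <- simulate_model(m, 60, mode = "mr+tgf", record_every = 5L)
  tv <- rowSums(tr$V)
  expect_lt(max(abs(tv - tv[1])), 1e-6)
  valves <- c("LA_LV", "LV_AA", "RA_RV", "RV_PA")
  expect_gte(min(tr$Q[, valves]), 0)
})

test_that("numerical blow-up names the offending compartment", {
  m <- two_compartment_model(dt = 10)   # far beyond the stability limit
  expect_error(simulate_model(m, 2000), "non-finite volume")
})

test_that("R and C++ engines produce the same trajectories", {
  m <- calibrated_model()
  t_cpp <- simulate_model(m, 2, mode = "mr+tgf")
  t_r <- simulate_model(m, 2, mode = "mr+tgf", engine = "r")
  expect_lt(max(abs(t_cpp$P - t_r$P)), 1e-9)
  expect_lt(max(abs(t_cpp$Q - t_r$Q)), 1e-11)
  expect_lt(max(abs(t_cpp$r_aff - t_r$r_aff)), 1e-8)
})
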