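# Shared fixtures, built in code and memoised for the session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) assign(key, expr, envir = .cache)
  .cache[[key]]
}

# canonical calibrated first-trimester model (no simulation on load)
calibrated_model <- function(mode = NULL) {
  m <- cached("model", default_model())
  if (!is.null(mode)) m$autoregulation$mode <- mode
  m
}

baseline_steady <- function() {
  cached("baseline_steady", measure_steady(calibrated_model(), mode = "none"))
}

# minimal two-compartment RC pair with a known analytic relaxation
two_compartment_model <- function(dt = 1e-3, e1 = 500, e2 = 1000, r = 100,
                                  v1 = 0.15, v2 = 0.06, v0 = 0.05) {
  build_model(list(compartment("A", e1, v0, v1),
                   compartment("B", e2, v0, v2)),
              list(connector("A_B", "A", "B", r)),
              heart_rate = 60, dt = dt, require_gestational = FALSE)
}

# small deterministic pseudo-random stream for property loops
lcg <- function(n, seed = 42) {
  out <- numeric(n)
  x <- seed
  for (i in seq_len(n)) {
    x <- (1103515245 * x + 12345) %% 2^31
    out[i] <- x / 2^31
  }
  out
}

mr_pars_toy <- function(...) {
  mr_params(r_base = 1000, r_gl_vr = 400, r_gl_tu = 300, r_tu_vr = 100,
            r_vr_vc = 50, ...)
}
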