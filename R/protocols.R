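#' Declare a perfusion-pressure step protocol
#'
#' A step experiment holds the renal perfusion pressure at each level in
#' turn and records beat-averaged renal outputs at the end of each hold.
#' The default realisation is the renal perfusion-pressure clamp: the
#' isolated renal submodel (AR…VC) is driven by a prescribed pulsatile AR
#' inlet pressure whose systolic value equals the level, mirroring
#' isolated-nephron preparations.  `whole_body` instead volume-loads the
#' closed loop until mean arterial pressure reaches each level.
#'
#' @param mode controller mode (`"none"`, `"mr"`, `"mr+tgf"`)
#' @param levels pressure levels (mmHg), at least two
#' @param hold_s hold duration per level (s); default 120 s, or 210 s when
#'   TGF is active (≥ 5·max(τ) + δ3)
#' @param clamp `"renal"` (perfusion clamp) or `"whole_body"`
#' @param pulse_frac clamp pulse pressure as a fraction of the systolic
#'   level (the sensed maximum equals the level)
#' @param shape `"pulse"` (default) or `"steady"` (non-pulsatile clamp, used
#'   for curve generation)
#' @param baseline_beats beats averaged at the end of each hold
#' @return a `protocol_spec`
#' @export
protocol_spec <- function(mode = "mr", levels = c(100, 123, 148),
                          hold_s = NULL, clamp = c("renal", "whole_body"),
                          pulse_frac = 0.4, shape = c("pulse", "steady"),
                          baseline_beats = 5L) {
  clamp <- match.arg(clamp)
  shape <- match.arg(shape)
  md <- controller_mode(mode)
  if (length(levels) < 2) stop("protocol needs at least two pressure levels")
  if (any(levels <= 0)) stop("pressure levels must be positive")
  if (is.null(hold_s)) hold_s <- if (md$tgf_active) 210 else 120
  # hold must allow the active controllers to settle
  need <- 10
  if (md$mr_active) need <- max(need, 5 * 5.3 + 1.2)
  if (md$tgf_active) need <- max(need, 5 * 33 + 18)
  if (hold_s < need)
    stop("hold_s = ", hold_s, " s too short for the active controllers (need >= ",
         need, " s)")
  structure(list(mode = mode, levels = levels, hold_s = hold_s,
                 clamp = clamp, pulse_frac = pulse_frac, shape = shape,
                 baseline_beats = as.integer(baseline_beats)),
            class = "protocol_spec")
}

#' Percent radius change implied by a resistance change
#'
#' Poiseuille: resistance is inversely proportional to the fourth power of
#' the radius, so \eqn{\Delta r = 100\,((R/R_{ref})^{-1/4} - 1)}.
#'
#' @param r resistance(s) (mmHg·s/L)
#' @param r_ref reference resistance (mmHg·s/L)
#' @return percent change in radius relative to the reference
#' @export
#' @examples
#' radius_change_from_resistance(2.4414, 1)  # -20%
radius_change_from_resistance <- function(r, r_ref) {
  if (any(r <= 0) || r_ref <= 0) stop("resistances must be positive")
  100 * ((r / r_ref)^(-0.25) - 1)
}

#' Extract the isolated renal submodel
#'
#' The AR…VC path on its own: AR and VC become boundary (prescribed
#' pressure) nodes for the perfusion clamp; GL, TU and VR keep their volume
#' dynamics; the five renal connectors and the controllers are retained.
#'
#' @param model a gestational `hemo_model`
#' @return a 5-compartment `hemo_model`
#' @export
renal_submodel <- function(model) {
  keep_c <- c("AR", "GL", "TU", "VR", "VC")
  keep_k <- c("AR_GL", "GL_TU", "GL_VR", "TU_VR", "VR_VC")
  comps <- Filter(function(co) co$name %in% keep_c, model$compartments)
  conns <- Filter(function(co) co$name %in% keep_k, model$connectors)
  build_model(comps, conns, heart_rate = model$heart_rate, dt = model$dt,
              autoregulation = model$autoregulation,
              calibration = model$calibration,
              require_gestational = FALSE)
}

# Clamp inlet waveform for one level over steps s0..s1 (absolute indices):
# diastolic + pulse * (1 - cos)/2, systolic value = level.
clamp_pressure <- function(steps, level, pulse_frac, spb, shape) {
  if (shape == "steady") return(rep(level, length(steps)))
  pp <- pulse_frac * level
  ph <- steps %% spb
  (level - pp) + pp * 0.5 * (1 - cos(2 * pi * ph / spb))
}

baseline_vc_pressure <- function(model) {
  p <- model$calibration$achieved$p_vc
  if (!is.null(p)) return(p)
  measure_steady(model, mode = "none")$p_vc
}

#' Run a perfusion-pressure step protocol
#'
#' Simulates each pressure level in turn (controller state carried across
#' the step), beat-averages the renal outputs over the final
#' `baseline_beats` of each hold, and reports percent changes against the
#' first level.
#'
#' @param model calibrated `hemo_model`
#' @param protocol a [protocol_spec()]
#' @return `step_result` data.frame with one row per level: `level`,
#'   `p_renal` (mean renal arterial pressure), `rbf_l_min`, `gfr_ml_min`,
#'   `r_aff` (afferent resistance), `rvr` (total AR→VC resistance over
#'   RBF), and percent changes `pct_rbf`, `pct_radius`, `pct_rvr`,
#'   `pct_r_aff` against level 1.  Attribute `steady` flags per-level
#'   convergence within the hold.
#' @export
run_pressure_step <- function(model, protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (protocol$clamp == "renal") {
    res <- run_step_clamped(model, protocol)
  } else {
    res <- run_step_whole_body(model, protocol)
  }
  res$pct_rbf <- 100 * (res$rbf_l_min / res$rbf_l_min[1] - 1)
  res$pct_radius <- radius_change_from_resistance(res$r_aff, res$r_aff[1])
  res$pct_rvr <- 100 * (res$rvr / res$rvr[1] - 1)
  res$pct_r_aff <- 100 * (res$r_aff / res$r_aff[1] - 1)
  class(res) <- c("step_result", "data.frame")
  res
}

run_step_clamped <- function(model, protocol) {
  sub <- renal_submodel(model)
  p_vc <- baseline_vc_pressure(model)
  spb <- steps_per_beat(sub)
  beat_s <- spb * sub$dt
  n_beats <- ceiling(protocol$hold_s / beat_s)
  n_steps <- n_beats * spb
  state <- NULL
  step_at <- 0L
  rows <- vector("list", length(protocol$levels))
  steady <- logical(length(protocol$levels))
  for (i in seq_along(protocol$levels)) {
    lev <- protocol$levels[i]
    steps <- step_at + seq_len(n_steps) - 1L
    bnd <- list(names = c("AR", "VC"),
                P = cbind(clamp_pressure(steps, lev, protocol$pulse_frac,
                                         spb, protocol$shape),
                          rep(p_vc, n_steps)))
    tr <- simulate_model(sub, n_steps * sub$dt, mode = protocol$mode,
                         init = state, boundary = bnd)
    state <- tr$final
    step_at <- step_at + n_steps
    rows[[i]] <- summarise_level(tr, lev, rbf_conn = "AR_GL",
                                 window_beats = protocol$baseline_beats)
    steady[i] <- level_steady(tr, "AR_GL")
  }
  out <- do.call(rbind, rows)
  attr(out, "steady") <- steady
  out
}

run_step_whole_body <- function(model, protocol) {
  rows <- vector("list", length(protocol$levels))
  steady <- logical(length(protocol$levels))
  state <- NULL
  spb <- steps_per_beat(model)
  beat_s <- spb * model$dt
  n_beats <- ceiling(protocol$hold_s / beat_s)
  base_v <- vapply(model$compartments, `[[`, 0, "volume")
  v0 <- vapply(model$compartments, `[[`, 0, "v0")
  for (i in seq_along(protocol$levels)) {
    lev <- protocol$levels[i]
    dr <- drive_to_map(model, lev)
    vols <- v0 + dr$factor * (base_v - v0)
    init <- if (is.null(state)) list(volumes = vols) else {
      state$volumes <- vols   # volume step at the level switch
      state
    }
    tr <- simulate_model(dr$model, n_beats * beat_s, mode = protocol$mode,
                         init = init, record_every = 5L)
    state <- tr$final
    rows[[i]] <- summarise_level(tr, lev, rbf_conn = "AD_AR",
                                 window_beats = protocol$baseline_beats)
    steady[i] <- level_steady(tr, "AD_AR")
  }
  out <- do.call(rbind, rows)
  attr(out, "steady") <- steady
  out
}

summarise_level <- function(tr, level, rbf_conn, window_beats) {
  ba <- function(what, name = NULL) beat_average(tr, what, window_beats, name)
  rbf <- ba("flow", rbf_conn)
  p_ar <- ba("pressure", "AR")
  p_vc <- ba("pressure", "VC")
  data.frame(level = level, p_renal = p_ar,
             rbf_l_min = rbf * 60,
             gfr_ml_min = ba("flow", "GL_TU") * 60000,
             r_aff = ba("r_aff"),
             rvr = (p_ar - p_vc) / rbf)
}

level_steady <- function(tr, conn, tol = 5e-3) {
  rpb <- tr$steps_per_beat %/% tr$record_every
  q <- trace_signal(tr, "flow", conn)
  n <- length(q)
  if (n < 2 * rpb) return(FALSE)
  b1 <- mean(q[(n - 2 * rpb + 1):(n - rpb)])
  b2 <- mean(q[(n - rpb + 1):n])
  abs(b2 - b1) / max(abs(b2), 1e-6) < tol
}

#' Steady-state autoregulatory curve
#'
#' The myogenic controller's stationary response over a grid of renal
#' perfusion pressures: target conductance, afferent target resistance,
#' implied renal flow, and percent radius change relative to the maximally
#' dilated reference at 80 mmHg.  Under a steady (non-pulsatile) clamp the
#' first-order myogenic filter converges exactly to its target, so the
#' curve is evaluated in closed form from the calibrated parameters.
#'
#' @param model calibrated `hemo_model`
#' @param p_grid pressure grid (mmHg), within [60, 200]
#' @param reference_p maximal-dilation reference pressure (mmHg)
#' @return data.frame: `p` (mmHg), `c_t` (L/(s·mmHg)), `r_t` (mmHg·s/L),
#'   `flow_l_min` (implied renal flow), `pct_radius`
#' @export
autoregulatory_curve <- function(model, p_grid = seq(60, 200, by = 2),
                                 reference_p = 80) {
  if (any(p_grid < 60 | p_grid > 200))
    stop("pressure grid must lie within [60, 200] mmHg")
  pars <- model_mr_params(model)
  p_vc <- baseline_vc_pressure(model)
  c_t <- target_conductance(p_grid, p_vc, pars)
  r_t <- afferent_target_resistance(c_t, pars)
  r_ref <- afferent_target_resistance(
    target_conductance(reference_p, p_vc, pars), pars)
  data.frame(p = p_grid, c_t = c_t, r_t = r_t,
             flow_l_min = c_t * (p_grid - p_vc) * 60,
             pct_radius = radius_change_from_resistance(r_t, r_ref))
}

#' Simulated afferent radius change between two clamp pressures
#'
#' Runs the MR-only perfusion clamp at a low (maximally dilated reference)
#' and a high systolic pressure and converts the steady-state afferent
#' resistances to a percent radius decrease via the inverse-fourth-power
#' relation.
#'
#' @param model calibrated `hemo_model`
#' @param p_low,p_high systolic clamp levels (mmHg)
#' @param hold_s hold per level (s)
#' @return list: `pct_decrease` (positive magnitude of the radius decrease
#'   at `p_high` vs `p_low`), `r_low`, `r_high` (afferent resistances)
#' @export
mr_radius_change <- function(model, p_low = 80, p_high = 180, hold_s = 60) {
  pr <- protocol_spec(mode = "mr", levels = c(p_low, p_high),
                      hold_s = max(hold_s, 5 * 5.3 + 1.2))
  res <- run_pressure_step(model, pr)
  list(pct_decrease = -res$pct_radius[nrow(res)],
       r_low = res$r_aff[1], r_high = res$r_aff[nrow(res)])
}

#' Deviation of modelled percent changes from reference observations
#'
#' Absolute difference (percentage points) between modelled and
#' user-supplied reference percent changes, graded: < 10 very good, 10–20
#' good, 20–30 fair, ≥ 30 poor.  Reference observations (e.g. rat
#' preparations) are external and never shipped.
#'
#' @param result a `step_result` from [run_pressure_step()]
#' @param reference data.frame with columns `quantity` (one of `pct_rbf`,
#'   `pct_radius`, `pct_rvr`), `level` (matching a protocol level) and
#'   `value` (reference percent change)
#' @return `reference` with appended `model`, `deviation` and `grade`
#' @export
deviation_vs_reference <- function(result, reference) {
  stopifnot(all(c("quantity", "level", "value") %in% names(reference)))
  bad <- setdiff(reference$quantity, c("pct_rbf", "pct_radius", "pct_rvr"))
  if (length(bad))
    stop("unknown quantities in reference: ", paste(bad, collapse = ", "))
  if (!all(reference$level %in% result$level))
    stop("reference levels not present in the step result")
  reference$model <- mapply(function(q, l)
    result[[q]][match(l, result$level)],
    reference$quantity, reference$level)
  reference$deviation <- abs(reference$model - reference$value)
  reference$grade <- grade_deviation(reference$deviation)
  reference
}

#' @rdname deviation_vs_reference
#' @param deviation absolute deviations (percentage points)
#' @export
grade_deviation <- function(deviation) {
  as.character(cut(deviation, breaks = c(-Inf, 10, 20, 30, Inf),
                   labels = c("very good", "good", "fair", "poor"),
                   right = FALSE))
}

#' One-at-a-time sensitivity analysis
#'
#' Re-runs a step protocol with `k` (myogenic slope) or `g_TGF` (TGF gain)
#' perturbed by the given relative amounts and reports, per perturbation,
#' the largest absolute change of any reported percent-change output
#' relative to the unperturbed run.
#'
#' @param model calibrated `hemo_model`
#' @param parameter `"k"` or `"g_tgf"`
#' @param perturbations relative perturbations (e.g. `c(-0.2, -0.1, 0.1, 0.2)`)
#' @param protocol a [protocol_spec()]; defaults to the 100→123→148 clamp in
#'   MR-only mode for `k` and intact mode for `g_tgf`
#' @param outputs percent-change columns compared
#' @return list: `table` (data.frame parameter, perturbation, output, level,
#'   delta), `max_delta` (largest |delta| over everything)
#' @export
sensitivity_analysis <- function(model, parameter = c("k", "g_tgf"),
                                 perturbations = c(-0.2, -0.1, 0.1, 0.2),
                                 protocol = NULL,
                                 outputs = c("pct_rbf", "pct_radius",
                                             "pct_rvr")) {
  parameter <- match.arg(parameter)
  if (is.null(protocol))
    protocol <- protocol_spec(
      mode = if (parameter == "k") "mr" else "mr+tgf",
      levels = c(100, 123, 148))
  perturb <- function(m, rel) {
    if (parameter == "k")
      m$autoregulation$mr$k <- m$autoregulation$mr$k * (1 + rel)
    else
      m$autoregulation$tgf$gain <- m$autoregulation$tgf$gain * (1 + rel)
    m
  }
  base <- run_pressure_step(model, protocol)
  tab <- list()
  for (rel in perturbations) {
    res <- run_pressure_step(perturb(model, rel), protocol)
    for (out in outputs) {
      d <- res[[out]] - base[[out]]
      tab[[length(tab) + 1L]] <- data.frame(
        parameter = parameter, perturbation = rel, output = out,
        level = base$level, delta = d)
    }
  }
  tab <- do.call(rbind, tab)
  list(table = tab, max_delta = max(abs(tab$delta)))
}
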