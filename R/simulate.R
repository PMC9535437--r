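#' Simulate the circulation model
#'
#' Fixed-step explicit Euler integration of the compartment/connector
#' network, with the autoregulation controllers (when active) updated once
#' per step and their output applied with an explicit one-step lag.  The
#' cardiac period is quantised to an integer number of steps
#' (`round((60/HR)/dt)`), so the effective heart rate can differ from the
#' nominal one by a fraction of a percent; [effective_heart_rate()] reports
#' it.
#'
#' @param model a `hemo_model`
#' @param duration simulated time (s); rounded to an integer number of steps
#' @param mode controller mode override (`"none"`, `"mr"`, `"mr+tgf"`);
#'   default: the model's configured mode
#' @param record_every record every n-th step; must divide the steps per beat
#' @param init state carried from a previous run (the `final` element of a
#'   `hemo_trace`), for protocol continuation
#' @param boundary optional perfusion clamp: list with `names` (compartment
#'   names with prescribed pressure) and `P` (matrix, one column per boundary
#'   compartment, one row per step)
#' @param engine `"cpp"` (default) or `"r"` (reference implementation,
#'   identical operation order, used for cross-validation)
#' @return a `hemo_trace`
#' @export
simulate_model <- function(model, duration, mode = NULL, record_every = 1L,
                           init = NULL, boundary = NULL, engine = "cpp") {
  dt <- model$dt
  spb <- steps_per_beat(model)
  record_every <- as.integer(record_every)
  if (spb %% record_every != 0)
    stop("record_every must divide the steps per beat (", spb, ")")
  n_steps <- as.integer(round(duration / dt))
  if (n_steps < 1) stop("duration shorter than one step")

  comps <- model$compartments
  conns <- model$connectors
  n <- length(comps); m <- length(conns)
  cn <- vapply(comps, `[[`, "", "name")
  kn <- vapply(conns, `[[`, "", "name")

  e_const <- vapply(comps, function(co) co$elastance %||% 0, 0)
  v0 <- vapply(comps, `[[`, 0, "v0")
  v_init <- if (!is.null(init)) init$volumes else
    vapply(comps, `[[`, 0, "volume")
  tv <- which(!vapply(comps, function(co) is.null(co$elastance_profile),
                      TRUE))
  period <- spb * dt
  tv_act <- matrix(0, spb, max(1L, length(tv)))
  tv_ees <- numeric(max(1L, length(tv)))
  tv_ed <- numeric(max(1L, length(tv)))
  if (length(tv)) {
    tgrid <- (seq_len(spb) - 1L) * dt
    for (j in seq_along(tv)) {
      pr <- comps[[tv[j]]]$elastance_profile
      tv_act[, j] <- elastance_activation(
        tgrid, period,
        alpha1_frac = pr$alpha1_frac %||% 0.303, n1 = pr$n1 %||% 1.32,
        alpha2_frac = pr$alpha2_frac %||% 0.508, n2 = pr$n2 %||% 21.9,
        shift_frac = pr$shift_frac %||% 0)
      tv_ees[j] <- pr$ees
      tv_ed[j] <- pr$ed
    }
  }

  if (!is.null(boundary)) {
    bnd_idx <- vapply(boundary$names, function(nm) comp_index(model, nm), 0L)
    bnd_p <- boundary$P
    if (!is.matrix(bnd_p) || nrow(bnd_p) != n_steps ||
        ncol(bnd_p) != length(bnd_idx))
      stop("boundary$P must be a ", n_steps, " x ", length(bnd_idx),
           " matrix")
  } else {
    bnd_idx <- integer(0)
    bnd_p <- matrix(0, n_steps, 0)
  }

  src <- vapply(conns, function(co) comp_index(model, co$source), 0L)
  tgt <- vapply(conns, function(co) comp_index(model, co$target), 0L)
  rr <- vapply(conns, `[[`, 0, "resistance")
  vlv <- vapply(conns, `[[`, TRUE, "valve")

  ctrl <- resolve_controller(model, mode = mode, state = init$state)
  phase0 <- as.integer(init$phase %||% 0L)
  if (isTRUE(ctrl$warm)) {
    # quiescent warm-up: pre-fill sensing buffers with the initial state
    e0 <- e_const
    if (length(tv))
      e0[tv] <- tv_ed + tv_act[phase0 + 1L, seq_along(tv)] * (tv_ees - tv_ed)
    p0 <- e0 * (v_init - v0)
    if (length(bnd_idx)) p0[bnd_idx] <- bnd_p[1, ]
    ctrl$p_buf[] <- p0[ctrl$ar_comp + 1L]
    gfr0 <- (p0[comp_index(model, "GL")] - p0[comp_index(model, "TU")]) /
      get_resistance(model, "GL_TU")
    ctrl$gfr_buf[] <- gfr0
  }
  ctrl$warm <- NULL

  core <- if (identical(engine, "cpp")) sim_core_cpp else sim_core_r
  out <- core(e_const, as.integer(tv - 1L), tv_act, tv_ees, tv_ed,
              v0, v_init, as.integer(bnd_idx - 1L), bnd_p,
              as.integer(src - 1L), as.integer(tgt - 1L), rr, vlv,
              dt, n_steps, spb, record_every, phase0, ctrl, cn)

  t_off <- init$time_offset %||% 0
  structure(list(
    time = out$time + t_off,
    P = `colnames<-`(out$P, cn),
    V = `colnames<-`(out$V, cn),
    Q = `colnames<-`(out$Q, kn),
    r_aff = out$r_aff, dr_mr = out$dr_mr, dr_tgf = out$dr_tgf,
    heart_rate = effective_heart_rate(model),
    dt = dt, record_every = record_every, steps_per_beat = spb,
    boundary = boundary$names,
    final = list(volumes = out$V_final, state = c(out$state, warm = FALSE),
                 phase = out$state$phase,
                 time_offset = t_off + n_steps * dt)),
    class = "hemo_trace")
}

# Pure-R reference stepper; mirrors sim_core_cpp operation for operation.
sim_core_r <- function(e_const, tv_idx0, tv_act, tv_ees, tv_ed, v0, v_init,
                       bnd_idx0, bnd_p, src0, tgt0, rr, vlv, dt, n_steps,
                       spb, record_every, phase0, ctrl, cn) {
  n <- length(e_const); m <- length(src0)
  tv <- tv_idx0 + 1L; bnd <- bnd_idx0 + 1L
  src <- src0 + 1L; tgt <- tgt0 + 1L
  v <- v_init
  is_bnd <- rep(FALSE, n); is_bnd[bnd] <- TRUE
  aff <- ctrl$afferent + 1L
  rw <- rr
  mr_on <- ctrl$mr_active; tgf_on <- ctrl$tgf_active
  any_ctrl <- mr_on || tgf_on
  if (any_ctrl) rw[aff] <- ctrl$r_aff
  p_buf <- ctrl$p_buf; g_buf <- ctrl$gfr_buf
  p_head <- ctrl$p_head; g_head <- ctrl$g_head
  pL <- length(p_buf); gL <- length(g_buf)
  dr_mr <- ctrl$dr_mr; dr_tgf <- ctrl$dr_tgf
  r_down <- 1 / (1 / ctrl$r_gl_vr + 1 / (ctrl$r_gl_tu + ctrl$r_tu_vr)) +
    ctrl$r_vr_vc
  r_floor <- ctrl$floor_frac * ctrl$r_base

  n_rec <- (n_steps - 1) %/% record_every + 1
  recP <- matrix(0, n_rec, n); recV <- matrix(0, n_rec, n)
  recQ <- matrix(0, n_rec, m)
  rec_t <- numeric(n_rec); rec_raff <- numeric(n_rec)
  rec_drmr <- numeric(n_rec); rec_drtgf <- numeric(n_rec)
  irec <- 0L

  e <- e_const
  for (s in 0:(n_steps - 1L)) {
    ph <- (phase0 + s) %% spb
    e[] <- e_const
    if (length(tv))
      e[tv] <- tv_ed + tv_act[ph + 1L, seq_along(tv)] * (tv_ees - tv_ed)
    p <- e * (v - v0)
    if (length(bnd)) p[bnd] <- bnd_p[s + 1L, ]
    q <- (p[src] - p[tgt]) / rw
    q[vlv & q < 0] <- 0

    if (s %% record_every == 0L) {
      irec <- irec + 1L
      rec_t[irec] <- s * dt
      recP[irec, ] <- p; recV[irec, ] <- v; recQ[irec, ] <- q
      rec_raff[irec] <- rw[aff]
      rec_drmr[irec] <- dr_mr; rec_drtgf[irec] <- dr_tgf
    }

    if (any_ctrl) {
      p_head <- (p_head + 1L) %% pL
      p_buf[p_head + 1L] <- p[ctrl$ar_comp + 1L]
      g_head <- (g_head + 1L) %% gL
      g_buf[g_head + 1L] <- q[ctrl$gfr_conn + 1L]
      if (mr_on) {
        ages <- ctrl$a1:ctrl$a2
        pmaxv <- max(p_buf[((p_head - ages) %% pL) + 1L])
        p_vc <- p[ctrl$vc_comp + 1L]
        c_t <- if (pmaxv < ctrl$p0) {
          ctrl$q0 / (ctrl$p0 - p_vc)
        } else if (pmaxv <= ctrl$p1) {
          ctrl$q0 * (1 + ctrl$k * (pmaxv - ctrl$p0) / ctrl$p0) /
            (pmaxv - p_vc)
        } else {
          ctrl$q0 * (1 + ctrl$k * (ctrl$p1 - ctrl$p0) / ctrl$p0) /
            (ctrl$p1 - p_vc)
        }
        r_t <- max(1 / c_t - r_down, r_floor)
        d_r <- r_t - ctrl$r_base
        constrict <- if (ctrl$tau_literal) rw[aff] > r_t else r_t > rw[aff]
        tau <- if (constrict) ctrl$tau1 else ctrl$tau2
        dr_mr <- dr_mr + dt * (d_r - dr_mr) / tau
      }
      if (tgf_on) {
        gd <- if (ctrl$gfr_avg_steps > 0) {
          ages <- ctrl$a3:(ctrl$a3 + ctrl$gfr_avg_steps - 1L)
          mean(g_buf[((g_head - ages) %% gL) + 1L]) * 60000
        } else g_buf[((g_head - ctrl$a3) %% gL) + 1L] * 60000
        a_tgf <- min(max(gd, ctrl$th_gfr), ctrl$sa_gfr) - ctrl$op_gfr
        tau <- if (a_tgf > 0) ctrl$tau3 else ctrl$tau4
        dr_tgf <- dr_tgf + dt * (a_tgf - dr_tgf) / tau
      }
      r_new <- ctrl$r_base +
        (if (mr_on) ctrl$g_mr * dr_mr else 0) +
        (if (tgf_on) ctrl$g_tgf * dr_tgf else 0)
      rw[aff] <- max(r_new, r_floor)
    }

    dv <- numeric(n)
    for (j in seq_len(m)) {
      dv[tgt[j]] <- dv[tgt[j]] + q[j]
      dv[src[j]] <- dv[src[j]] - q[j]
    }
    dv[is_bnd] <- 0
    v <- v + dt * dv
    if (any(!is.finite(v)))
      stop("numerical failure: non-finite volume in compartment '",
           cn[which(!is.finite(v))[1]], "' at t = ", s * dt, " s")
  }
  list(time = rec_t, P = recP, V = recV, Q = recQ, r_aff = rec_raff,
       dr_mr = rec_drmr, dr_tgf = rec_drtgf, V_final = v,
       state = list(dr_mr = dr_mr, dr_tgf = dr_tgf, p_buf = p_buf,
                    gfr_buf = g_buf, p_head = p_head, g_head = g_head,
                    r_aff = rw[aff], phase = (phase0 + n_steps) %% spb))
}

#' Steps per cardiac beat and effective heart rate
#'
#' @param model a `hemo_model`
#' @return `steps_per_beat()`: integer; `effective_heart_rate()`: bpm after
#'   period quantisation to the step grid
#' @export
steps_per_beat <- function(model) {
  as.integer(round((60 / model$heart_rate) / model$dt))
}

#' @rdname steps_per_beat
#' @export
effective_heart_rate <- function(model) {
  60 / (steps_per_beat(model) * model$dt)
}

#' @export
print.hemo_trace <- function(x, ...) {
  cat("<hemo_trace> ", length(x$time), " samples, ",
      format(max(x$time) - min(x$time) + x$dt * x$record_every, digits = 4),
      " s at dt ", x$dt * 1000, " ms (recorded every ", x$record_every,
      " step(s))\n", sep = "")
  invisible(x)
}

#' Extract a signal from a trace
#'
#' @param trace a `hemo_trace`
#' @param what one of `"pressure"`, `"volume"`, `"flow"`, `"r_aff"`,
#'   `"dr_mr"`, `"dr_tgf"`, `"total_volume"`
#' @param name compartment/connector name (for pressure, volume, flow)
#' @return numeric vector aligned with `trace$time`
#' @export
trace_signal <- function(trace,
                         what = c("pressure", "volume", "flow", "r_aff",
                                  "dr_mr", "dr_tgf", "total_volume"),
                         name = NULL) {
  what <- match.arg(what)
  switch(what,
    pressure = trace$P[, name],
    volume = trace$V[, name],
    flow = trace$Q[, name],
    r_aff = trace$r_aff,
    dr_mr = trace$dr_mr,
    dr_tgf = trace$dr_tgf,
    total_volume = rowSums(trace$V))
}

#' Beat-averaged value of a signal
#'
#' Time-average over an integer number of final cardiac cycles.
#'
#' @param trace a `hemo_trace`
#' @param signal numeric vector aligned with the trace (e.g. from
#'   [trace_signal()]), or a character `what` passed to [trace_signal()]
#' @param window_beats number of final beats to average over
#' @param name forwarded to [trace_signal()] when `signal` is a string
#' @return mean value
#' @export
beat_average <- function(trace, signal, window_beats = 5L, name = NULL) {
  if (is.character(signal))
    signal <- trace_signal(trace, signal, name = name)
  rpb <- trace$steps_per_beat %/% trace$record_every
  need <- rpb * window_beats
  if (need > length(signal))
    stop("window of ", window_beats, " beats (", need,
         " samples) longer than trace (", length(signal), " samples)")
  mean(signal[(length(signal) - need + 1L):length(signal)])
}

#' Run to periodic steady state
#'
#' Integrates beat by beat until the relative change of every beat-averaged
#' compartment pressure and connector flow between consecutive beats stays
#' below `tol` for `consecutive` beats, then records `keep_beats` further
#' beats and returns them as the trace.
#'
#' @param model a `hemo_model`
#' @param mode controller mode override
#' @param max_beats give up (with `converged = FALSE`) after this many beats
#' @param tol relative beat-to-beat tolerance (default 0.1%)
#' @param consecutive beats that must consecutively satisfy `tol`
#' @param keep_beats beats recorded in the returned trace
#' @param init carried state (as in [simulate_model()])
#' @param boundary_fun optional `function(step_from, step_to)` returning the
#'   boundary-pressure matrix rows for those absolute steps plus the boundary
#'   compartment names (list `names`, `P`), for perfusion-clamp runs
#' @param min_beats do not test convergence before this many beats
#' @return a `hemo_trace` with attributes `converged` (logical) and
#'   `beats_run`
#' @export
run_to_steady_state <- function(model, mode = NULL, max_beats = 300L,
                                tol = 1e-3, consecutive = 3L, keep_beats = 6L,
                                init = NULL, boundary_fun = NULL,
                                min_beats = 5L) {
  spb <- steps_per_beat(model)
  beat_s <- spb * model$dt
  prev <- NULL
  streak <- 0L
  converged <- FALSE
  beats <- 0L
  state <- init
  step_at <- as.integer(round((init$time_offset %||% 0) / model$dt))
  while (beats < max_beats) {
    bnd <- if (!is.null(boundary_fun))
      boundary_fun(step_at, step_at + spb - 1L)
    tr <- simulate_model(model, beat_s, mode = mode, init = state,
                         boundary = bnd)
    state <- tr$final
    step_at <- step_at + spb
    beats <- beats + 1L
    cur <- c(colMeans(tr$P), colMeans(tr$Q))
    if (!is.null(prev) && beats >= min_beats) {
      relchg <- abs(cur - prev) /
        pmax(abs(cur), c(rep(0.1, ncol(tr$P)), rep(1e-6, ncol(tr$Q))))
      streak <- if (all(relchg < tol)) streak + 1L else 0L
      if (streak >= consecutive) { converged <- TRUE; break }
    }
    prev <- cur
  }
  bnd <- if (!is.null(boundary_fun))
    boundary_fun(step_at, step_at + keep_beats * spb - 1L)
  out <- simulate_model(model, keep_beats * beat_s, mode = mode,
                        init = state, boundary = bnd)
  attr(out, "converged") <- converged
  attr(out, "beats_run") <- beats + keep_beats
  out
}

#' Export a trace to CSV
#'
#' Wide format: `time_s`, one pressure and one volume column per compartment
#' and one flow column per connector (`compartments*2 + connectors + 1`
#' columns).  Tidy format: `time_s, variable, value, units`.  Output is
#' deterministic: identical traces produce byte-identical files.
#'
#' @param trace a `hemo_trace`
#' @param path output file
#' @param format `"wide"` or `"tidy"`
#' @return `path`, invisibly
#' @export
export_trace <- function(trace, path, format = c("wide", "tidy")) {
  format <- match.arg(format)
  cn <- colnames(trace$P); kn <- colnames(trace$Q)
  if (format == "wide") {
    df <- data.frame(time_s = trace$time)
    for (nm in cn) df[[paste0("P_", nm, "_mmHg")]] <- trace$P[, nm]
    for (nm in cn) df[[paste0("V_", nm, "_L")]] <- trace$V[, nm]
    for (nm in kn) df[[paste0("Q_", nm, "_L_s")]] <- trace$Q[, nm]
  } else {
    nt <- length(trace$time)
    df <- data.frame(
      time_s = c(rep(trace$time, times = 2L * length(cn) + length(kn))),
      variable = c(rep(paste0("P_", cn), each = nt),
                   rep(paste0("V_", cn), each = nt),
                   rep(paste0("Q_", kn), each = nt)),
      value = c(as.vector(trace$P), as.vector(trace$V), as.vector(trace$Q)),
      units = c(rep("mmHg", nt * length(cn)), rep("L", nt * length(cn)),
                rep("L/s", nt * length(kn))))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read back a wide-format trace CSV
#' @param path file written by [export_trace()] with `format = "wide"`
#' @return list with `time`, `P`, `V`, `Q` matrices
#' @export
read_trace <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  pick <- function(prefix, suffix) {
    cols <- grep(paste0("^", prefix, "_.*_", suffix, "$"), names(df),
                 value = TRUE)
    mat <- as.matrix(df[cols])
    colnames(mat) <- sub(paste0("_", suffix, "$"), "",
                         sub(paste0("^", prefix, "_"), "", cols))
    mat
  }
  list(time = df$time_s, P = pick("P", "mmHg"), V = pick("V", "L"),
       Q = pick("Q", "L_s"))
}
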