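#' @name topology
#' @title First-trimester circulation topology constants
#' @description The 19 named compartments of the gestational circulation and
#'   the six resistances of the renal branch.  The kidney is a lumped single
#'   nephron: descending aorta (AD) feeds the renal artery (AR); the afferent
#'   arteriole (connector `AR_GL`) feeds the glomerulus (GL), which drains in
#'   parallel through the efferent arteriole (`GL_VR`) and through filtration
#'   into the tubule (`GL_TU` then `TU_VR`); the renal vein (VR) drains to the
#'   caval vein (VC, `VR_VC`).
#' @keywords internal
NULL

.compartment_names <- c("PV", "LA", "LV", "AA", "AD", "UB", "LB", "AR", "GL",
                        "TU", "VR", "UA", "SA", "PL", "UV", "VC", "RA", "RV",
                        "PA")
.renal_connectors <- c("AD_AR", "AR_GL", "GL_VR", "GL_TU", "TU_VR", "VR_VC")
.heart_valves <- c("LA_LV", "LV_AA", "RA_RV", "RV_PA")

#' Build a compartment
#'
#' An elastic volume-holding node.  Pressure follows
#' \eqn{P(t) = E(t)\,(V(t) - V_0)}: elastance times stressed volume.
#'
#' @param name identifier
#' @param elastance constant elastance (mmHg/L); ignored when
#'   `elastance_profile` is given
#' @param v0 unstressed volume (L)
#' @param volume current/starting volume (L)
#' @param elastance_profile optional list (`ees`, `ed`, activation shape) for
#'   a time-varying-elastance heart chamber; see [chamber_elastance()]
#' @return a `compartment` list
#' @export
compartment <- function(name, elastance = NULL, v0, volume,
                        elastance_profile = NULL) {
  if (is.null(elastance) && is.null(elastance_profile))
    stop("compartment '", name, "': elastance or elastance_profile required")
  if (!is.null(elastance) && elastance <= 0)
    stop("compartment '", name, "': elastance must be > 0")
  if (!is.null(elastance_profile) &&
      (is.null(elastance_profile$ees) || is.null(elastance_profile$ed) ||
       elastance_profile$ed <= 0 || elastance_profile$ees < elastance_profile$ed))
    stop("compartment '", name, "': invalid elastance profile")
  if (v0 < 0 || volume < 0)
    stop("compartment '", name, "': volumes must be non-negative")
  structure(list(name = name, elastance = elastance, v0 = v0, volume = volume,
                 elastance_profile = elastance_profile),
            class = "compartment")
}

#' Build a connector
#'
#' A volumeless resistive edge between two compartments.  Valves have
#' infinite backward resistance: backward flow is exactly zero.
#'
#' @param name identifier, conventionally `SOURCE_TARGET`
#' @param source,target compartment names
#' @param resistance mmHg·s/L, must be positive
#' @param valve logical; one-way flow
#' @return a `connector` list
#' @export
connector <- function(name, source, target, resistance, valve = FALSE) {
  if (!is.numeric(resistance) || resistance <= 0)
    stop("connector '", name, "': resistance must be > 0")
  structure(list(name = name, source = source, target = target,
                 resistance = resistance, valve = isTRUE(valve)),
            class = "connector")
}

#' Compartment pressure
#'
#' \eqn{P(t) = E(t)\,(V - V_0)}.  Negative pressure is allowed and signals an
#' under-filled compartment (no collapse model).
#'
#' @param comp a [compartment()]
#' @param t time (s), used only for time-varying elastance chambers
#' @param period cardiac cycle length (s); required for time-varying chambers
#' @return pressure (mmHg)
#' @export
#' @examples
#' compartment_pressure(compartment("AA", elastance = 500, v0 = 0.09,
#'                                  volume = 0.10))  # 5 mmHg
compartment_pressure <- function(comp, t = 0, period = NULL) {
  if (!is.null(comp$elastance_profile)) {
    if (is.null(period))
      stop("compartment '", comp$name,
           "': period required for a time-varying elastance profile")
    e <- chamber_elastance(t, comp$elastance_profile, period)
  } else if (!is.null(comp$elastance)) {
    e <- comp$elastance
  } else {
    stop("compartment '", comp$name, "': unknown elastance profile")
  }
  e * (comp$volume - comp$v0)
}

#' Flow through a connector
#'
#' \eqn{q = (P_1 - P_2)/R}; a valve returns exactly zero when the gradient
#' is adverse.
#'
#' @param p_source,p_target pressures (mmHg)
#' @param conn a [connector()]
#' @return flow (L/s)
#' @export
#' @examples
#' connector_flow(100, 0, connector("X_Y", "X", "Y", 50))  # 2 L/s
connector_flow <- function(p_source, p_target, conn) {
  if (conn$resistance <= 0)
    stop("connector '", conn$name, "': resistance must be > 0")
  q <- (p_source - p_target) / conn$resistance
  if (conn$valve) q <- pmax(q, 0)
  q
}

#' Volume balance of a compartment
#'
#' \eqn{dV/dt = \sum q_{in} - \sum q_{out}}.
#'
#' @param inflows,outflows numeric vectors of flows (L/s)
#' @return dV/dt (L/s)
#' @export
volume_derivative <- function(inflows, outflows) {
  sum(inflows) - sum(outflows)
}

#' Assemble and validate a circulation model
#'
#' Validates the closed-loop network: every connector endpoint must exist,
#' every compartment must be reachable (single connected loop), and — when
#' the model claims the full gestational topology — all 19 named
#' compartments, the six renal resistances and the four heart valves must be
#' present.
#'
#' @param compartments list of [compartment()]s
#' @param connectors list of [connector()]s
#' @param heart_rate bpm
#' @param dt integration step (s)
#' @param autoregulation autoregulation parameter block (see
#'   [default_autoregulation()]); `NULL` gives mode "none"
#' @param calibration optional calibration-target block
#' @param require_gestational if `TRUE` (default for 19-compartment models)
#'   enforce the full first-trimester topology
#' @return a `hemo_model` object
#' @export
build_model <- function(compartments, connectors, heart_rate = 69, dt = 1e-3,
                        autoregulation = NULL, calibration = NULL,
                        require_gestational = NULL) {
  cn <- vapply(compartments, `[[`, "", "name")
  if (anyDuplicated(cn)) stop("duplicate compartment names")
  kn <- vapply(connectors, `[[`, "", "name")
  if (anyDuplicated(kn)) stop("duplicate connector names")
  for (co in connectors) {
    if (!(co$source %in% cn))
      stop("connector '", co$name, "': unknown source compartment '",
           co$source, "'")
    if (!(co$target %in% cn))
      stop("connector '", co$name, "': unknown target compartment '",
           co$target, "'")
  }
  # connectivity: undirected reachability from the first compartment
  adj <- lapply(seq_along(cn), function(i) integer(0))
  names(adj) <- cn
  for (co in connectors) {
    adj[[co$source]] <- c(adj[[co$source]], match(co$target, cn))
    adj[[co$target]] <- c(adj[[co$target]], match(co$source, cn))
  }
  seen <- logical(length(cn)); stack <- 1L; seen[1] <- TRUE
  while (length(stack)) {
    i <- stack[[1]]; stack <- stack[-1]
    for (j in adj[[i]]) if (!seen[j]) { seen[j] <- TRUE; stack <- c(stack, j) }
  }
  if (!all(seen))
    stop("network not connected: unreachable compartment(s) ",
         paste(cn[!seen], collapse = ", "))

  if (is.null(require_gestational))
    require_gestational <- length(compartments) >= 19
  if (require_gestational) {
    missing_c <- setdiff(.compartment_names, cn)
    if (length(missing_c))
      stop("missing compartment(s): ", paste(missing_c, collapse = ", "))
    missing_k <- setdiff(.renal_connectors, kn)
    if (length(missing_k))
      stop("missing renal connector(s): ", paste(missing_k, collapse = ", "))
    for (v in .heart_valves) {
      i <- match(v, kn)
      if (is.na(i)) stop("missing heart valve connector '", v, "'")
      if (!connectors[[i]]$valve)
        stop("connector '", v, "' must be a valve")
    }
  }
  if (dt <= 0) stop("dt must be > 0")
  if (heart_rate <= 0) stop("heart_rate must be > 0")
  if (is.null(autoregulation)) autoregulation <- default_autoregulation()
  structure(list(compartments = compartments, connectors = connectors,
                 heart_rate = heart_rate, dt = dt,
                 autoregulation = autoregulation,
                 calibration = calibration,
                 gestational = require_gestational),
            class = "hemo_model")
}

#' @export
print.hemo_model <- function(x, ...) {
  cat("<hemo_model> ", length(x$compartments), " compartments, ",
      length(x$connectors), " connectors\n", sep = "")
  cat("  heart rate ", x$heart_rate, " bpm, dt ", x$dt * 1000, " ms, mode '",
      x$autoregulation$mode, "'\n", sep = "")
  cat("  total volume ", format(total_volume(x), digits = 4), " L\n", sep = "")
  invisible(x)
}

#' Total blood volume held in the model's compartments
#' @param model a `hemo_model`
#' @return volume (L)
#' @export
total_volume <- function(model) {
  sum(vapply(model$compartments, `[[`, 0, "volume"))
}

comp_index <- function(model, name) {
  i <- match(name, vapply(model$compartments, `[[`, "", "name"))
  if (is.na(i)) stop("unknown compartment '", name, "'")
  i
}

conn_index <- function(model, name) {
  i <- match(name, vapply(model$connectors, `[[`, "", "name"))
  if (is.na(i)) stop("unknown connector '", name, "'")
  i
}

#' Get or set a connector resistance
#' @param model a `hemo_model`
#' @param name connector name
#' @param value new resistance (mmHg·s/L)
#' @return the resistance, or the modified model
#' @export
get_resistance <- function(model, name) {
  model$connectors[[conn_index(model, name)]]$resistance
}

#' @rdname get_resistance
#' @export
set_resistance <- function(model, name, value) {
  if (value <= 0) stop("connector '", name, "': resistance must be > 0")
  model$connectors[[conn_index(model, name)]]$resistance <- value
  model
}

#' Scale the stressed volume of every compartment
#'
#' Multiplies every starting stressed volume `V - V0` by `factor`, leaving
#' unstressed volumes untouched.  This is the whole-body perturbation used to
#' drive mean arterial pressure up or down (volume loading/unloading).
#'
#' @param model a `hemo_model`
#' @param factor positive scale
#' @return modified model
#' @export
scale_stressed_volume <- function(model, factor) {
  stopifnot(factor > 0)
  model$compartments <- lapply(model$compartments, function(co) {
    co$volume <- co$v0 + factor * (co$volume - co$v0)
    co
  })
  model
}
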