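#' Load and validate a model configuration
#'
#' Configurations are JSON with explicit unit suffixes in the field names
#' (`elastance_mmHg_L`, `resistance_mmHg_s_L`, ...).  Validation checks the
#' schema field by field; a missing `autoregulation` block defaults the
#' controllers to mode `"none"` with a message.
#'
#' @param path JSON file
#' @return validated configuration list
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  validate_config_list(cfg)
}

#' @rdname validate_config
#' @param cfg configuration list (already parsed)
#' @export
validate_config_list <- function(cfg) {
  need <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  need(is.numeric(cfg$heart_rate_bpm) && cfg$heart_rate_bpm > 0,
       "heart_rate_bpm must be a positive number")
  cfg$dt_s <- cfg$dt_s %||% 1e-3
  need(is.numeric(cfg$dt_s) && cfg$dt_s > 0, "dt_s must be > 0")
  need(length(cfg$compartments) > 0, "compartments block missing")
  need(length(cfg$connectors) > 0, "connectors block missing")
  for (co in cfg$compartments) {
    need(!is.null(co$name), "compartment without a name")
    has_e <- !is.null(co$elastance_mmHg_L)
    has_p <- !is.null(co$elastance_profile)
    need(has_e || has_p,
         paste0("compartment '", co$name,
                "': elastance_mmHg_L or elastance_profile required"))
    if (has_e) need(co$elastance_mmHg_L > 0,
                    paste0("compartment '", co$name,
                           "': elastance must be > 0"))
    if (has_p) {
      pr <- co$elastance_profile
      need(!is.null(pr$ees_mmHg_L) && !is.null(pr$ed_mmHg_L) &&
             pr$ed_mmHg_L > 0 && pr$ees_mmHg_L >= pr$ed_mmHg_L,
           paste0("compartment '", co$name, "': invalid elastance_profile"))
    }
    need(!is.null(co$unstressed_volume_L) && co$unstressed_volume_L >= 0,
         paste0("compartment '", co$name, "': unstressed_volume_L >= 0"))
    need(!is.null(co$volume_L) && co$volume_L >= 0,
         paste0("compartment '", co$name, "': volume_L >= 0"))
  }
  for (co in cfg$connectors) {
    need(!is.null(co$name), "connector without a name")
    need(!is.null(co$source) && !is.null(co$target),
         paste0("connector '", co$name, "': source and target required"))
    need(is.numeric(co$resistance_mmHg_s_L) && co$resistance_mmHg_s_L > 0,
         paste0("connector '", co$name, "': resistance_mmHg_s_L must be > 0"))
  }
  if (is.null(cfg$autoregulation)) {
    message("config: no autoregulation block; controllers default to mode 'none'")
    cfg$autoregulation <- default_autoregulation()
  } else {
    au <- cfg$autoregulation
    need(au$mode %in% c("none", "mr", "mr+tgf", "tgf"),
         "autoregulation$mode must be none|mr|mr+tgf|tgf")
    defaults <- default_autoregulation(au$mode)
    au$mr <- modifyList(defaults$mr, au$mr %||% list())
    au$tgf <- modifyList(defaults$tgf, au$tgf %||% list())
    need(au$mr$p0 < au$mr$p1, "mr: p0 < p1 required")
    need(au$mr$delta1 < au$mr$delta2, "mr: delta1 < delta2 required")
    need(au$tgf$th_gfr < au$tgf$op_gfr && au$tgf$op_gfr < au$tgf$sa_gfr,
         "tgf: th_gfr < op_gfr < sa_gfr required")
    cfg$autoregulation <- au
  }
  cfg
}

#' Build a model from a configuration
#'
#' @param cfg configuration list (from [validate_config()]) or a path to a
#'   JSON config
#' @return a `hemo_model`
#' @export
model_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  comps <- lapply(cfg$compartments, function(co) {
    prof <- NULL
    if (!is.null(co$elastance_profile)) {
      pr <- co$elastance_profile
      prof <- list(ees = pr$ees_mmHg_L, ed = pr$ed_mmHg_L,
                   alpha1_frac = pr$alpha1_frac %||% 0.303,
                   n1 = pr$n1 %||% 1.32,
                   alpha2_frac = pr$alpha2_frac %||% 0.508,
                   n2 = pr$n2 %||% 21.9,
                   shift_frac = pr$shift_frac %||% 0)
    }
    compartment(co$name, elastance = co$elastance_mmHg_L,
                v0 = co$unstressed_volume_L, volume = co$volume_L,
                elastance_profile = prof)
  })
  conns <- lapply(cfg$connectors, function(co)
    connector(co$name, co$source, co$target, co$resistance_mmHg_s_L,
              valve = isTRUE(co$valve)))
  build_model(comps, conns, heart_rate = cfg$heart_rate_bpm, dt = cfg$dt_s,
              autoregulation = cfg$autoregulation,
              calibration = cfg$calibration)
}

#' Serialise a model back to a configuration list
#'
#' Round-trips with [model_from_config()]: `write_config(config_from_model(m))`
#' reloaded is semantically identical to `m`.
#'
#' @param model a `hemo_model`
#' @return configuration list
#' @export
config_from_model <- function(model) {
  comps <- lapply(model$compartments, function(co) {
    out <- list(name = co$name)
    if (!is.null(co$elastance_profile)) {
      pr <- co$elastance_profile
      out$elastance_profile <- list(
        ees_mmHg_L = pr$ees, ed_mmHg_L = pr$ed,
        alpha1_frac = pr$alpha1_frac, n1 = pr$n1,
        alpha2_frac = pr$alpha2_frac, n2 = pr$n2,
        shift_frac = pr$shift_frac)
    } else {
      out$elastance_mmHg_L <- co$elastance
    }
    out$unstressed_volume_L <- co$v0
    out$volume_L <- co$volume
    out
  })
  conns <- lapply(model$connectors, function(co)
    list(name = co$name, source = co$source, target = co$target,
         resistance_mmHg_s_L = co$resistance, valve = co$valve))
  list(heart_rate_bpm = model$heart_rate, dt_s = model$dt,
       compartments = comps, connectors = conns,
       autoregulation = model$autoregulation,
       calibration = model$calibration)
}

#' Write a configuration to JSON
#' @param cfg configuration list
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Path to a shipped configuration
#'
#' `"first_trimester"` is the canonical calibrated first-trimester parameter
#' set (regenerated by [calibrate_model()] from the non-pregnant base);
#' `"nonpregnant_base"` is the pre-calibration, non-pregnant starting point
#' with the gestational volume multipliers recorded but not yet applied.
#'
#' @param which configuration name
#' @return file path
#' @export
default_config_path <- function(which = c("first_trimester",
                                          "nonpregnant_base")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, ".json"), package = "renautoreg",
              mustWork = TRUE)
}

#' Load the canonical calibrated first-trimester model
#' @param mode optional controller mode override
#' @return a `hemo_model`
#' @export
default_model <- function(mode = NULL) {
  m <- model_from_config(default_config_path("first_trimester"))
  if (!is.null(mode)) m$autoregulation$mode <- mode
  m
}

#' Apply first-trimester gestational volume adjustments
#'
#' Scales compartment volumes by the multipliers recorded in the config's
#' `gestation` block: heart chambers, renal and uterine compartments grow
#' (both stressed and unstressed volume), and the global plasma-volume
#' multiplier scales every stressed volume.
#'
#' @param cfg configuration list with a `gestation` block
#' @return configuration with volumes adjusted and `gestation$applied = TRUE`
#' @export
apply_gestation <- function(cfg) {
  g <- cfg$gestation
  if (is.null(g)) stop("config has no gestation block")
  if (isTRUE(g$applied)) {
    message("gestation multipliers already applied; config unchanged")
    return(cfg)
  }
  mult <- g$multipliers
  groups <- list(heart = c("LA", "LV", "RA", "RV"),
                 renal = c("AR", "GL", "TU", "VR"),
                 uterine = c("UA", "SA", "PL", "UV"))
  cfg$compartments <- lapply(cfg$compartments, function(co) {
    for (grp in names(groups)) {
      if (co$name %in% groups[[grp]] && !is.null(mult[[grp]])) {
        co$unstressed_volume_L <- co$unstressed_volume_L * mult[[grp]]
        co$volume_L <- co$volume_L * mult[[grp]]
      }
    }
    if (!is.null(mult$plasma_stressed)) {
      co$volume_L <- co$unstressed_volume_L +
        mult$plasma_stressed * (co$volume_L - co$unstressed_volume_L)
    }
    co
  })
  cfg$gestation$applied <- TRUE
  cfg
}
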