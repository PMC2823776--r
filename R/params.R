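#' Default model parameters
#'
#' Returns the full parameter set of the model with its calibrated default
#' values.  Constants printed in the published rule table keep their printed
#' values and are not meant to be changed when reproducing the published
#' scenarios; the remaining entries (geometry, copy numbers, step lengths,
#' cytokine lifetimes, T-helper influx law) are artifact defaults fixed by
#' pattern-oriented calibration against the self-limited response (stimulus
#' clearance within the first hours, transcriptional resolution within 24 h).
#' See the methods vignette for the provenance of every value.
#'
#' Groups (flat names, documented by prefix of use):
#' \describe{
#'   \item{world}{\code{width}, \code{height} (patches, 161 x 161),
#'     \code{n_macrophages} (4), \code{ticks_per_hour} (tick-to-hour mapping,
#'     800), \code{cell_move_interval} (cellular agents move every 800th tick,
#'     giving the published 800:1 molecular:cellular movement-frequency
#'     ratio), \code{cell_step}, \code{lps_step}, \code{mol_step},
#'     \code{intra_step} (patch units per move), \code{contact_radius}
#'     (two agents interact within 1 patch).}
#'   \item{macrophage}{\code{cell_radius}, \code{nucleus_radius},
#'     \code{membrane_count} (240 membrane agents), \code{n_tlr4} (30),
#'     \code{n_tnfr} (15), \code{n_il4r} (15), \code{nfkb_per_cell} (120
#'     inactive NF-kB:IkBa complexes), \code{energy_init} (100),
#'     \code{energy_switch_frac} (TNF amplification switch turns on strictly
#'     below 25\% of initial energy).}
#'   \item{receptors}{\code{sensitivity_max} (5), \code{sensitivity_inclusive}
#'     (use \code{<=} instead of the literal \code{<} in the sensitivity
#'     rule), \code{sensitivity_recovery_ticks} (+1 sensitivity per interval,
#'     cap 5), \code{tlr4_prod_interval} (activated TLR4 emits 1 TNF-a every
#'     100 ticks), \code{tlr4_activation_window} (100 ticks per binding,
#'     renewable).}
#'   \item{molecules}{\code{lps_bound_decay_min}/\code{max} (bound LPS
#'     degrades in 1-2 ticks), \code{tnf_life} (600), \code{tnf_bound_decay}
#'     (50), \code{tnf_bound_decay_il4} (200 with nearby bound IL-4),
#'     \code{il4_speeds_tnf_decay} (swap the two constants' roles),
#'     \code{ikk_prod_interval} (1 IKK per 5 ticks), \code{ikk_life_max}
#'     (uniform 1-799 tick lifetime), \code{p_bind_ikk} (0.70),
#'     \code{ikk_bind_ticks} (dissociation after 10),
#'     \code{transcription_interval} (10), \code{p_il12} (0.80),
#'     \code{tnf_amplified} (TNF units per cycle while the energy switch is
#'     on), \code{il4_burst} (3), \code{p_il4} (0.86),
#'     \code{il4_interval_max} (cycle every 1-5 ticks), \code{a_boost}
#'     (anti-inflammatory production multiplier while switched on),
#'     \code{il12_life}, \code{il4_life}, \code{il4_bound_duration},
#'     \code{ikba_life} (free activated IkBa is turned over by the
#'     proteasome after this many ticks).}
#'   \item{T helpers}{\code{th0_entry_threshold}, \code{th0_entry_interval},
#'     \code{th0_cap}, \code{th1_secretion_interval},
#'     \code{th2_secretion_interval}, \code{th_life} (ticks a recruited T
#'     helper resides in the world before leaving the circulation)
#'     (differentiation itself is hard-wired:
#'     25 bound interleukins, majority species wins, ties fall to Th2).}
#' }
#'
#' @param ... named overrides of individual defaults.
#' @return A named list of class \code{abm_params}.
#' @examples
#' p <- default_params(lps_step = 6)
#' p$lps_step
#' @export
default_params <- function(...) {
  p <- default_params_raw()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    p <- modifyList(p, over)
  }
  p <- validate_params(p)
  class(p) <- "abm_params"
  p
}

#' Validate a parameter set
#'
#' Checks the parameter invariants: probabilities in [0, 1]; tick intervals,
#' lifetimes and counts at least 1; geometric consistency (nucleus inside
#' membrane, world large enough to place the macrophages without overlap).
#' Errors name the offending key.
#'
#' @param p named list of parameters (all fields of [default_params()]).
#' @return The validated parameter list, invisibly classed `abm_params`.
#' @export
validate_params <- function(p) {
  need <- names(default_params_raw())
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(p), need)
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "), call. = FALSE)
  probs <- c("p_bind_ikk", "p_il12", "p_il4", "energy_switch_frac",
             "p_ikba_starved")
  for (nm in probs)
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stop("parameter '", nm, "' must be a probability in [0, 1]", call. = FALSE)
  at_least_1 <- c("ticks_per_hour", "cell_move_interval", "sensitivity_max",
                  "sensitivity_recovery_ticks", "tlr4_prod_interval",
                  "tlr4_activation_window", "lps_bound_decay_min",
                  "lps_bound_decay_max", "tnf_life", "tnf_bound_decay",
                  "tnf_bound_decay_il4", "ikk_prod_interval", "ikk_life_max",
                  "ikk_bind_ticks", "transcription_interval", "tnf_amplified",
                  "il4_burst", "il4_interval_max", "a_boost", "il12_life",
                  "il4_life", "il4_bound_duration", "ikba_life", "energy_recovery_ticks",
                  "ikba_seek_radius", "ikba_kill_radius",
                  "th0_entry_interval",
                  "th0_cap", "th1_secretion_interval", "th2_secretion_interval",
                  "th_life",
                  "membrane_count", "energy_init", "width", "height")
  for (nm in at_least_1)
    if (!is.numeric(p[[nm]]) || p[[nm]] < 1)
      stop("parameter '", nm, "' must be >= 1", call. = FALSE)
  non_neg <- c("n_macrophages", "n_tlr4", "n_tnfr", "n_il4r", "nfkb_per_cell",
               "th0_entry_threshold", "cell_step", "lps_step", "mol_step",
               "intra_step")
  for (nm in non_neg)
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0)
      stop("parameter '", nm, "' must be >= 0", call. = FALSE)
  flags <- c("sensitivity_inclusive", "il4_speeds_tnf_decay")
  for (nm in flags)
    if (!is.logical(p[[nm]]) || is.na(p[[nm]]))
      stop("parameter '", nm, "' must be TRUE or FALSE", call. = FALSE)
  if (p$nucleus_radius >= p$cell_radius)
    stop("parameter 'nucleus_radius' must be smaller than 'cell_radius'",
         call. = FALSE)
  if (p$lps_bound_decay_max < p$lps_bound_decay_min)
    stop("parameter 'lps_bound_decay_max' must be >= 'lps_bound_decay_min'",
         call. = FALSE)
  class(p) <- "abm_params"
  invisible(p)
}

# single source of truth for the default values
default_params_raw <- function() {
  list(
    width = 161, height = 161, n_macrophages = 4,
    ticks_per_hour = 800, cell_move_interval = 800,
    cell_step = 1, lps_step = 20, mol_step = 4, intra_step = 2,
    contact_radius = 1,
    cell_radius = 10, nucleus_radius = 4, membrane_count = 240,
    n_tlr4 = 30, n_tnfr = 15, n_il4r = 15, nfkb_per_cell = 120,
    energy_init = 1000, energy_switch_frac = 0.25,
    energy_recovery_ticks = 8,
    sensitivity_max = 5, sensitivity_inclusive = FALSE,
    sensitivity_recovery_ticks = 5600,
    tlr4_prod_interval = 100, tlr4_activation_window = 100,
    lps_bound_decay_min = 1, lps_bound_decay_max = 2,
    tnf_life = 600, tnf_bound_decay = 50, tnf_bound_decay_il4 = 200,
    il4_speeds_tnf_decay = FALSE,
    ikk_prod_interval = 5, ikk_life_max = 799,
    p_bind_ikk = 0.7, ikk_bind_ticks = 10,
    transcription_interval = 10, p_il12 = 0.8, tnf_amplified = 2,
    il4_burst = 3, p_il4 = 0.86, il4_interval_max = 5, a_boost = 2,
    il12_life = 800, il4_life = 800, il4_bound_duration = 1500,
    ikba_life = 20000, ikba_seek_radius = 3, ikba_kill_radius = 2,
    p_ikba_starved = 0.5,
    th0_entry_threshold = 100, th0_entry_interval = 200, th0_cap = 50,
    th1_secretion_interval = 100, th2_secretion_interval = 50,
    th_life = 6400
  )
}
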