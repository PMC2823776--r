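# Rule-level stochastic operations, exposed for direct measurement.
#
# The trial functions below run the exact inline draw helpers the engine's
# tick loop calls, under a fresh seeded stream, so measured frequencies are
# frequencies of the shipped rules and not of a re-implementation.

#' Probability that an LPS molecule binds an unoccupied TLR4
#'
#' The published rule draws an integer uniformly on 1..`sensitivity_max` (5);
#' binding succeeds when the draw is strictly below the receptor's current
#' sensitivity, so P(bind | s) = (s - 1) / 5.  With
#' `sensitivity_inclusive = TRUE` the comparison is `<=` and
#' P(bind | s) = s / 5.
#'
#' @param sensitivity current receptor sensitivity (0..5).
#' @param params parameter set.
#' @return exact binding probability.
#' @examples
#' lps_binding_prob(5)  # 4/5
#' lps_binding_prob(1)  # 0: no draw in 1..5 is < 1
#' @export
lps_binding_prob <- function(sensitivity, params = default_params()) {
  smax <- params$sensitivity_max
  if (params$sensitivity_inclusive)
    pmin(sensitivity, smax) / smax
  else
    pmax(0, pmin(sensitivity, smax + 1) - 1) / smax
}

#' Seeded trials of the TLR4 sensitivity binding rule
#'
#' @param n number of contact trials.
#' @param sensitivity receptor sensitivity held fixed across trials.
#' @param seed integer seed.
#' @param params parameter set.
#' @return number of successful bindings out of `n`.
#' @export
attempt_lps_binding <- function(n, sensitivity, seed = 1L,
                                params = default_params()) {
  cpp_lps_bind_trials(as.integer(n), as.integer(sensitivity), seed, params)
}

#' Seeded trials of the IKK to NF-kB:IkBa binding rule (70% chance)
#'
#' Each trial is one contact event between an activated IKK and an inactive
#' NF-kB:IkBa complex.
#'
#' @param n number of contact trials.
#' @param seed integer seed.
#' @param params parameter set.
#' @return number of bindings out of `n`.
#' @export
ikk_bind_nfkb_trials <- function(n, seed = 1L, params = default_params()) {
  cpp_ikk_bind_trials(as.integer(n), seed, params)
}

#' Seeded nuclear NF-kB transcription cycles
#'
#' Each cycle emits exactly 1 activated IkBa, 1 IL-12 with 80% chance, and
#' 1 unit of TNF-a (`tnf_amplified` units while the energy switch is on).
#'
#' @param n number of transcription cycles.
#' @param seed integer seed.
#' @param switch_on whether the macrophage's energy switch is on.
#' @param params parameter set.
#' @return list with total `il12`, `ikba` and `tnf` emissions over `n`
#'   cycles.
#' @export
nfkb_transcribe_trials <- function(n, seed = 1L, switch_on = FALSE,
                                   params = default_params()) {
  cpp_transcribe_trials(as.integer(n), seed, params, switch_on)
}

#' Seeded IL-4 production cycles
#'
#' In the presence of free IL-12, each cycle yields `il4_burst` (3) units of
#' IL-4 with 86% probability; cycles recur every 1..5 ticks (interval redrawn
#' each cycle).  While any macrophage energy switch is on the burst size is
#' multiplied by `a_boost`.
#'
#' @param n number of production cycles.
#' @param seed integer seed.
#' @param boost whether the anti-inflammatory boost is active.
#' @param params parameter set.
#' @return list with integer vectors `yields` (units per cycle) and
#'   `intervals` (ticks to the next cycle).
#' @export
il4_production_trials <- function(n, seed = 1L, boost = FALSE,
                                  params = default_params()) {
  cpp_il4_cycle_trials(as.integer(n), seed, params, boost)
}

#' Seeded IKK lifetime draws (uniform on 1..799 ticks)
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @param params parameter set.
#' @return integer vector of lifetimes.
#' @export
ikk_lifetime_draws <- function(n, seed = 1L, params = default_params()) {
  cpp_ikk_lifetime_draws(as.integer(n), seed, params)
}

#' Seeded bound-LPS decay draws (uniform on 1..2 ticks)
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @param params parameter set.
#' @return integer vector of decay times.
#' @export
lps_decay_draws <- function(n, seed = 1L, params = default_params()) {
  cpp_lps_decay_draws(as.integer(n), seed, params)
}
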