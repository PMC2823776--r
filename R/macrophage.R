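#' Construct a macrophage
#'
#' A macrophage is a composite agent: a membrane ring of `membrane_count`
#' point agents at `cell_radius`, a nucleus region of `nucleus_radius` around
#' the center, receptors (TLR4 at full sensitivity, TNFR, IL-4R) embedded at
#' membrane positions, and `nfkb_per_cell` inactive NF-kB:IkBa complexes at
#' random cytosolic positions.  The cell carries an energetic level `energy`
#' (initially `energy_init`) whose switch state turns on strictly below 25%
#' of the initial value.  Under the published composition constraint a cell
#' must comprise more than 400 constituent agents.
#'
#' Membrane and receptor placements are deterministic (evenly spaced, receptor
#' types interleaved over distinct membrane slots); intracellular positions
#' use R's RNG stream, so seed before calling for reproducibility.
#'
#' @param center length-2 numeric, cell center in patch coordinates.
#' @param params parameter set, see [default_params()].
#' @param check enforce the >400 constituent-agent invariant (disable only
#'   for reduced unit-test fixtures).
#' @return list of class `abm_macrophage` with elements `center`, `membrane`
#'   (data.frame of ring positions), `receptors` (data.frame: type, angle,
#'   sensitivity), `intracellular` (data.frame of NF-kB complex positions),
#'   `energy`, `energy_init`, `switch_on`, `n_constituents`.
#' @examples
#' m <- build_macrophage(c(80, 80))
#' m$n_constituents  # 240 membrane + 60 receptors + 120 NF-kB = 420
#' @export
build_macrophage <- function(center, params = default_params(), check = TRUE) {
  stopifnot(length(center) == 2)
  n_rec <- params$n_tlr4 + params$n_tnfr + params$n_il4r
  n_tot <- params$membrane_count + n_rec + params$nfkb_per_cell
  if (check && n_tot <= 400)
    stop("macrophage would comprise ", n_tot,
         " constituent agents; the model requires more than 400",
         call. = FALSE)
  ang <- 2 * pi * seq_len(params$membrane_count) / params$membrane_count
  mem <- wrap_position(center[1] + params$cell_radius * cos(ang),
                       center[2] + params$cell_radius * sin(ang),
                       params$width, params$height)
  membrane <- data.frame(x = mem$x, y = mem$y, angle = ang)
  # receptors evenly spread over distinct membrane slots, types interleaved
  if (n_rec > 0) {
    slots <- 2 * pi * (seq_len(n_rec) - 0.5) / n_rec
    counts <- c(TLR4 = params$n_tlr4, TNFR = params$n_tnfr,
                IL4R = params$n_il4r)
    type <- character(0)
    while (any(counts > 0))  # round-robin so types are spread over the ring
      for (nm in names(counts)) if (counts[[nm]] > 0) {
        type <- c(type, nm); counts[[nm]] <- counts[[nm]] - 1
      }
    receptors <- data.frame(
      type = type, angle = slots,
      sensitivity = ifelse(type == "TLR4", params$sensitivity_max, NA))
  } else {
    receptors <- data.frame(type = character(), angle = numeric(),
                            sensitivity = numeric())
  }
  k <- params$nfkb_per_cell
  if (k > 0) {
    rr <- sqrt(params$nucleus_radius^2 +
                 runif(k) * 0.96 * (params$cell_radius^2 - params$nucleus_radius^2))
    aa <- runif(k) * 2 * pi
    pos <- wrap_position(center[1] + rr * cos(aa), center[2] + rr * sin(aa),
                         params$width, params$height)
    intracellular <- data.frame(x = pos$x, y = pos$y)
  } else {
    intracellular <- data.frame(x = numeric(), y = numeric())
  }
  structure(list(center = center, membrane = membrane, receptors = receptors,
                 intracellular = intracellular,
                 energy = params$energy_init, energy_init = params$energy_init,
                 switch_on = FALSE, n_constituents = n_tot),
            class = "abm_macrophage")
}

# Rejection-sample non-overlapping macrophage centers (pairwise center
# distance >= 2 * (cell_radius + 1)); uses R's RNG stream.
place_macrophages <- function(params) {
  n <- params$n_macrophages
  if (n == 0) return(matrix(numeric(), ncol = 2))
  mind <- 2 * (params$cell_radius + 1)
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in seq_len(10000)) {
      cand <- c(runif(1, 0, params$width), runif(1, 0, params$height))
      ok <- TRUE
      if (i > 1) {
        d <- torus_distance(cand[1], cand[2], centers[seq_len(i - 1), 1],
                            centers[seq_len(i - 1), 2],
                            params$width, params$height)
        ok <- all(d >= mind)
      }
      if (ok) { centers[i, ] <- cand; break }
    }
    if (anyNA(centers[i, ]))
      stop("could not place ", n, " non-overlapping macrophages in a ",
           params$width, " x ", params$height, " world", call. = FALSE)
  }
  centers
}

#' Energy bookkeeping of a macrophage
#'
#' Transcription cycles cost 1 energy unit (floored at 0); each IL-4 binding
#' adds 1.  The bistability switch is on strictly below
#' `energy_switch_frac` (25%) of the initial energy; while on, NF-kB-driven
#' TNF-a output is amplified and anti-inflammatory production is boosted.
#'
#' @param energy current energy.
#' @param energy_init initial energy.
#' @param event `"transcription_cycle"` or `"il4_binding"`.
#' @param params parameter set.
#' @return list with updated `energy` and `switch_on`.
#' @examples
#' energy_update(25, 100, "transcription_cycle")$switch_on  # 24 < 25 -> TRUE
#' @export
energy_update <- function(energy, energy_init, event,
                          params = default_params()) {
  energy <- switch(event,
                   transcription_cycle = max(0, energy - 1),
                   il4_binding = energy + 1,
                   stop("unknown energy event: ", event, call. = FALSE))
  list(energy = energy,
       switch_on = energy < params$energy_switch_frac * energy_init)
}

#' T-helper differentiation rule
#'
#' A Th0 cell counts the interleukin units bound on its surface receptors.
#' Once IL-12 + IL-4 reaches 25 it differentiates, irreversibly: Th1 when
#' strictly more IL-12 than IL-4 is present, otherwise Th2 (ties included).
#'
#' @param il12,il4 non-negative integer surface counts (vectorized).
#' @return character vector: `"Th0"` (below threshold), `"Th1"` or `"Th2"`.
#' @examples
#' th0_differentiate(13, 12)  # "Th1"
#' th0_differentiate(12, 12)  # still "Th0": 24 < 25
#' @export
th0_differentiate <- function(il12, il4) {
  stopifnot(all(il12 >= 0), all(il4 >= 0))
  ifelse(il12 + il4 >= 25, ifelse(il12 > il4, "Th1", "Th2"), "Th0")
}
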