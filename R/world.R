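# WorldState construction, stepping, snapshots and unit-test fixtures.
#
# A world is an S3 object of class "abm_world": a list with
#   $state  - tabular agent registries consumed by the compiled engine
#             (macs, receptors, mols, ths, doses, tick, il4_timer, rng, seed)
#   $params - the parameter set in force
# The molecule table uses integer type codes shared with the engine.

MOL_TYPE <- c(LPS = 0L, TNF = 1L, IL12 = 2L, IL4 = 3L, IKK = 4L, NFKB = 5L,
              IKBA = 6L, INH = 7L)

empty_mols <- function() {
  data.frame(type = integer(), state = integer(), mac = integer(),
             x = numeric(), y = numeric(), t1 = integer(), t2 = integer(),
             partner = integer())
}

empty_ths <- function() {
  data.frame(kind = integer(), x = numeric(), y = numeric(),
             il12 = integer(), il4 = integer(), clock = integer(),
             age = integer())
}

empty_doses <- function() {
  data.frame(tick = integer(), type = integer(), amount = integer())
}

#' Create a simulation world
#'
#' Places `n_macrophages` non-overlapping macrophages at random positions on
#' the torus and registers their constituents with the engine.  All
#' randomness (placement and the engine's own stream) derives from `seed`.
#'
#' @param params parameter set, see [default_params()].
#' @param seed integer seed; every source of randomness in the run derives
#'   from it.
#' @param doses optional dose schedule, a data.frame with columns
#'   `time_hours`, `species` (`"LPS"`, `"TNF"` or `"IKK_inhibitor"`) and
#'   `amount`.
#' @param check_composition enforce the >400 constituent-agent invariant for
#'   every constructed macrophage (disable only for reduced test fixtures).
#' @return An object of class `abm_world` at tick 0.
#' @export
world_new <- function(params = default_params(), seed = 1L, doses = NULL,
                      check_composition = TRUE) {
  params <- validate_params(params)
  set.seed(seed)
  centers <- place_macrophages(params)
  n <- nrow(centers)
  macs <- data.frame(cx = numeric(n), cy = numeric(n), heading = numeric(n),
                     energy = numeric(n), energy_init = numeric(n),
                     sw = logical(n))
  receptors <- data.frame(mac = integer(), type = integer(), angle = numeric(),
                          sens = integer(), lps_left = integer(),
                          act_left = integer(), act_accum = integer(),
                          recov = integer(), tnf_left = integer(),
                          il4_left = integer())
  mols <- empty_mols()
  rec_code <- c(TLR4 = 0L, TNFR = 1L, IL4R = 2L)
  for (i in seq_len(n)) {
    m <- build_macrophage(centers[i, ], params, check = check_composition)
    macs[i, ] <- list(m$center[1], m$center[2], runif(1) * 2 * pi,
                      m$energy, m$energy_init, FALSE)
    if (nrow(m$receptors)) {
      receptors <- rbind(receptors, data.frame(
        mac = i - 1L, type = rec_code[m$receptors$type],
        angle = m$receptors$angle,
        sens = ifelse(is.na(m$receptors$sensitivity), 0L,
                      as.integer(m$receptors$sensitivity)),
        lps_left = 0L, act_left = 0L, act_accum = 0L, recov = 0L,
        tnf_left = 0L, il4_left = 0L))
    }
    if (nrow(m$intracellular)) {
      mols <- rbind(mols, data.frame(
        type = MOL_TYPE[["NFKB"]], state = 0L, mac = i - 1L,
        x = m$intracellular$x, y = m$intracellular$y,
        t1 = 0L, t2 = 0L, partner = -1L))
    }
  }
  rownames(receptors) <- NULL
  state <- list(tick = 0, il4_timer = -1L, rng = NULL, seed = seed,
                macs = macs, receptors = receptors, mols = mols,
                ths = empty_ths(), doses = dose_table(doses, params),
                counters = c(0, 0, 0, 0))
  structure(list(state = state, params = params, seed = seed),
            class = "abm_world")
}

# convert a time_hours/species/amount schedule into engine tick doses
dose_table <- function(doses, params) {
  if (is.null(doses) || nrow(doses) == 0) return(empty_doses())
  species_code <- c(LPS = MOL_TYPE[["LPS"]], TNF = MOL_TYPE[["TNF"]],
                    IKK_inhibitor = MOL_TYPE[["INH"]])
  if (!all(doses$species %in% names(species_code)))
    stop("injectable species are ", paste(names(species_code), collapse = ", "),
         call. = FALSE)
  if (any(doses$amount < 0) || any(doses$time_hours < 0))
    stop("dose amounts and times must be non-negative", call. = FALSE)
  out <- data.frame(tick = as.integer(floor(doses$time_hours *
                                              params$ticks_per_hour)),
                    type = as.integer(species_code[doses$species]),
                    amount = as.integer(doses$amount))
  out[order(out$tick), , drop = FALSE]
}

#' Advance a world by whole ticks
#'
#' Runs the engine's fixed phase order (doses, LPS, receptor production,
#' TNF-a, macrophage production/chemotaxis, IKK, NF-kB transcription, IkBa,
#' cytokines, T helpers, energy switch, census) once per tick.  Stepping a
#' world in pieces is bit-identical to one uninterrupted run because the RNG
#' state travels with the world.
#'
#' @param world an `abm_world`.
#' @param ticks number of ticks to advance.
#' @param record keep the per-tick census rows (in `$series`).
#' @param audit run the exhaustive per-tick agent audit (positions in bounds,
#'   containment, TNF-a tick budgets); an audit failure is an engine bug and
#'   raises an error.
#' @return The advanced world; with `record = TRUE` the census rows of this
#'   call are in `world$series` (a [timeseries_frame()]).
#' @export
world_step <- function(world, ticks = 1, record = TRUE, audit = FALSE) {
  stopifnot(inherits(world, "abm_world"))
  out <- cpp_run(world$state, world$params, as.integer(ticks), record, audit)
  world$state <- out$state
  if (record)
    world$series <- timeseries_frame(out$series, world$params,
                                     seed = world$seed)
  world
}

#' Save / load a world snapshot
#'
#' Snapshots are self-describing JSON dumps of the full simulation state
#' (agent registries, tick counter, pending doses, RNG stream state), so a
#' reloaded world resumes bit-identically.
#'
#' @param world an `abm_world`.
#' @param path file path.
#' @return `world_save` returns `path` invisibly; `world_load` the restored
#'   world.
#' @export
world_save <- function(world, path) {
  stopifnot(inherits(world, "abm_world"))
  payload <- list(params = unclass(world$params), seed = world$seed,
                  state = world$state)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname world_save
#' @export
world_load <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- validate_params(payload$params)
  state <- payload$state
  for (nm in c("macs", "receptors", "mols", "ths", "doses"))
    state[[nm]] <- as.data.frame(state[[nm]])
  # jsonlite drops all-NA / empty frames to lists; restore schemas
  if (nrow(state$mols) == 0) state$mols <- empty_mols()
  if (nrow(state$ths) == 0) state$ths <- empty_ths()
  if (nrow(state$doses) == 0) state$doses <- empty_doses()
  state$counters <- as.numeric(state$counters)
  structure(list(state = state, params = params, seed = payload$seed),
            class = "abm_world")
}

#' Minimal deterministic unit-test worlds
#'
#' Each fixture exercises exactly one rule cluster:
#' \describe{
#'   \item{empty}{no agents at all; stepping changes no counts.}
#'   \item{single_macrophage}{one default macrophage, nothing else.}
#'   \item{one_receptor_one_lps}{one reduced macrophage carrying a single
#'     TLR4 at full sensitivity with one free LPS adjacent to it.}
#'   \item{nfkb_unit}{one reduced macrophage with a single active nuclear
#'     NF-kB, transcription clock at 0.}
#'   \item{th_unit}{no macrophages, one undifferentiated Th0 at the world
#'     center.}
#' }
#'
#' @param kind fixture name.
#' @param seed integer seed.
#' @param params optional base parameters; fixture-specific composition
#'   overrides are applied on top.
#' @return an `abm_world`.
#' @export
build_fixture <- function(kind = c("empty", "single_macrophage",
                                   "one_receptor_one_lps", "nfkb_unit",
                                   "th_unit"),
                          seed = 1L, params = NULL) {
  kind <- match.arg(kind)
  base <- if (is.null(params)) default_params() else params
  if (kind == "empty") {
    p <- modifyList(base, list(n_macrophages = 0))
    return(world_new(validate_params(p), seed))
  }
  if (kind == "single_macrophage") {
    p <- modifyList(base, list(n_macrophages = 1))
    return(world_new(validate_params(p), seed))
  }
  if (kind == "one_receptor_one_lps") {
    p <- modifyList(base, list(n_macrophages = 1, n_tlr4 = 1, n_tnfr = 0,
                               n_il4r = 0, nfkb_per_cell = 0))
    w <- world_new(validate_params(p), seed, check_composition = FALSE)
    rc <- w$state$receptors[1, ]
    pos <- wrap_position(w$state$macs$cx[1] +
                           (p$cell_radius + 0.5) * cos(rc$angle),
                         w$state$macs$cy[1] +
                           (p$cell_radius + 0.5) * sin(rc$angle),
                         p$width, p$height)
    w$state$mols <- rbind(w$state$mols, data.frame(
      type = MOL_TYPE[["LPS"]], state = 0L, mac = -1L,
      x = pos$x, y = pos$y, t1 = 0L, t2 = 0L, partner = -1L))
    return(w)
  }
  if (kind == "nfkb_unit") {
    p <- modifyList(base, list(n_macrophages = 1, n_tlr4 = 0, n_tnfr = 0,
                               n_il4r = 0, nfkb_per_cell = 0))
    w <- world_new(validate_params(p), seed, check_composition = FALSE)
    w$state$mols <- rbind(w$state$mols, data.frame(
      type = MOL_TYPE[["NFKB"]], state = 3L, mac = 0L,
      x = w$state$macs$cx[1], y = w$state$macs$cy[1],
      t1 = 0L, t2 = 0L, partner = -1L))
    return(w)
  }
  # th_unit
  p <- modifyList(base, list(n_macrophages = 0))
  w <- world_new(validate_params(p), seed)
  w$state$ths <- data.frame(kind = 0L, x = p$width / 2, y = p$height / 2,
                            il12 = 0L, il4 = 0L, clock = 0L, age = 0L)
  w
}

#' @export
print.abm_world <- function(x, ...) {
  st <- x$state
  cat("<abm_world> tick", st$tick,
      "|", nrow(st$macs), "macrophages,",
      nrow(st$mols), "molecules,", nrow(st$ths), "Th cells,",
      sum(st$doses$amount), "dose units pending\n")
  invisible(x)
}
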