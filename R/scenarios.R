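# The seven published dosing scenarios, the replicate runner, and the
# parameter-sweep calibration harness.

#' Construct a dosing scenario
#'
#' @param name scenario label.
#' @param doses data.frame with columns `time_hours`, `species` (`"LPS"`,
#'   `"TNF"`, `"IKK_inhibitor"`) and `amount` (agent units).
#' @param run_hours simulated horizon in hours.
#' @param overrides named list of parameter overrides applied on top of the
#'   run's parameter set.
#' @return list of class `abm_scenario`.
#' @export
scenario_spec <- function(name, doses, run_hours = 24, overrides = list()) {
  stopifnot(is.data.frame(doses),
            all(c("time_hours", "species", "amount") %in% names(doses)),
            run_hours > 0)
  if (any(doses$amount < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  structure(list(name = name, doses = doses, run_hours = run_hours,
                 overrides = overrides),
            class = "abm_scenario")
}

#' The published dosing scenarios
#'
#' Dose schedules exactly as printed in the scenario figures:
#' \describe{
#'   \item{self_limited}{LPS 350 at 0 h; clearance within the first hours and
#'     resolution of all channels within 24 h.}
#'   \item{high_dose}{LPS 750 at 0 h; the response does not abate.}
#'   \item{persistent_infectious}{LPS 1000 at 0 h; receptor saturation leaves
#'     stimulus in the system.}
#'   \item{tolerance}{LPS 100 at 0 h + LPS 650 at 8 h; the early sub-lethal
#'     dose desensitizes signaling and the combined insult resolves.}
#'   \item{potentiation}{LPS 100 at 0 h + LPS 250 at 2 h; the second hit
#'     arrives while mediators are still elevated and the response is
#'     exaggerated.}
#'   \item{two_hit}{LPS 350 + TNF-a 300 at 0 h; pre-existing inflammatory
#'     mediators amplify IKK activity.}
#'   \item{ikk_inhibitor}{LPS 750 + 400 IKK-inhibitor molecules at 0 h; the
#'     intervention rescues the high-dose response.}
#' }
#'
#' @param name one of the scenario names above.
#' @return an [scenario_spec()] object.
#' @examples
#' builtin_scenario("tolerance")$doses
#' @export
builtin_scenario <- function(name) {
  d <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(time_hours = as.numeric(m[, 1]),
               species = c("LPS", "TNF", "IKK_inhibitor")[as.integer(m[, 2])],
               amount = as.numeric(m[, 3]))
  }
  tbl <- list(
    self_limited          = d(0, 1, 350),
    high_dose             = d(0, 1, 750),
    persistent_infectious = d(0, 1, 1000),
    tolerance             = d(0, 1, 100, 8, 1, 650),
    potentiation          = d(0, 1, 100, 2, 1, 250),
    two_hit               = d(0, 1, 350, 0, 2, 300),
    ikk_inhibitor         = d(0, 1, 750, 0, 3, 400)
  )
  if (!name %in% names(tbl))
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(tbl), collapse = ", "), call. = FALSE)
  scenario_spec(name, tbl[[name]])
}

#' Run one scenario
#'
#' Builds a fresh world, queues the scenario's doses (applied at
#' `floor(time_hours * ticks_per_hour)`), and advances
#' `run_hours * ticks_per_hour` ticks.
#'
#' @param spec an `abm_scenario` (or a name accepted by
#'   [builtin_scenario()]).
#' @param params parameter set; the scenario's overrides are applied on top.
#' @param seed integer seed for the whole run.
#' @param audit enable the per-tick agent audit (slow; test use).
#' @return the per-tick [timeseries_frame()] of the run.
#' @export
run_scenario <- function(spec, params = default_params(), seed = 1L,
                         audit = FALSE) {
  if (is.character(spec)) spec <- builtin_scenario(spec)
  stopifnot(inherits(spec, "abm_scenario"))
  p <- params
  if (length(spec$overrides)) p <- do.call(default_params, spec$overrides)
  w <- world_new(p, seed = seed, doses = spec$doses)
  nticks <- as.integer(round(spec$run_hours * p$ticks_per_hour))
  w <- world_step(w, nticks, record = TRUE, audit = audit)
  s <- w$series
  attr(s, "scenario") <- spec$name
  s
}

#' Run seeded replicates of a scenario
#'
#' Replicate `i` uses seed `seed_base + i - 1`.
#'
#' @param spec scenario (object or name).
#' @param params parameter set.
#' @param n number of replicates.
#' @param seed_base base seed.
#' @param tol,hold_hours classification settings, see [classify_outcome()].
#' @param keep_series keep the full per-tick series of every replicate (they
#'   are large; reports alone often suffice).
#' @return list of class `abm_replicates`: `runs` (list with `series` when
#'   kept, `report`, `seed`), `summary` (see [summarize_replicates()]),
#'   `scenario`, `seed_base`.
#' @export
run_replicates <- function(spec, params = default_params(), n = 20,
                           seed_base = 1L, tol = 0.05, hold_hours = 1,
                           keep_series = FALSE) {
  stopifnot(n >= 1)
  if (is.character(spec)) spec <- builtin_scenario(spec)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    sd <- as.integer(seed_base + i - 1)
    ser <- run_scenario(spec, params, seed = sd)
    rep_i <- classify_outcome(ser, tol = tol, hold_hours = hold_hours)
    runs[[i]] <- list(series = if (keep_series) ser else NULL,
                      report = rep_i, seed = sd)
  }
  structure(list(runs = runs,
                 summary = summarize_replicates(lapply(runs, `[[`, "report")),
                 scenario = spec$name, seed_base = seed_base),
            class = "abm_replicates")
}

#' @export
print.abm_replicates <- function(x, ...) {
  s <- x$summary
  cat("<abm_replicates>", x$scenario, "-", s$n, "seeded runs\n",
      sprintf(" fraction resolved: %.2f\n", s$fraction_resolved),
      sprintf(" clearance median: %s h\n",
              format(s$clearance_hours[["median"]], digits = 3)),
      sprintf(" resolution median: %s h\n",
              format(s$resolution_hours[["median"]], digits = 3)))
  invisible(x)
}

#' Pattern-oriented parameter sweep
#'
#' Scores every point of a parameter grid by the calibration pattern: the
#' self-limited scenario must clear the stimulus within `clearance_hours` and
#' resolve within `resolution_hours`.  Points are ranked by the fraction of
#' replicates that meet the pattern (margin), then by median resolution time.
#'
#' @param grid named list mapping parameter names to value vectors; the full
#'   Cartesian product is evaluated.
#' @param base_params parameter set the grid points are applied on top of.
#' @param scenario scenario to score against (default `self_limited`).
#' @param n_replicates seeded replicates per grid point.
#' @param seed_base base seed.
#' @param clearance_hours,resolution_hours acceptance pattern thresholds.
#' @return data.frame with one row per grid point: the swept values,
#'   `fraction_pass`, `fraction_resolved`, `median_clearance_h`,
#'   `median_resolution_h`, ordered best first.  If no point passes in any
#'   replicate the function signals an error of class
#'   `abm_calibration_failure` carrying the nearest-miss diagnostics table.
#' @export
calibrate <- function(grid, base_params = default_params(),
                      scenario = "self_limited", n_replicates = 5,
                      seed_base = 1L, clearance_hours = 2,
                      resolution_hours = 24) {
  stopifnot(length(grid) >= 1, all(lengths(grid) >= 1), n_replicates >= 1)
  bad <- setdiff(names(grid), names(default_params_raw()))
  if (length(bad))
    stop("unknown parameter(s) in grid: ", paste(bad, collapse = ", "),
         call. = FALSE)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- unclass(base_params)
    for (nm in names(pts)) p[[nm]] <- pts[i, nm]
    p <- validate_params(p)
    rr <- run_replicates(scenario, p, n = n_replicates, seed_base = seed_base)
    reports <- lapply(rr$runs, `[[`, "report")
    pass <- vapply(reports, function(r) {
      # the pattern requires an actual inflammatory response (a parameter set
      # that never activates NF-kB has no resolution dynamics to score)
      r$peaks[["P"]] > 0 &&
        !is.na(r$clearance_time_hours) &&
        r$clearance_time_hours <= clearance_hours &&
        r$resolved && r$resolution_time_hours <= resolution_hours
    }, TRUE)
    res[[i]] <- data.frame(
      pts[i, , drop = FALSE],
      fraction_pass = mean(pass),
      fraction_resolved = rr$summary$fraction_resolved,
      median_clearance_h = rr$summary$clearance_hours[["median"]],
      median_resolution_h = rr$summary$resolution_hours[["median"]])
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$fraction_pass, out$median_resolution_h), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (all(out$fraction_pass == 0)) {
    cond <- structure(
      class = c("abm_calibration_failure", "error", "condition"),
      list(message = paste0(
        "no grid point met the calibration pattern (clearance <= ",
        clearance_hours, " h, resolution <= ", resolution_hours,
        " h); nearest miss: ",
        paste(names(out)[seq_along(grid)], "=",
              unlist(out[1, seq_along(grid)]), collapse = ", "),
        " with fraction_resolved = ", out$fraction_resolved[1]),
        call = sys.call(-1), diagnostics = out))
    stop(cond)
  }
  out
}
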