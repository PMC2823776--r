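# Config parsing, output writers, trajectory plots.
#
# Run configs are YAML: a scenario name or explicit dose list, parameter
# overrides (flat under `params:` or grouped under
# params.world/params.cells/params.molecules), run.hours/seed/replicates.
# Unknown keys are rejected by name; missing keys take the documented
# defaults.

#' Load a run configuration
#'
#' @param path YAML file.  Recognized top-level keys: `scenario` (builtin
#'   name), `doses` (list of `{time_hours, species, amount}` records),
#'   `params` (parameter overrides, flat or grouped), `run` (`hours`,
#'   `seed`, `replicates`, `tol`, `hold_hours`), `out_dir`.
#' @return list of class `abm_config` with `scenario` (an `abm_scenario`),
#'   `params`, `seed`, `replicates`, `tol`, `hold_hours`, `out_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known_top <- c("scenario", "doses", "params", "run", "out_dir")
  bad <- setdiff(names(raw), known_top)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  over <- list()
  if (!is.null(raw$params)) {
    pr <- raw$params
    groups <- intersect(names(pr), c("world", "engine", "cells", "molecules"))
    flat <- pr[setdiff(names(pr), groups)]
    for (g in groups) flat <- c(flat, pr[[g]])
    bad <- setdiff(names(flat), names(default_params_raw()))
    if (length(bad))
      stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    over <- flat
  }
  params <- do.call(default_params, over)
  run <- raw$run
  if (!is.null(run)) {
    bad <- setdiff(names(run), c("hours", "seed", "replicates", "tol",
                                 "hold_hours"))
    if (length(bad))
      stop("unknown run key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  hours <- if (!is.null(run$hours)) run$hours else 24
  if (!is.null(raw$scenario) && !is.null(raw$doses))
    stop("give either 'scenario' or 'doses', not both", call. = FALSE)
  if (!is.null(raw$scenario)) {
    scen <- builtin_scenario(raw$scenario)
    scen$run_hours <- hours
  } else if (!is.null(raw$doses)) {
    doses <- do.call(rbind, lapply(raw$doses, function(d) {
      bad <- setdiff(names(d), c("time_hours", "species", "amount"))
      if (length(bad))
        stop("unknown dose key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      if (!d$species %in% c("LPS", "TNF", "IKK_inhibitor"))
        stop("dose species '", d$species,
             "' is not injectable; use LPS, TNF or IKK_inhibitor",
             call. = FALSE)
      data.frame(time_hours = d$time_hours, species = d$species,
                 amount = d$amount)
    }))
    scen <- scenario_spec("custom", doses, run_hours = hours)
  } else {
    stop("config must name a 'scenario' or give an explicit 'doses' list",
         call. = FALSE)
  }
  structure(list(scenario = scen, params = params,
                 seed = if (!is.null(run$seed)) as.integer(run$seed) else 1L,
                 replicates = if (!is.null(run$replicates))
                   as.integer(run$replicates) else 1L,
                 tol = if (!is.null(run$tol)) run$tol else 0.05,
                 hold_hours = if (!is.null(run$hold_hours))
                   run$hold_hours else 1,
                 out_dir = raw$out_dir),
            class = "abm_config")
}

#' Save a run configuration
#'
#' Writes a YAML file that [load_config()] restores to an equal config
#' (lossless round-trip).
#'
#' @param config an `abm_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "abm_config"))
  doses <- config$scenario$doses
  payload <- list(
    doses = lapply(seq_len(nrow(doses)), function(i)
      list(time_hours = doses$time_hours[i],
           species = doses$species[i], amount = doses$amount[i])),
    params = unclass(config$params),
    run = list(hours = config$scenario$run_hours, seed = config$seed,
               replicates = config$replicates, tol = config$tol,
               hold_hours = config$hold_hours))
  if (!is.null(config$out_dir)) payload$out_dir <- config$out_dir
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Write replicate outputs to a directory
#'
#' For each replicate: a per-tick CSV (`<scenario>_seed<seed>.csv`, header
#' comments with metadata) and an outcome-report JSON; plus one summary JSON
#' and a copy of the effective configuration, so the directory reproduces the
#' run bit-identically.
#'
#' @param replicates an `abm_replicates` from [run_replicates()] run with
#'   `keep_series = TRUE`.
#' @param dir output directory (created if needed).
#' @param params the parameter set used (stored alongside).
#' @param downsample write every k-th tick row (1 = native resolution).
#' @return character vector of files written, invisibly.
#' @export
write_outputs <- function(replicates, dir, params = default_params(),
                          downsample = 1L) {
  stopifnot(inherits(replicates, "abm_replicates"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (run in replicates$runs) {
    stem <- file.path(dir, sprintf("%s_seed%d", replicates$scenario,
                                   run$seed))
    if (!is.null(run$series)) {
      ser <- run$series
      if (downsample > 1L)
        ser <- ser[seq(1, nrow(ser), by = downsample), , drop = FALSE]
      csv <- paste0(stem, ".csv")
      con <- file(csv, "w")
      writeLines(c(
        paste0("# scenario: ", replicates$scenario),
        paste0("# seed: ", run$seed),
        paste0("# ticks_per_hour: ", attr(run$series, "ticks_per_hour")),
        paste0("# params_hash: ", attr(run$series, "params_hash"))), con)
      write.csv(ser, con, row.names = FALSE)
      close(con)
      files <- c(files, csv)
    }
    rj <- paste0(stem, "_report.json")
    jsonlite::write_json(unclass(run$report), rj, auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, rj)
  }
  sj <- file.path(dir, sprintf("%s_summary.json", replicates$scenario))
  jsonlite::write_json(replicates$summary, sj, auto_unbox = TRUE, digits = NA)
  pj <- file.path(dir, "effective_params.json")
  jsonlite::write_json(c(unclass(params),
                         list(seed_base = replicates$seed_base)),
                       pj, auto_unbox = TRUE, digits = NA)
  files <- c(files, sj, pj)
  invisible(files)
}

#' Plot the tracked channels of a run
#'
#' Small-multiple trajectory panels (one per channel) in the layout used for
#' the published scenario figures.
#'
#' @param series an `abm_series`.
#' @param channels channels to draw.
#' @param normalized rescale each channel to (0, 1) first.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the series.
#' @export
plot_series <- function(series,
                        channels = c("lps_total", "tnf_free", "P", "A", "E",
                                     "nfkb_active"),
                        normalized = FALSE, ...) {
  if (normalized) series <- normalize_series(series)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(channels)),
                       mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  for (cl in channels) {
    graphics::plot(series$hours, series[[cl]], type = "l", lwd = 1.2,
                   xlab = "hours", ylab = cl, main = cl, ...)
  }
  invisible(series)
}
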