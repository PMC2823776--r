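# Tracked quantities and outcome classification.
#
# The engine reports one census row per tick.  Aggregates follow the model's
# definitions: LPS is the total in circulation (bound + free); TNF-a counts
# free molecules only; P is the circulating IL-12 population; A the IL-4/A
# population (free plus receptor-bound); E the summed macrophage energy;
# activated NF-kB/IKK/IkBa are summed over all macrophages.

TS_COLS <- c("tick", "lps_total", "tnf_free", "P", "A", "E", "nfkb_active",
             "ikk_active", "ikba_active", "th0", "th1", "th2")

#' Assemble a time-series table from engine census rows
#'
#' @param mat numeric matrix of engine census rows.
#' @param params parameter set of the run (provides `ticks_per_hour`).
#' @param seed,scenario run metadata stored as attributes.
#' @return data.frame with columns tick, hours, lps_total, tnf_free, P, A, E,
#'   nfkb_active, ikk_active, ikba_active, th0, th1, th2; attributes
#'   `ticks_per_hour`, `seed`, `scenario`, `params_hash`.
#' @export
timeseries_frame <- function(mat, params, seed = NA_integer_,
                             scenario = NA_character_) {
  colnames(mat) <- TS_COLS
  df <- as.data.frame(mat)
  df <- cbind(df[1], hours = df$tick / params$ticks_per_hour,
              df[-1])
  attr(df, "ticks_per_hour") <- params$ticks_per_hour
  attr(df, "seed") <- seed
  attr(df, "scenario") <- scenario
  attr(df, "params_hash") <- params_hash(params)
  class(df) <- c("abm_series", "data.frame")
  df
}

params_hash <- function(params) {
  s <- paste(names(params), vapply(params, format, ""), sep = "=",
             collapse = ";")
  # small deterministic polynomial hash; identity marker, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

channel_cols <- function() setdiff(TS_COLS, "tick")

#' Normalize a time series to (0, 1)
#'
#' Divides every channel by its own run maximum (the convention used when
#' comparing trajectories across models); all-zero channels stay all-zero.
#'
#' @param series an `abm_series` (or any data.frame with the same columns).
#' @return the rescaled series; non-zero channels have maximum exactly 1.
#' @export
normalize_series <- function(series) {
  for (cl in channel_cols()) {
    m <- max(series[[cl]])
    if (m > 0) series[[cl]] <- series[[cl]] / m
  }
  series
}

#' Stimulus clearance time
#'
#' First time at which total LPS (bound + free) reaches zero and remains zero
#' for the rest of the run, in hours; `NA` if the stimulus is never cleared.
#'
#' @param series an `abm_series`.
#' @return hours, or `NA_real_`.
#' @export
clearance_time <- function(series) {
  lps <- series$lps_total
  n <- length(lps)
  nz <- which(lps > 0)
  if (length(nz) == 0) return(series$hours[1])
  last_nz <- max(nz)
  if (last_nz == n) return(NA_real_)
  series$hours[last_nz + 1]
}

#' Classify a run as resolved or unconstrained
#'
#' A run is resolved when the pro-inflammatory channels P (circulating
#' IL-12), free TNF-a and activated NF-kB each return to within
#' `tol` x (run peak) of their pre-dose baseline (the tick-0 census) and stay
#' there through the horizon for at least `hold_hours`.  Unresolved runs are
#' the complementary attractor: one or more channels settle at a sustained
#' elevated level.
#'
#' @param series an `abm_series`.
#' @param tol relative tolerance band, fraction of each channel's run peak.
#' @param hold_hours minimum time the channels must hold baseline through the
#'   end of the run.
#' @param require_clearance a self-limited episode means successful
#'   elimination of the stimulus followed by transcriptional resolution, so
#'   by default a run whose total LPS never reaches zero is classified
#'   unresolved no matter how quiet its mediator channels are; set to `FALSE`
#'   to classify on the mediator channels alone.
#' @return list of class `abm_outcome`: `resolved`, `clearance_time_hours`,
#'   `resolution_time_hours` (`NA` when unresolved), `peaks` (named vector of
#'   per-channel run maxima), `horizon_hours`.
#' @export
classify_outcome <- function(series, tol = 0.05, hold_hours = 1,
                             require_clearance = TRUE) {
  stopifnot(tol > 0, tol < 1, hold_hours >= 0)
  chans <- c("P", "tnf_free", "nfkb_active")
  n <- nrow(series)
  in_band <- rep(TRUE, n)
  for (cl in chans) {
    x <- series[[cl]]
    band <- tol * max(x)
    in_band <- in_band & (abs(x - x[1]) <= band)
  }
  horizon <- series$hours[n]
  # latest entry time T with all later ticks in band
  if (!in_band[n]) {
    entry <- NA_real_
  } else {
    out <- which(!in_band)
    entry_idx <- if (length(out) == 0) 1L else max(out) + 1L
    entry <- series$hours[entry_idx]
  }
  resolved <- !is.na(entry) && (horizon - entry) >= hold_hours
  cl_t <- clearance_time(series)
  if (require_clearance && is.na(cl_t)) resolved <- FALSE
  peaks <- vapply(channel_cols(), function(cl) max(series[[cl]]), 0)
  structure(list(resolved = resolved,
                 clearance_time_hours = cl_t,
                 resolution_time_hours = if (resolved) entry else NA_real_,
                 peaks = peaks, horizon_hours = horizon,
                 tol = tol, hold_hours = hold_hours),
            class = "abm_outcome")
}

#' @export
print.abm_outcome <- function(x, ...) {
  cat("<abm_outcome>",
      if (x$resolved) "resolved" else "unresolved (sustained inflammation)",
      "\n  clearance:",
      if (is.na(x$clearance_time_hours)) "never"
      else sprintf("%.2f h", x$clearance_time_hours),
      "\n  resolution:",
      if (is.na(x$resolution_time_hours)) "none within horizon"
      else sprintf("%.2f h", x$resolution_time_hours),
      sprintf("(horizon %.0f h)\n", x$horizon_hours))
  invisible(x)
}

#' Summarize replicate outcomes
#'
#' @param reports list of `abm_outcome` objects.
#' @return list: `n`, `fraction_resolved`, medians and interquartile ranges
#'   of clearance and resolution times (over replicates where defined).
#' @export
summarize_replicates <- function(reports) {
  res <- vapply(reports, function(r) r$resolved, TRUE)
  cl <- vapply(reports, function(r) r$clearance_time_hours, 0)
  rt <- vapply(reports, function(r) r$resolution_time_hours, 0)
  iqr3 <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  }
  list(n = length(reports),
       fraction_resolved = mean(res),
       clearance_hours = setNames(iqr3(cl), c("q25", "median", "q75")),
       resolution_hours = setNames(iqr3(rt), c("q25", "median", "q75")))
}
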