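# Shared fixtures and a lazy cache of scenario replicate batteries, so the
# acceptance properties reuse one set of seeded runs instead of re-simulating
# per test block.

# reduced single-cell parameter sets for rule-level fixtures
mini_params <- function(...) {
  default_params(n_macrophages = 1, n_tlr4 = 0, n_tnfr = 0, n_il4r = 0,
                 nfkb_per_cell = 0, ...)
}

# a world with no cells at all; molecules can be injected via `add_mols`
no_cell_params <- function(...) {
  default_params(n_macrophages = 0, ...)
}

# append molecule rows to a world state (types as in MOL_TYPE codes)
add_mols <- function(world, type, state, x, y, mac = -1L, t1 = 0L, t2 = 0L,
                     partner = -1L) {
  rows <- data.frame(type = as.integer(type), state = as.integer(state),
                     mac = as.integer(mac), x = x, y = y,
                     t1 = as.integer(t1), t2 = as.integer(t2),
                     partner = as.integer(partner))
  world$state$mols <- rbind(world$state$mols, rows)
  world
}

lps_dose <- function(amount, hours = 0) {
  data.frame(time_hours = hours, species = "LPS", amount = amount)
}

# ---- replicate batteries (cached across test files) -----------------------

battery_cache <- new.env(parent = emptyenv())

# per-seed outcome statistics for a builtin scenario under shipped defaults
scenario_battery <- function(name, seeds = 1:20) {
  key <- paste0(name, "_", min(seeds), "_", max(seeds))
  if (!is.null(battery_cache[[key]])) return(battery_cache[[key]])
  rows <- lapply(seeds, function(sd) {
    s <- run_scenario(builtin_scenario(name), default_params(), seed = sd)
    o <- classify_outcome(s)
    data.frame(seed = sd,
               resolved = o$resolved,
               clearance = o$clearance_time_hours,
               resolution = o$resolution_time_hours,
               tnf_peak = max(s$tnf_free),
               tnf_peak_post8h = max(s$tnf_free[s$hours >= 8]),
               nfkb_total_end = sum(tail(s, 1)[, c("nfkb_active")]))
  })
  out <- do.call(rbind, rows)
  battery_cache[[key]] <- out
  out
}
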