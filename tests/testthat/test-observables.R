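# Census definitions, normalization, clearance and outcome classification.

# build a series frame from hand-written channel vectors
mk_series <- function(n, tph = 800, ...) {
  chans <- list(...)
  mat <- matrix(0, n, 12)
  colnames(mat) <- c("tick", "lps_total", "tnf_free", "P", "A", "E",
                     "nfkb_active", "ikk_active", "ikba_active",
                     "th0", "th1", "th2")
  mat[, "tick"] <- 0:(n - 1)
  for (nm in names(chans)) mat[, nm] <- chans[[nm]]
  timeseries_frame(mat, default_params(ticks_per_hour = tph))
}

test_that("the census counts follow the model's aggregate definitions", {
  p <- default_params(energy_init = 100)
  w <- world_new(p, seed = 1)
  # 3 free + 2 bound LPS -> lps_total 5; 4 free + 1 bound TNF -> tnf_free 4
  w <- add_mols(w, type = 0L, state = c(0L, 0L, 0L, 1L, 1L),
                x = 1:5, y = 1:5, t1 = 2L)
  w <- add_mols(w, type = 1L, state = c(0L, 0L, 0L, 0L, 1L),
                x = 6:10, y = 6:10, t1 = 50L)
  w <- world_step(w, 0)          # census only, no rules executed
  row <- tail(w$series, 1)
  expect_equal(row$lps_total, 5)
  expect_equal(row$tnf_free, 4)
  expect_equal(row$E, 400)       # four macrophages at energy 100
  expect_equal(row$nfkb_active, 0)
})

test_that("activated signaling molecules are summed over all macrophages", {
  w <- world_new(default_params(), seed = 2)
  st <- w$state
  # activate three NF-kB across different cells by direct state edit
  idx <- c(1, 121, 241)
  st$mols$state[idx] <- 2L
  w$state <- st
  w <- world_step(w, 0)
  expect_equal(tail(w$series$nfkb_active, 1), 3)
})

test_that("normalization is per-channel max-scaling with an all-zero rule", {
  s <- mk_series(4, tnf_free = c(0, 5, 10, 5), P = c(0, 0, 0, 0),
                 E = c(2, 2, 2, 2))
  n <- normalize_series(s)
  expect_equal(n$tnf_free, c(0, 0.5, 1, 0.5))
  expect_equal(n$P, rep(0, 4))                 # no division by zero
  expect_equal(max(n$E), 1)
  nonzero <- vapply(c("tnf_free", "E"), function(cl) max(n[[cl]]), 0)
  expect_true(all(nonzero == 1))
})

test_that("clearance time is the first tick LPS stays at zero", {
  s <- mk_series(5, lps_total = c(0, 0, 0, 0, 0))
  expect_equal(clearance_time(s), 0)
  lps <- c(rep(5, 600), rep(0, 401))
  s <- mk_series(1001, lps_total = lps)
  expect_equal(clearance_time(s), 600 / 800)   # 0.75 h at 800 ticks per hour
  s <- mk_series(100, lps_total = rep(1, 100))
  expect_true(is.na(clearance_time(s)))
  # transient zero followed by recurrence does not count
  s <- mk_series(10, lps_total = c(1, 0, 0, 2, 1, 1, 0, 0, 0, 1))
  expect_true(is.na(clearance_time(s)))
})

test_that("classification detects return-to-baseline with a hold window", {
  tph <- 100
  n <- 24 * tph + 1
  # all channels flat at baseline: resolved instantly
  s <- mk_series(n, tph = tph)
  o <- classify_outcome(s)
  expect_true(o$resolved)
  expect_equal(o$resolution_time_hours, 0)
  # P peaks then returns at 10 h and holds
  p_curve <- c(seq(0, 1000, length.out = 2 * tph),
               seq(1000, 0, length.out = 8 * tph + 1)[-1])
  p_curve <- c(p_curve, rep(0, n - length(p_curve)))
  s <- mk_series(n, tph = tph, P = p_curve)
  o <- classify_outcome(s)
  expect_true(o$resolved)
  expect_equal(o$resolution_time_hours, 10, tolerance = 0.05)
  # NF-kB plateaued at 60% of its peak: a sustained elevated attractor
  nf <- c(seq(0, 100, length.out = 2 * tph), rep(60, n - 2 * tph))
  s <- mk_series(n, tph = tph, nfkb_active = nf)
  o <- classify_outcome(s)
  expect_false(o$resolved)
  expect_true(is.na(o$resolution_time_hours))
})

test_that("classification is invariant to per-channel rescaling", {
  tph <- 100
  n <- 24 * tph + 1
  p_curve <- c(seq(0, 500, length.out = 3 * tph),
               seq(500, 0, length.out = 9 * tph + 1)[-1])
  p_curve <- c(p_curve, rep(0, n - length(p_curve)))
  s1 <- mk_series(n, tph = tph, P = p_curve, tnf_free = 2 * p_curve)
  s2 <- mk_series(n, tph = tph, P = 10 * p_curve, tnf_free = 0.2 * p_curve)
  o1 <- classify_outcome(s1); o2 <- classify_outcome(s2)
  expect_equal(o1$resolved, o2$resolved)
  expect_equal(o1$resolution_time_hours, o2$resolution_time_hours)
})

test_that("a run with stimulus left in the system is not a resolved episode", {
  tph <- 100
  n <- 24 * tph + 1
  s <- mk_series(n, tph = tph, lps_total = rep(3, n))
  expect_false(classify_outcome(s)$resolved)
  expect_true(classify_outcome(s, require_clearance = FALSE)$resolved)
})

test_that("replicate summaries aggregate outcome reports", {
  tph <- 100; n <- 24 * tph + 1
  mk <- function(lps0) mk_series(n, tph = tph,
                                 lps_total = c(lps0, rep(0, n - 1)))
  reports <- list(classify_outcome(mk(5)), classify_outcome(mk(9)))
  sm <- summarize_replicates(reports)
  expect_equal(sm$n, 2)
  expect_equal(sm$fraction_resolved, 1)
  expect_equal(unname(sm$clearance_hours[["median"]]), 1 / tph)
})

test_that("NF-kB is conserved per macrophage through a full dosed run", {
  p <- default_params()
  w <- world_new(p, seed = 11, doses = lps_dose(350))
  for (k in 1:4) {
    w <- world_step(w, 400)
    st <- w$state
    nfkb <- st$mols[st$mols$type == 5, ]
    expect_equal(as.integer(table(factor(nfkb$mac, levels = 0:3))),
                 rep(p$nfkb_per_cell, 4))
  }
})

test_that("the IkBa ledger balances production against its sinks", {
  w <- world_new(default_params(), seed = 12, doses = lps_dose(350))
  w <- world_step(w, 2000)
  st <- w$state
  ct <- st$counters   # ubiquitinated, transcribed, re-bound, turned over
  initial <- 4 * default_params()$nfkb_per_cell
  complexed_now <- sum(st$mols$type == 5 & st$mols$state %in% c(0, 1))
  free_now <- sum(st$mols$type == 6)
  expect_gt(ct[2], 0)
  expect_equal(initial + ct[2], ct[1] + complexed_now + free_now + ct[4])
})
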