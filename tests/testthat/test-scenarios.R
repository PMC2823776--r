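# Builtin dosing schedules, replicate runner, calibration harness.

test_that("builtin scenarios carry the published dose schedules exactly", {
  expect_equal(builtin_scenario("self_limited")$doses,
               data.frame(time_hours = 0, species = "LPS", amount = 350))
  expect_equal(builtin_scenario("high_dose")$doses$amount, 750)
  expect_equal(builtin_scenario("persistent_infectious")$doses$amount, 1000)
  expect_equal(builtin_scenario("tolerance")$doses,
               data.frame(time_hours = c(0, 8), species = c("LPS", "LPS"),
                          amount = c(100, 650)))
  expect_equal(builtin_scenario("potentiation")$doses,
               data.frame(time_hours = c(0, 2), species = c("LPS", "LPS"),
                          amount = c(100, 250)))
  expect_equal(builtin_scenario("two_hit")$doses,
               data.frame(time_hours = c(0, 0), species = c("LPS", "TNF"),
                          amount = c(350, 300)))
  expect_equal(builtin_scenario("ikk_inhibitor")$doses,
               data.frame(time_hours = c(0, 0),
                          species = c("LPS", "IKK_inhibitor"),
                          amount = c(750, 400)))
  expect_equal(builtin_scenario("self_limited")$run_hours, 24)
  expect_error(builtin_scenario("sepsis"), "self_limited.*tolerance")
})

test_that("a zero-dose run is a homeostatic fixed point", {
  s <- run_scenario(scenario_spec("none", lps_dose(0), run_hours = 4),
                    seed = 1)
  for (cl in c("lps_total", "tnf_free", "P", "A", "nfkb_active",
               "ikk_active", "ikba_active", "th0", "th1", "th2"))
    expect_true(all(s[[cl]] == 0), label = paste(cl, "flat at zero"))
  expect_equal(length(unique(s$E)), 1)   # energy constant
})

test_that("replicates are independently seeded and summarized", {
  spec <- scenario_spec("mini", lps_dose(150), run_hours = 1)
  rr <- run_replicates(spec, n = 3, seed_base = 5, keep_series = TRUE)
  expect_equal(vapply(rr$runs, `[[`, 0L, "seed"), 5:7)
  expect_false(identical(rr$runs[[1]]$series$tnf_free,
                         rr$runs[[2]]$series$tnf_free))
  expect_true(rr$summary$fraction_resolved >= 0 &&
                rr$summary$fraction_resolved <= 1)
  # n = 1 summary equals the single run's report
  r1 <- run_replicates(spec, n = 1, seed_base = 5)
  expect_equal(r1$summary$fraction_resolved,
               as.numeric(r1$runs[[1]]$report$resolved))
  expect_equal(unname(r1$summary$clearance_hours[["median"]]),
               r1$runs[[1]]$report$clearance_time_hours)
})

test_that("the shipped defaults pass their own calibration pattern", {
  out <- calibrate(list(lps_step = default_params()$lps_step),
                   n_replicates = 2, seed_base = 1)
  expect_equal(nrow(out), 1)
  expect_equal(out$fraction_pass, 1)
  expect_lte(out$median_clearance_h, 2)
  expect_lte(out$median_resolution_h, 24)
})

test_that("a degenerate parameter point fails calibration with diagnostics", {
  # no IKK:NF-kB binding: no transcription, no resolution dynamics to score
  err <- tryCatch(
    calibrate(list(p_bind_ikk = 0), n_replicates = 1, seed_base = 1),
    abm_calibration_failure = function(e) e)
  expect_s3_class(err, "abm_calibration_failure")
  expect_true(is.data.frame(attr(err, "diagnostics")) ||
                is.data.frame(err$diagnostics))
  expect_match(conditionMessage(err), "p_bind_ikk")
})

test_that("unknown grid parameters are rejected by name", {
  expect_error(calibrate(list(p_bogus = 1)), "p_bogus")
})
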