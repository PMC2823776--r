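# Macrophage composition, energy switch, T-helper rules.

test_that("a default macrophage comprises more than 400 constituent agents", {
  set.seed(1)
  m <- build_macrophage(c(80, 80))
  expect_equal(m$n_constituents, 240 + 60 + 120)
  expect_gt(m$n_constituents, 400)
  expect_equal(nrow(m$membrane), 240)
  expect_equal(sum(m$receptors$type == "TLR4"), 30)
  expect_equal(sum(m$receptors$type == "TNFR"), 15)
  expect_equal(sum(m$receptors$type == "IL4R"), 15)
  expect_equal(nrow(m$intracellular), 120)
  expect_equal(m$switch_on, FALSE)
})

test_that("an undersized composition is rejected at construction", {
  expect_error(build_macrophage(c(80, 80),
                                default_params(membrane_count = 50)),
               "more than 400")
  # reduced fixtures may opt out explicitly
  expect_no_error(build_macrophage(c(80, 80),
                                   default_params(membrane_count = 50),
                                   check = FALSE))
})

test_that("receptors sit on the membrane ring at full sensitivity", {
  set.seed(1)
  p <- default_params()
  m <- build_macrophage(c(80, 80), p)
  expect_true(all(m$receptors$sensitivity[m$receptors$type == "TLR4"] ==
                    p$sensitivity_max))
  rx <- 80 + p$cell_radius * cos(m$receptors$angle)
  ry <- 80 + p$cell_radius * sin(m$receptors$angle)
  expect_equal(torus_distance(rx, ry, 80, 80), rep(p$cell_radius, 60))
  # intracellular complexes are in the cytosol: outside the nucleus,
  # inside the membrane
  d <- torus_distance(m$intracellular$x, m$intracellular$y, 80, 80)
  expect_true(all(d < p$cell_radius & d >= p$nucleus_radius))
})

test_that("the energy switch is on strictly below 25% of initial energy", {
  # crossing from 25 to 24 of 100 flips the switch on
  u <- energy_update(25, 100, "transcription_cycle")
  expect_equal(u$energy, 24)
  expect_true(u$switch_on)
  # exactly 25 is not below 25%
  u <- energy_update(24, 100, "il4_binding")
  expect_equal(u$energy, 25)
  expect_false(u$switch_on)
  # floor at zero
  u <- energy_update(0, 100, "transcription_cycle")
  expect_equal(u$energy, 0)
  expect_error(energy_update(10, 100, "mitosis"), "unknown energy event")
})

test_that("Th0 differentiates at 25 bound interleukins by majority", {
  expect_equal(th0_differentiate(13, 12), "Th1")
  expect_equal(th0_differentiate(12, 13), "Th2")
  expect_equal(th0_differentiate(12, 12), "Th0")   # 24 < 25
  expect_equal(th0_differentiate(25, 0), "Th1")
  expect_equal(th0_differentiate(0, 25), "Th2")
})

test_that("the differentiation rule matches brute-force enumeration to 60", {
  # independent reference: a literal transcription of the published sentence
  reference <- function(il12, il4) {
    if (il12 + il4 >= 25) {
      if (il12 > il4) "Th1" else "Th2"
    } else "Th0"
  }
  grid <- expand.grid(il12 = 0:60, il4 = 0:60)
  grid <- grid[grid$il12 + grid$il4 <= 60, ]
  want <- mapply(reference, grid$il12, grid$il4)
  got <- th0_differentiate(grid$il12, grid$il4)
  expect_identical(unname(got), unname(want))
  # ties at or above threshold fall to Th2 ("otherwise")
  expect_equal(th0_differentiate(13, 13), "Th2")
})

test_that("a Th1 cell secretes IL-12 on its interval and Th0 secretes nothing", {
  p <- no_cell_params(p_il4 = 0)   # silence world IL-4 so P is pure Th output
  w <- world_new(p, seed = 2)
  w$state$ths <- data.frame(kind = 1L, x = 40, y = 40, il12 = 0L, il4 = 0L,
                            clock = 0L, age = 0L)
  w <- world_step(w, 500)
  expect_equal(tail(w$series$P, 1), 5)   # one unit per 100 ticks
  w0 <- world_new(p, seed = 2)
  w0$state$ths <- data.frame(kind = 0L, x = 40, y = 40, il12 = 0L, il4 = 0L,
                             clock = 0L, age = 0L)
  w0 <- world_step(w0, 500)
  expect_equal(max(w0$series$P), 0)
  expect_equal(max(w0$series$A), 0)
})

test_that("engine Th0 differentiation follows the surface-count rule", {
  # flood a lone Th0 with IL-12: it must become Th1, irreversibly
  p <- no_cell_params(p_il4 = 0, th0_entry_threshold = 1e6)
  w <- build_fixture("th_unit", seed = 3, params = p)
  th <- w$state$ths
  set.seed(3)
  ang <- runif(200) * 2 * pi; r <- runif(200) * 3
  w <- add_mols(w, type = 2L, state = 0L,
                x = (th$x + r * cos(ang)) %% 161,
                y = (th$y + r * sin(ang)) %% 161, t1 = 800L)
  w <- world_step(w, 400)
  expect_equal(tail(w$series$th1, 1), 1)
  expect_equal(tail(w$series$th0, 1), 0)
  expect_gte(w$state$ths$il12[1], 25)
  # surface counts freeze at differentiation; kind never reverts
  w <- world_step(w, 400)
  expect_equal(w$state$ths$kind[1], 1L)
})

test_that("IL-4 binding to a macrophage receptor raises its energy by one", {
  p <- default_params(n_macrophages = 1, n_tlr4 = 0, n_tnfr = 0, n_il4r = 15,
                      nfkb_per_cell = 0, p_il4 = 0, energy_init = 100,
                      mol_step = 0.5, energy_recovery_ticks = 1e6)
  w <- world_new(p, seed = 5, check_composition = FALSE)
  w$state$macs$energy <- 50   # below cap so the +1 credit is visible
  rc <- w$state$receptors[1, ]
  pos <- wrap_position(w$state$macs$cx[1] + p$cell_radius * cos(rc$angle),
                       w$state$macs$cy[1] + p$cell_radius * sin(rc$angle))
  w <- add_mols(w, type = 3L, state = 0L, x = pos$x, y = pos$y, t1 = 800L)
  w <- world_step(w, 5)
  expect_equal(w$state$macs$energy, 51)
  expect_equal(sum(w$state$receptors$il4_left > 0), 1)
  expect_equal(sum(w$state$mols$type == 3), 0)   # absorbed by the receptor
})

test_that("cytokines are species-specific: IL-12 never binds an IL-4 receptor", {
  p <- default_params(n_macrophages = 1, n_tlr4 = 0, n_tnfr = 0, n_il4r = 15,
                      nfkb_per_cell = 0, p_il4 = 0, energy_init = 100)
  w <- world_new(p, seed = 6, check_composition = FALSE)
  set.seed(6)
  ang <- runif(100) * 2 * pi
  w <- add_mols(w, type = 2L, state = 0L,
                x = (w$state$macs$cx[1] + (p$cell_radius + 1) * cos(ang)) %% 161,
                y = (w$state$macs$cy[1] + (p$cell_radius + 1) * sin(ang)) %% 161,
                t1 = 800L)
  w <- world_step(w, 300)
  expect_true(all(w$series$E == 100))           # no energy credit
  expect_true(all(w$state$receptors$il4_left == 0))
})

test_that("Th0 recruitment requires circulating P above its threshold", {
  # homeostasis: without any stimulus no T helper ever enters the world
  s <- run_scenario(scenario_spec("none", lps_dose(0), run_hours = 2),
                    seed = 7)
  expect_true(all(s$th0 + s$th1 + s$th2 == 0))
})
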