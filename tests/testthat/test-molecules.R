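# Molecule state machines and the stochastic interaction rules.

se3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)

test_that("the sensitivity rule matches its exact enumeration", {
  # oracle: enumerate the 5 equiprobable draws 1..5 against strict <
  enum_p <- function(s, inclusive = FALSE) {
    draws <- 1:5
    mean(if (inclusive) draws <= s else draws < s)
  }
  for (s in 0:5) {
    expect_equal(lps_binding_prob(s), enum_p(s))
    expect_equal(lps_binding_prob(s, default_params(sensitivity_inclusive = TRUE)),
                 enum_p(s, TRUE))
  }
  expect_equal(lps_binding_prob(1), 0)      # no draw in 1..5 is < 1
  expect_equal(lps_binding_prob(5), 4 / 5)
})

test_that("seeded binding trials reproduce the enumerated probabilities", {
  n <- 10000
  f3 <- attempt_lps_binding(n, 3, seed = 1) / n
  expect_lt(abs(f3 - 0.4), se3(0.4, n))
  f5 <- attempt_lps_binding(n, 5, seed = 1) / n
  expect_lt(abs(f5 - 0.8), se3(0.8, n))
  expect_equal(attempt_lps_binding(n, 1, seed = 1), 0)
  # inclusive variant shifts every probability up by exactly one draw
  p_inc <- default_params(sensitivity_inclusive = TRUE)
  f3i <- attempt_lps_binding(n, 3, seed = 1, p_inc) / n
  expect_lt(abs(f3i - 0.6), se3(0.6, n))
})

test_that("bound LPS degrades within two ticks and frees its receptor", {
  d <- lps_decay_draws(10000, seed = 1)
  expect_true(all(d %in% 1:2))
  expect_lt(abs(mean(d) - 1.5), 3 * 0.5 / 100)
})

test_that("IKK lifetimes are uniform on 1..799 ticks", {
  d <- ikk_lifetime_draws(10000, seed = 1)
  expect_true(all(d >= 1 & d <= 799))
  expect_lt(abs(mean(d) - 400), 7)   # 3 SE of the uniform mean
})

test_that("IKK binds an inactive NF-kB complex with 70% probability", {
  n <- 10000
  f <- ikk_bind_nfkb_trials(n, seed = 1) / n
  expect_lt(abs(f - 0.7), se3(0.7, n))
})

test_that("transcription cycles emit 1 IkBa, 1 TNF-a and IL-12 at 80%", {
  out <- nfkb_transcribe_trials(1000, seed = 1)
  expect_equal(out$ikba, 1000)     # exactly one inhibitor per cycle
  expect_equal(out$tnf, 1000)      # exactly one TNF-a per cycle
  expect_lt(abs(out$il12 / 1000 - 0.8), se3(0.8, 1000))
  # while the energy switch is on, TNF-a output is amplified
  amp <- nfkb_transcribe_trials(10, seed = 1, switch_on = TRUE)
  expect_equal(amp$tnf, 10 * default_params()$tnf_amplified)
})

test_that("IL-4 production yields 3-unit bursts at 86% every 1-5 ticks", {
  n <- 10000
  out <- il4_production_trials(n, seed = 1)
  expect_true(all(out$yields %in% c(0, 3)))
  expect_lt(abs(mean(out$yields) - 3 * 0.86), 0.05)
  expect_true(all(out$intervals %in% 1:5))
  expect_lt(abs(mean(out$intervals) - 3), 0.1)
  boosted <- il4_production_trials(1000, seed = 1, boost = TRUE)
  expect_true(all(boosted$yields %in% c(0, 3 * default_params()$a_boost)))
})

test_that("free TNF-a lives exactly its 600-tick budget", {
  w <- world_new(no_cell_params(), seed = 7,
                 doses = data.frame(time_hours = 0, species = "TNF",
                                    amount = 1))
  w <- world_step(w, 650)
  tnf <- w$series$tnf_free
  # injected during the first tick, then ticks down its 600-tick budget
  expect_equal(tnf[601], 1)        # alive with the budget not yet spent
  expect_equal(tnf[602], 0)        # removed exactly when the budget hits 0
  expect_true(all(tnf[seq(2, 601)] == 1))
})

test_that("bound TNF-a is removed 50 ticks after binding, 200 with bound IL-4", {
  run_bound_tnf <- function(il4_bound) {
    # near-zero step keeps the molecule in the receptor's contact band
    p <- default_params(n_macrophages = 1, n_tlr4 = 0, n_tnfr = 1,
                        n_il4r = 1, nfkb_per_cell = 0, mol_step = 0.1)
    w <- world_new(p, seed = 4, check_composition = FALSE)
    if (il4_bound) w$state$receptors$il4_left[w$state$receptors$type == 2] <- 5000L
    # place one TNF right on the TNFR so it binds on its first move
    rc <- w$state$receptors[w$state$receptors$type == 1, ]
    pos <- wrap_position(w$state$macs$cx[1] + p$cell_radius * cos(rc$angle),
                         w$state$macs$cy[1] + p$cell_radius * sin(rc$angle))
    w <- add_mols(w, type = 1, state = 0, x = pos$x, y = pos$y, t1 = 600)
    bind_tick <- NA
    for (k in 1:20) {
      w <- world_step(w, 1)
      if (any(w$state$mols$type == 1 & w$state$mols$state == 1)) {
        bind_tick <- w$state$tick
        break
      }
    }
    expect_false(is.na(bind_tick))
    expected <- if (il4_bound) 200 else 50
    w <- world_step(w, expected - 1)
    expect_true(any(w$state$mols$type == 1))   # one tick before removal
    w <- world_step(w, 1)
    expect_false(any(w$state$mols$type == 1))  # removed exactly on schedule
    expect_true(all(w$state$receptors$tnf_left == 0))
  }
  run_bound_tnf(il4_bound = FALSE)
  run_bound_tnf(il4_bound = TRUE)
})

test_that("IKK-inhibitor consumption is 1:1 and bounded by IKK supply", {
  p <- mini_params()
  w <- world_new(p, seed = 6, check_composition = FALSE,
                 doses = data.frame(time_hours = 0, species = "IKK_inhibitor",
                                    amount = 400))
  ticks <- 2000
  w <- world_step(w, ticks)
  produced <- floor(ticks / p$ikk_prod_interval) + 1
  consumed <- 400 - sum(w$state$mols$type == 7)
  expect_gt(consumed, 0)
  expect_lte(consumed, produced)
  # every consumption deactivated one kinase permanently
  dead_or_deact <- consumed
  alive_deact <- sum(w$state$mols$type == 4 & w$state$mols$state == 3)
  expect_lte(alive_deact, dead_or_deact)
})

test_that("an inhibitor with no IKK to find persists and keeps walking", {
  w <- world_new(no_cell_params(), seed = 8,
                 doses = data.frame(time_hours = 0, species = "IKK_inhibitor",
                                    amount = 5))
  w <- world_step(w, 500)
  expect_equal(sum(w$state$mols$type == 7), 5)
})
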