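test_that("a zero-dose regimen produces identically zero drug everywhere", {
  ph <- fx_phys("NZ_rabbit")
  sim <- simulate_ocular(fx_drug("levofloxacin"), ph$ocular, ph$systemic,
                         dose_regimen(0, 0, 0), t_grid = c(0.5, 1, 2))
  expect_true(all(sim$amounts == 0))
  expect_true(all(sim$ledgers == 0))
  expect_equal(mass_balance(sim), 0)
})

test_that("with zero permeabilities pre-cornea drug follows the drainage closed form", {
  ph <- fx_phys("NZ_rabbit")
  lev <- fx_drug("levofloxacin")
  lev$perm_cm_s[] <- 0
  tg <- c(0.002, 0.005, 0.01, 0.02, 0.03, 0.05, 0.08, 0.12)
  sim <- simulate_ocular(lev, ph$ocular, ph$systemic, fx_single_drop(),
                         t_grid = tg)
  v_t <- 5 + 30 * exp(-60 * tg)              # uL
  a_t <- 150 * v_t / 35                      # A = A0 V(t)/V0
  got <- sim$amounts[match(tg, sim$time), "precornea"]
  expect_equal(got, a_t, tolerance = 1e-4)
  expect_equal(sim$precornea_volume_uL[match(tg, sim$time)], v_t,
               tolerance = 1e-6)
  # concentration in the shrinking film stays constant
  cpre <- sim$conc[match(tg, sim$time), "precornea"]
  expect_equal(cpre, rep(150 / 0.035, length(tg)), tolerance = 1e-4)
})

test_that("concentrations scale exactly with dose strength", {
  ph <- fx_phys("NZ_rabbit")
  lev <- fx_drug("levofloxacin")
  tg <- c(0.5, 2, 8, 24)
  s1 <- simulate_ocular(lev, ph$ocular, ph$systemic,
                        dose_regimen(0, 30, 0.5), t_grid = tg)
  s2 <- simulate_ocular(lev, ph$ocular, ph$systemic,
                        dose_regimen(0, 30, 1.0), t_grid = tg)
  expect_equal(s2$conc, 2 * s1$conc, tolerance = 1e-6)
})

test_that("superposition holds for regimens sharing a fluid-event schedule", {
  # the tear-film volume trajectory is set by drop volumes and times, so
  # two regimens with the same fluid events but complementary strengths
  # sum linearly
  ph <- fx_phys("NZ_rabbit")
  lev <- fx_drug("levofloxacin")
  tg <- c(0.5, 1.5, 4, 12)
  sA <- simulate_ocular(lev, ph$ocular, ph$systemic,
                        dose_regimen(c(0, 1), 30, c(0.5, 0)), t_grid = tg)
  sB <- simulate_ocular(lev, ph$ocular, ph$systemic,
                        dose_regimen(c(0, 1), 30, c(0, 0.3)), t_grid = tg)
  sAB <- simulate_ocular(lev, ph$ocular, ph$systemic,
                         dose_regimen(c(0, 1), 30, c(0.5, 0.3)), t_grid = tg)
  expect_equal(sAB$amounts, sA$amounts + sB$amounts, tolerance = 1e-6)
})

test_that("mass balance stays below 1e-6 across representative scenarios", {
  scenarios <- list(
    list(api = "levofloxacin", sp = "NZ_rabbit", reg = fx_single_drop()),
    list(api = "moxifloxacin", sp = "DB_rabbit",
         reg = expand_regimen("q15minx3", 24)),
    list(api = "gatifloxacin", sp = "human",
         reg = expand_regimen("QIDx1d", 30, strength_pct = 0.3))
  )
  for (sc in scenarios) {
    ph <- fx_phys(sc$sp)
    sim <- simulate_ocular(fx_drug(sc$api), ph$ocular, ph$systemic, sc$reg,
                           t_grid = seq(0.5, 30, by = 2.5))
    expect_lt(mass_balance(sim), 1e-6)
  }
  # decoupled variant books drained/absorbed as terminal sinks
  ph <- fx_phys("NZ_rabbit")
  sim <- simulate_ocular(fx_drug("levofloxacin"), ph$ocular, ph$systemic,
                         fx_single_drop(), t_grid = c(1, 8, 24),
                         options = sim_options(couple_systemic = FALSE))
  expect_lt(mass_balance(sim), 1e-6)
})

test_that("pigmentation flags are inert when the melanin unbound fraction is 1", {
  lev <- fx_drug("levofloxacin")
  tg <- c(0.5, 2, 8, 24)
  opts <- sim_options(fu_melanin_override = 1)
  nz <- fx_phys("NZ_rabbit"); db <- fx_phys("DB_rabbit")
  s_nz <- simulate_ocular(lev, nz$ocular, nz$systemic, fx_single_drop(),
                          t_grid = tg, options = opts)
  s_db <- simulate_ocular(lev, db$ocular, db$systemic, fx_single_drop(),
                          t_grid = tg, options = opts)
  expect_equal(s_nz$conc, s_db$conc, tolerance = 1e-10)
})

test_that("melanin binding raises peak pigmented-tissue exposure", {
  # binding throttles the unbound back-flux out of the iris-ciliary body,
  # so total drug accumulates to a higher peak than in the unbound case
  lev <- fx_drug("levofloxacin")
  tg <- c(0.5, 1, 2, 4, 8, 24)
  db <- fx_phys("DB_rabbit")
  bound <- simulate_ocular(lev, db$ocular, db$systemic, fx_single_drop(),
                           t_grid = tg)
  free <- simulate_ocular(lev, db$ocular, db$systemic, fx_single_drop(),
                          t_grid = tg,
                          options = sim_options(fu_melanin_override = 1))
  expect_gt(max(bound$conc[, "ICB"]), 2 * max(free$conc[, "ICB"]))
})

test_that("unbound concentration applies the melanin fraction only when pigmented", {
  lev <- fx_drug("levofloxacin")
  db <- fx_phys("DB_rabbit")$ocular
  nz <- fx_phys("NZ_rabbit")$ocular
  expect_equal(unbound_concentration("ICB", 10, lev, db), 0.01)
  expect_equal(unbound_concentration("ICB", 10, lev, nz), 10)
  lev1 <- lev; lev1$fu_melanin <- 1
  for (cc in ocular_compartments())
    expect_equal(unbound_concentration(cc, 10, lev1, db), 10)
})

test_that("halving solver tolerances leaves exposure metrics unchanged to 0.1%", {
  ph <- fx_phys("NZ_rabbit")
  lev <- fx_drug("levofloxacin")
  tg <- seq(0.25, 24, by = 0.25)
  s1 <- simulate_ocular(lev, ph$ocular, ph$systemic, fx_single_drop(),
                        t_grid = tg)
  s2 <- simulate_ocular(lev, ph$ocular, ph$systemic, fx_single_drop(),
                        t_grid = tg,
                        options = sim_options(rtol = 5e-9, atol = 5e-11))
  for (tt in c("AH", "cornea_epi", "conjunctiva")) {
    m1 <- nca(s1$time, tissue_conc(s1, tt))
    m2 <- nca(s2$time, tissue_conc(s2, tt))
    expect_equal(m1$cmax, m2$cmax, tolerance = 1e-3)
    expect_equal(m1$auc, m2$auc, tolerance = 1e-3)
  }
})

test_that("input validation catches inconsistent simulation calls", {
  nz <- fx_phys("NZ_rabbit"); hu <- fx_phys("human")
  lev <- fx_drug("levofloxacin")
  expect_error(simulate_ocular(lev, nz$ocular, hu$systemic,
                               fx_single_drop()), "different species")
  expect_error(simulate_ocular(lev, nz$ocular, nz$systemic,
                               dose_regimen(c(0, 10)), t_grid = c(1, 2)),
               "cover the dosing regimen")
})

test_that("whole-cornea concentration is the amount-weighted layer average", {
  ph <- fx_phys("NZ_rabbit")
  sim <- simulate_ocular(fx_drug("levofloxacin"), ph$ocular, ph$systemic,
                         fx_single_drop(), t_grid = c(1, 4))
  vols <- ph$ocular$compartment_volumes_mL
  want <- (sim$amounts[, "cornea_epi"] + sim$amounts[, "cornea_stroma"]) /
    (vols[["cornea_epi"]] + vols[["cornea_stroma"]])
  expect_equal(tissue_conc(sim, "cornea"), want)
  expect_error(tissue_conc(sim, "lens"), "unknown tissue")
})
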