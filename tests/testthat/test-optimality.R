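test_that("least-cost chi has the correct limits, bounds and VPD response", {
  # D0 -> 0: stomata fully open, chi -> 1
  expect_equal(chi_optimal(25, 1e-12, 101.325, 40), 1, tolerance = 1e-4)
  # D0 -> Inf: chi -> Gamma*/ca
  gs <- rubisco_kinetics(25, 101.325)$gamma_star
  expect_equal(chi_optimal(25, 1e9, 101.325, 40), gs / 40,
               tolerance = 1e-3)
  expect_equal(chi_optimal(25, 1, 101.325, 40), oracle$chi_fix,
               tolerance = 1e-10)

  # bounds and monotone decrease in D0 on a grid
  grid <- expand.grid(temp = c(5, 15, 25), d0 = c(0.3, 0.8, 1.5, 3),
                      patm = c(60, 80, 101.325))
  chi <- chi_optimal(grid$temp, grid$d0, grid$patm,
                     co2_partial_pressure(grid$patm, 400))
  gs <- rubisco_kinetics(grid$temp, grid$patm)$gamma_star
  expect_true(all(chi > gs / co2_partial_pressure(grid$patm, 400)))
  expect_true(all(chi < 1))
  for (tt in c(5, 15, 25)) {
    idx <- grid$temp == tt & grid$patm == 80
    expect_true(all(diff(chi[idx][order(grid$d0[idx])]) < 0))
  }
  expect_error(chi_optimal(25, 0, 101.325, 40), "> 0")
  expect_error(chi_optimal(25, 1, 101.325, 2), "compensation")
})

test_that("lower pressure at fixed climate lowers chi and raises Vcmax25", {
  co2 <- 400
  p_low <- air_pressure(500); p_high <- air_pressure(4000)
  chi_low <- chi_optimal(15, 1, p_low, co2_partial_pressure(p_low, co2))
  chi_high <- chi_optimal(15, 1, p_high, co2_partial_pressure(p_high, co2))
  expect_lt(chi_high, chi_low)
  v_low <- vcmax25_predicted(15, 600, chi_low,
                             co2_partial_pressure(p_low, co2), p_low)
  v_high <- vcmax25_predicted(15, 600, chi_high,
                              co2_partial_pressure(p_high, co2), p_high)
  expect_gt(v_high, v_low)
})

test_that("isotope discrimination converts to chi and back", {
  # Delta = b' gives chi = 1 and Delta = a_s gives chi = 0 when the
  # photorespiration term vanishes
  cst0 <- leaf_constants(gammastar25 = 0)
  d13c_for_delta <- function(delta, d13c_air = -8) {
    (d13c_air - delta) / (1 + delta / 1000)
  }
  expect_equal(
    chi_from_isotope(d13c_for_delta(30), 25, 101.325, 40.53,
                     constants = cst0)$chi, 1)
  expect_equal(
    chi_from_isotope(d13c_for_delta(4.4), 25, 101.325, 40.53,
                     constants = cst0)$chi, 0)
  got <- chi_from_isotope(d13c_for_delta(20), 25, 101.325, 40.53)
  expect_equal(got$chi, oracle$chi_iso_fix, tolerance = 1e-10)
  expect_false(got$flag)
  # implausible chi is flagged, not clipped
  flagged <- chi_from_isotope(d13c_for_delta(36), 25, 101.325, 40.53,
                              constants = cst0)
  expect_true(flagged$flag)
  expect_gt(flagged$chi, 1.2)
})

test_that("coordination Vcmax is proportional to light", {
  expect_equal(vcmax_coordination(25, 0, 0.8, 40, 101.325), 0)
  v1 <- vcmax_coordination(25, 400, 0.8, 40, 101.325)
  v2 <- vcmax_coordination(25, 800, 0.8, 40, 101.325)
  expect_equal(v2, 2 * v1)
  expect_equal(v2, oracle$vcmax_fix, tolerance = 1e-10)
  # chi so low that m <= c: informative error naming the inequality
  expect_error(vcmax_coordination(25, 800, 0.2, 40, 101.325),
               "m = \\(ci - Gamma\\*\\)")
})

test_that("instantaneous temperature factor is anchored at 25 C", {
  expect_equal(fv_instantaneous(25), 1, tolerance = 1e-12)
  expect_lt(fv_instantaneous(15), 1)
  expect_gt(fv_instantaneous(30), 1)
  expect_equal(fv_instantaneous(10), oracle$fv_10, tolerance = 1e-10)
})

test_that("Vcmax25 composes coordination and temperature response", {
  expect_equal(vcmax25_predicted(25, 800, 0.8, 40, 101.325),
               vcmax_coordination(25, 800, 0.8, 40, 101.325))
  v <- vcmax25_predicted(12, 550, 0.72, 35, 75)
  expect_equal(v, vcmax_coordination(12, 550, 0.72, 35, 75) /
                 fv_instantaneous(12))
  expect_gt(v, 0)
})

test_that("theoretical LMA is proportional to light dose and longevity", {
  base <- lma_theoretical(20, 180, 25, 40, 0.75, 101.325)
  expect_equal(lma_theoretical(20, 360, 25, 40, 0.75, 101.325), 2 * base)
  expect_equal(lma_theoretical(40, 180, 25, 40, 0.75, 101.325), 2 * base)
  chi_std <- chi_optimal(25, 1, 101.325, 40)
  expect_equal(lma_theoretical(20, 180, 25, 40, chi_std, 101.325),
               oracle$lma_theory_fix, tolerance = 1e-10)
  # elasticity to absorbed light is exactly 1
  el <- num_deriv(function(li) {
    log(lma_theoretical(exp(li), 180, 25, 40, 0.75, 101.325))
  }, log(20))
  expect_equal(el, 1, tolerance = 1e-6)
})

test_that("calibrated deciduous LMA follows its printed coefficients", {
  base <- lma_deciduous(20, 0.6, 12, 0.8)
  expect_equal(base, oracle$lma_decid_fix, tolerance = 1e-10)
  expect_equal(lma_deciduous(40, 0.6, 12, 0.8), base * 2^1.22)
  expect_equal(lma_deciduous(20, 0.6, 12, 0.4), base * 2^0.60)
  expect_error(lma_deciduous(-1, 0.6, 12, 0.8), "log")
})

test_that("the two Narea formulations are linear and mutually consistent", {
  expect_equal(narea_simple(0, 0), 0)
  expect_equal(narea_simple(100, 50), 2.15)
  # additivity (no intercept, linear)
  expect_equal(narea_simple(30 + 70, 20 + 30),
               narea_simple(30, 20) + narea_simple(70, 30))
  expect_equal(narea_simple(50, 40, n_fixer = TRUE, n_fixer_offset = 0.3),
               narea_simple(50, 40) + 0.3)

  expect_equal(narea_two_step(0, 0), 0)
  expect_equal(narea_two_step(0, 100, alloc = 9.5), 9.5 * 0.3135)
  expect_equal(narea_two_step(80, 60, alloc = 7.2),
               oracle$narea_two_step_fix, tolerance = 1e-10)

  # under the algebraic identification (structural term linearised,
  # alloc * 0.003135 = 0.003) the two models coincide on a grid
  cst_lin <- leaf_constants(nstruct_coef = 0.02, nstruct_exp = 1)
  grid <- expand.grid(ma = c(20, 60, 120), v = c(10, 50, 90))
  expect_equal(
    narea_two_step(grid$ma, grid$v, alloc = 0.003 / 0.003135,
                   constants = cst_lin),
    narea_simple(grid$ma, grid$v)
  )
})

test_that("predict_traits returns one positive prediction set per site", {
  sites <- generate_sites(transect_scenario(seed = 11))
  pred <- predict_traits(sites)
  expect_equal(nrow(pred), nrow(sites))
  expect_true(all(pred$chi > 0 & pred$chi < 1))
  expect_true(all(pred$vcmax25 > 0))
  expect_true(all(pred$ma > 0))
  expect_true(all(pred$narea > 0))
  # temperature basis is selectable and changes the chi prediction
  pred_tg <- predict_traits(sites, temperature_basis = c(
    chi = "tg", vcmax25 = "tg", ma = "tg"))
  expect_false(isTRUE(all.equal(pred$chi, pred_tg$chi)))
  expect_error(predict_traits(dplyr::select(sites, -"alpha_p")),
               "alpha_p")
})
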