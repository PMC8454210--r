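test_that("barometric pressure reproduces the reference profile", {
  expect_equal(air_pressure(0), 101.325)
  expect_equal(air_pressure(4361), oracle$patm_4361, tolerance = 1e-10)
  expect_lt(air_pressure(3000), air_pressure(1000))
  elev <- seq(0, 5000, by = 250)
  expect_true(all(diff(air_pressure(elev)) < 0))
  expect_error(air_pressure(-600), ">= -500")
})

test_that("ambient CO2 partial pressure declines with elevation", {
  p <- air_pressure(c(1000, 3000))
  ca <- co2_partial_pressure(p, 400)
  expect_true(ca[2] < ca[1])
  expect_equal(co2_partial_pressure(101.325, 400), 400e-6 * 101325)
})

test_that("daytime temperature weights the diurnal extremes correctly", {
  # degenerate cycle: daytime mean equals the constant temperature
  expect_equal(daytime_temperature(15, 15, 29.6, 21.2), 15)
  # equator or equinox: x = 0, weights are 1/2 +- 1/pi
  expect_equal(daytime_temperature(20, 10, 0, 21.2),
               20 * (0.5 + 1 / pi) + 10 * (0.5 - 1 / pi))
  expect_equal(daytime_temperature(18, 8, 29.6, 21.2), oracle$tdj_fix,
               tolerance = 1e-10)
  # result is bounded by the extremes and shift-equivariant
  tdj <- daytime_temperature(18, 8, 29.6, 21.2)
  expect_true(tdj > 8 && tdj < 18)
  expect_equal(daytime_temperature(23, 13, 29.6, 21.2), tdj + 5)
  expect_error(daytime_temperature(18, 8, 80, 21.2), "Polar")
  expect_error(daytime_temperature(8, 18, 29.6, 21.2), ">=")
})

test_that("growing-season aggregation matches an explicit day loop", {
  expect_equal(
    growing_season_stats(data.frame(temp = rep(10, 365)))[c("tg", "f")],
    tibble::tibble(tg = 10, f = 1)
  )
  half <- data.frame(temp = rep(c(-5, 5), each = 100))
  gs <- growing_season_stats(half)
  expect_equal(gs$tg, 5)
  expect_equal(gs$f, 0.5)
  expect_error(growing_season_stats(data.frame(temp = rep(-1, 10))),
               "Degenerate")

  # property: agrees with a brute-force loop on random series
  for (seed in 1:5) {
    daily <- withr::with_seed(seed, data.frame(
      temp = 8 + 12 * sin(2 * pi * (1:365) / 365) + rnorm(365, 0, 3),
      vpd = runif(365, 0.2, 2),
      par = runif(365, 100, 900)
    ))
    got <- growing_season_stats(daily)
    # oracle: explicit accumulation day by day
    n_grow <- 0; s_t <- 0; s_v <- 0; s_p <- 0
    for (i in seq_len(nrow(daily))) {
      if (daily$temp[i] > 0) {
        n_grow <- n_grow + 1
        s_t <- s_t + daily$temp[i]
        s_v <- s_v + daily$vpd[i]
        s_p <- s_p + daily$par[i]
      }
    }
    expect_equal(got$tg, s_t / n_grow)
    expect_equal(got$d0, s_v / n_grow)
    expect_equal(got$r0, s_p / n_grow)
    expect_equal(got$f, n_grow / 365)
  }
})

test_that("canopy light averaging follows Beer-Lambert attenuation", {
  r_daily <- 800 * 1e-6 * 12 * 3600
  expect_equal(canopy_light(800, lai = 0), r_daily)
  expect_equal(canopy_light(800, lai = 2, extinction_k = 0.5),
               r_daily * (1 - exp(-1)))
  # attenuation strictly decreasing in LAI, and light is never created
  lai <- seq(0, 6, by = 0.5)
  rl <- canopy_light(800, lai)
  expect_true(all(diff(rl) < 0))
  expect_true(all(rl <= r_daily))
})

test_that("Rubisco kinetics hit the 25 C references and scale with pressure", {
  kin <- rubisco_kinetics(25, 101.325)
  expect_equal(kin$kc, 39.97)
  expect_equal(kin$ko, 27480)
  expect_equal(kin$gamma_star, oracle$gammastar_25_sea)
  expect_equal(kin$eta_rel, 1)
  expect_equal(kin$kmm, oracle$kmm_25_sea, tolerance = 1e-10)

  # halving pressure halves Po and Gamma* and strictly lowers K;
  # equivalently the pressure dependence acts only through Po and Gamma*
  full <- rubisco_kinetics(15, 90)
  half <- rubisco_kinetics(15, 45)
  expect_equal(half$po, full$po / 2)
  expect_equal(half$gamma_star, full$gamma_star / 2)
  expect_lt(half$kmm, full$kmm)
  expect_equal(half$kmm, full$kc * (1 + (full$po / 2) / full$ko))
  expect_warning(rubisco_kinetics(50, 101.325), "extrapolated")
})

test_that("derive_bioclim fills pressure-derived columns without overwriting", {
  sites <- tibble::tibble(site_id = "a", elevation_m = 2000,
                          r0 = 600, lai = 3)
  out <- derive_bioclim(sites)
  expect_equal(out$patm, air_pressure(2000))
  expect_equal(out$ca, co2_partial_pressure(out$patm, 400))
  expect_equal(out$r_lai, canopy_light(600, 3))
  # user-supplied values win
  out2 <- derive_bioclim(dplyr::mutate(sites, patm = 80))
  expect_equal(out2$patm, 80)
})
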