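test_that("agreement statistics behave under exact and shifted predictions", {
  d <- tibble::tibble(obs = c(1, 2, 3, 4), pred = c(1, 2, 3, 4))
  perfect <- agreement_stats(d, obs, pred)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r_squared, 1)

  shifted <- agreement_stats(dplyr::mutate(d, pred = obs + 0.7), obs, pred)
  expect_equal(shifted$r, 1)
  expect_equal(shifted$rmse, 0.7)
  # the 1:1-line R2 penalises the bias, squared correlation does not
  expect_lt(shifted$r_squared_identity, shifted$r_squared)

  expect_error(agreement_stats(d[1:2, ], obs, pred), "3")
  expect_warning(
    agreement_stats(tibble::tibble(obs = c(2, 2, 2), pred = 1:3),
                    obs, pred),
    "zero variance")
})

test_that("agreement statistics match direct formula evaluation", {
  d <- withr::with_seed(51, tibble::tibble(obs = rnorm(20, 50, 10),
                                           pred = rnorm(20, 50, 10)))
  got <- agreement_stats(d, obs, pred)
  # independent evaluation from first principles
  n <- nrow(d)
  mx <- sum(d$obs) / n; my <- sum(d$pred) / n
  r_hand <- sum((d$obs - mx) * (d$pred - my)) /
    sqrt(sum((d$obs - mx)^2) * sum((d$pred - my)^2))
  rmse_hand <- sqrt(sum((d$pred - d$obs)^2) / n)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$rmse, rmse_hand, tolerance = 1e-12)
  expect_equal(got$relative_rmse, rmse_hand / mx, tolerance = 1e-12)
  # invariances: site order, affine transform of either vector (for r)
  perm <- withr::with_seed(52, sample(n))
  expect_equal(agreement_stats(d[perm, ], obs, pred)$r, got$r)
  expect_equal(
    agreement_stats(dplyr::mutate(d, obs = 3 * obs + 2), obs, pred)$r,
    got$r)
})

test_that("coefficients of variation separate within from across sites", {
  d <- tibble::tibble(site_id = rep(c("a", "b"), each = 2),
                      ma = c(5, 5, 8, 8))
  cv0 <- cv_within_across(d, ma)
  expect_equal(cv0$within$cv, c(0, 0))

  d2 <- tibble::tibble(site_id = c("a", "a"), ma = c(1, 3))
  expect_equal(cv_within_across(d2, ma)$within$cv, sqrt(2) / 2)

  # within-site noise larger than the across-site spread is detected
  sc <- transect_scenario(n_sites = 6, lapse = 0.5, sd_ln_ma = 0.6,
                          seed = 61)
  traits <- generate_traits(generate_sites(sc), sc)
  cvs <- cv_within_across(traits, ma)
  expect_gt(cvs$n_sites_within_exceeds_across, 0)

  # single-species sites are skipped with a message
  d3 <- tibble::tibble(site_id = c("a", "b", "b"), ma = c(5, 4, 6))
  expect_message(out <- cv_within_across(d3, ma), "single-species")
  expect_equal(out$within$site_id, "b")
})

test_that("the statistical benchmark behaves as a calibrated regression", {
  sc <- transect_scenario(seed = 71)
  sites <- generate_sites(sc)
  traits <- generate_traits(sites, sc)
  data <- dplyr::left_join(site_mean_traits(traits), sites, by = "site_id")
  bench <- benchmark_regression(data)
  expect_setequal(bench$trait, c("chi", "vcmax25", "ma", "narea"))
  expect_true(all(bench$r_squared >= 0 & bench$r_squared <= 1))
  expect_true(all(bench$n == 18))

  # noise-free linear response: R2 -> 1
  lin <- dplyr::mutate(sites, ma = 2 * tg + 0.5 * r_lai + 3 * f +
                         alpha_p)
  # lm warns about the (intentionally) perfect fit when summarising
  expect_equal(suppressWarnings(benchmark_regression(lin, "ma")$r_squared),
               1, tolerance = 1e-10)

  # permuted response: R2 collapses toward the chance level p/(n-1)
  r2_perm <- vapply(1:20, function(seed) {
    shuffled <- dplyr::mutate(
      data, ma = withr::with_seed(seed, sample(ma)))
    benchmark_regression(shuffled, "ma")$r_squared
  }, numeric(1))
  p <- 4; n <- 18
  expect_lt(abs(mean(r2_perm) - p / (n - 1)), 0.15)
  expect_error(benchmark_regression(data[1:4, ], "ma"), "Overdetermined")
})

test_that("site means default to the deciduous community fraction", {
  sc <- transect_scenario(seed = 81)
  traits <- generate_traits(generate_sites(sc), sc)
  dec <- site_mean_traits(traits)
  all_sp <- site_mean_traits(traits, deciduous_only = FALSE)
  expect_true(all(dec$n_species <= all_sp$n_species))
  expect_equal(nrow(dec), 18)
  p <- plot_agreement(
    dplyr::left_join(dec,
                     predict_traits(generate_sites(sc)),
                     by = "site_id", suffix = c("_obs", "_pred")),
    ma_obs, ma_pred)
  expect_s3_class(p, "ggplot")
})
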