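fast_mcmc2 <- function(seed) {
  mcmc_config(chains = 1, iterations = 2500, burn_in = 500, thin = 1,
              seed = seed)
}

test_that("trophic-position arithmetic follows the baseline-referenced
           definition", {
  expect_equal(trophic_position(4, 4, tdf = 3.3), 2)
  expect_equal(trophic_position(7.3, 4.0, tdf = 3.3), 3)
  expect_equal(trophic_position(7.3, 4.0, tdf = 3.3, lambda = 1), 2)
  # affine in the consumer with slope 1/TDF, drawwise
  cons <- stats::rnorm(100, 7); tdf <- stats::runif(100, 3, 4)
  expect_equal(trophic_position(cons + 1, 4, tdf) - trophic_position(cons, 4, tdf),
               1 / tdf)
  # shift equivariance is exact
  expect_equal(trophic_position(cons + 5, 4 + 5, tdf),
               trophic_position(cons, 4, tdf))
  expect_warning(out <- trophic_position(7, 4, tdf = c(3, -1)), "non-positive")
  expect_true(is.na(out[2]))
})

test_that("the tooth-bone offset sub-model recovers a known offset", {
  set.seed(12)
  d <- stats::rnorm(35, 0.8, 0.5)
  fit <- fit_offset_submodel(d, mcmc = fast_mcmc2(1))
  s <- fit$summary[fit$summary$parameter == "muT", ]
  expect_true(s$eti90_lo < 0.8 && 0.8 < s$eti90_hi)

  z <- fit_offset_submodel(rep(0, 20) + stats::rnorm(20, 0, 1e-3),
                           mcmc = fast_mcmc2(2))
  expect_equal(z$summary$median[z$summary$parameter == "muT"], 0,
               tolerance = 0.01)
  expect_error(fit_offset_submodel(0.5), "at least 2")
})

test_that("the elevation sub-model recovers slope and type intercepts", {
  set.seed(13)
  n <- 69
  type <- sample(c("vegetation", "sheep wool"), n, replace = TRUE)
  elev <- stats::runif(n, 0, 3000)
  d15N <- ifelse(type == "vegetation", 2, 5) - 0.001 * elev +
    stats::rnorm(n, 0, 0.7)
  refs <- tibble::tibble(type = type, elevation = elev, d15N = d15N)
  fit <- fit_elevation_submodel(refs, mcmc = fast_mcmc2(3))
  s <- fit$summary[fit$summary$parameter == "betaE", ]
  expect_true(s$eti90_lo < -0.001 && -0.001 < s$eti90_hi)

  one_type <- dplyr::mutate(refs, type = "vegetation")
  f1 <- fit_elevation_submodel(one_type, mcmc = fast_mcmc2(4))
  expect_equal(sum(grepl("^typeI", f1$summary$parameter)), 1)

  flat <- dplyr::mutate(refs, elevation = 100)
  expect_error(fit_elevation_submodel(flat), "degenerate")
})

test_that("the joint paleo fit centres trophic position at 2 when consumer
           and baseline coincide", {
  tr <- paleo_truth(beta_reg = c(intercept = 2, npp = 0, gsl = 0),
                    sigma_tp = 1e-6, n_bear = 120, n_deer = 160, seed = 71)
  sim <- simulate_paleo(tr)
  # consumer means equal baseline means when tp == 2 exactly
  expect_equal(sim$truth$realised$consumer, sim$truth$realised$baseline,
               tolerance = 2e-5)
  fit <- quiet_fit(fit_paleo(sim$samples, sim$refs, sim$period_env,
                             mcmc = fast_mcmc2(5)))
  per <- dplyr::filter(fit$periods, identified)
  expect_true(all(per$tp_eti90_lo < 2 & 2 < per$tp_eti90_hi))
})

test_that("paleo fits are seed-deterministic and report nested intervals", {
  tr <- paleo_truth(n_bear = 40, n_deer = 60, seed = 72)
  sim <- simulate_paleo(tr)
  f1 <- quiet_fit(fit_paleo(sim$samples, sim$refs, sim$period_env,
                            mcmc = fast_mcmc2(6)))
  f2 <- quiet_fit(fit_paleo(sim$samples, sim$refs, sim$period_env,
                            mcmc = fast_mcmc2(6)))
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$periods$tp_eti50_lo >= f1$periods$tp_eti90_lo,
                  na.rm = TRUE))
})

test_that("shifting every d15N value by a constant leaves trophic position
           unchanged", {
  tr <- paleo_truth(n_bear = 60, n_deer = 80, seed = 73)
  sim <- simulate_paleo(tr)
  f1 <- quiet_fit(fit_paleo(sim$samples, sim$refs, sim$period_env,
                            mcmc = fast_mcmc2(7)))
  shifted <- dplyr::mutate(sim$samples, d15N = d15N + 3)
  f2 <- quiet_fit(fit_paleo(shifted, sim$refs, sim$period_env,
                            mcmc = fast_mcmc2(7)))
  expect_equal(dplyr::filter(f2$periods, identified)$tp_median,
               dplyr::filter(f1$periods, identified)$tp_median,
               tolerance = 0.05)
  # the arithmetic identity behind it is exact drawwise
  expect_equal(trophic_position(5 + 3, 2 + 3, tdf = 3),
               trophic_position(5, 2, tdf = 3))
})

test_that("periods lacking one taxon are flagged non-identified and excluded
           from the regression", {
  tr <- paleo_truth(n_bear = 60, n_deer = 80, seed = 74)
  sim <- simulate_paleo(tr)
  nodeer <- dplyr::filter(
    sim$samples, !(taxon == "red_deer" & period_true == "Meghalayan"))
  expect_message(
    fit <- quiet_fit2(fit_paleo(nodeer, sim$refs, sim$period_env,
                                mcmc = fast_mcmc2(8))),
    "not identified")
  meg <- dplyr::filter(fit$periods, period == "Meghalayan")
  expect_false(meg$identified)
  expect_true(is.na(meg$tp_median))
  expect_equal(meg$n_deer, 0L)
  # the regression used only the identified periods
  expect_equal(nrow(fit$design), sum(fit$periods$identified))
})

test_that("missing reference tables stop the joint fit", {
  tr <- paleo_truth(n_bear = 30, n_deer = 40, seed = 75)
  sim <- simulate_paleo(tr)
  refs <- sim$refs
  refs$tdf <- refs$tdf[0, ]
  expect_error(fit_paleo(sim$samples, refs, sim$period_env), "tdf")
})
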