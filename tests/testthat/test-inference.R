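test_that("equal-tailed intervals follow the interpolated quantile rule and
           nest across levels", {
  e <- eti(1:100, 0.9)
  expect_equal(unname(e), stats::quantile(1:100, c(0.05, 0.95), names = FALSE))
  expect_equal(unname(e), c(5.95, 95.05))
  expect_equal(unname(eti(rep(3, 10), 0.5)), c(3, 3))
  x <- c(-3, -1, 0, 1, 3)
  expect_equal(eti(x, 0.8)[["lo"]], -eti(x, 0.8)[["hi"]])
  set.seed(2)
  d <- stats::rnorm(500)
  e50 <- eti(d, 0.5); e90 <- eti(d, 0.9)
  expect_gte(e50[["lo"]], e90[["lo"]])
  expect_lte(e50[["hi"]], e90[["hi"]])
  expect_error(eti(numeric(0)), "at least one")
})

test_that("probability of direction counts the median's sign", {
  expect_equal(direction_probability(c(1, 2, 3)), 1)
  expect_equal(direction_probability(c(-1, 1, 2, 3)), 0.75)
  set.seed(3)
  s <- stats::rnorm(20000)
  expect_equal(direction_probability(s), 0.5, tolerance = 0.02)
  # zeros count toward the median's sign; result never below 0.5
  expect_equal(direction_probability(c(0, 0, 1)), 1)
  for (i in 1:10) {
    expect_gte(direction_probability(stats::rnorm(11)), 0.5)
  }
})

test_that("variance inflation factors match the closed form", {
  set.seed(4)
  # exactly uncorrelated, centred columns
  x <- cbind(rep(c(-1, 1), 10), rep(c(-1, 1), each = 10))
  expect_equal(vif(x)$vif, c(1, 1), tolerance = 1e-10)

  # two columns with sample correlation exactly r: VIF = 1/(1 - r^2)
  r <- 0.61
  u <- as.numeric(scale(stats::rnorm(200)))
  v <- as.numeric(scale(stats::resid(stats::lm(stats::rnorm(200) ~ u))))
  a <- u; b <- r * u + sqrt(1 - r^2) * v
  out <- vif(cbind(a, b))
  expect_equal(stats::cor(a, b), r, tolerance = 1e-12)
  expect_equal(out$vif, rep(1 / (1 - r^2), 2), tolerance = 1e-8)
  expect_equal(out$vif[1], 1.59, tolerance = 1e-2)

  expect_warning(out2 <- vif(cbind(a, a)), "collinearity")
  expect_true(all(is.infinite(out2$vif)))
})

test_that("mixed-model R2 obeys its limits and ordering", {
  set.seed(5)
  fixed <- matrix(stats::rnorm(50 * 30), 50)
  rnd <- cbind(stats::runif(50), stats::runif(50))
  res <- stats::runif(50)
  r2 <- r2_mixed(fixed, rnd, res)
  expect_true(all(r2$r2_conditional >= r2$r2_marginal))
  expect_true(all(r2$r2_marginal >= 0 & r2$r2_conditional <= 1))

  # no random effects, vanishing residual noise: both tend to 1
  r2b <- r2_mixed(fixed, NULL, rep(1e-12, 50))
  expect_equal(mean(r2b$r2_marginal), 1, tolerance = 1e-6)
  expect_equal(r2b$r2_marginal, r2b$r2_conditional)

  # zero fixed effects: marginal 0
  r2c <- r2_mixed(matrix(0, 50, 30), rnd, res)
  expect_equal(max(r2c$r2_marginal), 0)

  # known partition: fixed predictor variance 4, random 1, residual 3
  xfix <- matrix(rep(c(-2, 2), each = 15), 50, 30, byrow = TRUE)
  r2d <- r2_mixed(xfix, matrix(1, 50, 1), rep(3, 50))
  expect_equal(unique(round(r2d$r2_marginal, 10)),
               stats::var(rep(c(-2, 2), each = 15)) /
                 (stats::var(rep(c(-2, 2), each = 15)) + 4))
  expect_error(r2_mixed(matrix(0, 5, 3), NULL, rep(0, 5)), "zero")
})

test_that("posterior predictive p-value flags gross misfit and passes
           self-consistent data", {
  set.seed(6)
  n <- 40; ndraw <- 400
  mu <- matrix(stats::rnorm(ndraw, 2, 0.1), ndraw, n)
  sig <- rep(1, ndraw)
  y <- stats::rnorm(n, 2, 1)
  expect_gt(ppp_rss(y, mu, sig), 0.05)
  expect_lt(ppp_rss(y, mu, sig), 0.95)
  # shift the observations by 10 sigma: RSS_obs explodes, PPP -> 0
  expect_lt(ppp_rss(y + 10, mu, sig), 0.01)
  # zero-noise degenerate case is well-defined (documented convention: 1)
  expect_equal(ppp_rss(rep(2, n), matrix(2, ndraw, n), rep(0, ndraw)), 1)
  expect_error(ppp_rss(y[1:10], mu, sig), "dimension")
})

test_that("split-Rhat detects a drifting chain and accepts white noise", {
  set.seed(7)
  expect_lt(rhat_split(matrix(stats::rnorm(4000), ncol = 2)), 1.01)
  expect_gt(rhat_split(1:1000 + stats::rnorm(1000)), 1.1)
  expect_equal(rhat_split(rep(1, 100)), 1)
})

test_that("posterior summaries report nested intervals and labelled draws", {
  set.seed(8)
  draws <- tibble::tibble(
    chain = rep(1:2, each = 600),
    iteration = rep(1:600, 2),
    parameter = rep(rep(c("a", "b"), each = 300), 2),
    value = c(stats::rnorm(300, 1), stats::rnorm(300, -2),
              stats::rnorm(300, 1), stats::rnorm(300, -2))
  )
  s <- summarize_posterior(draws)
  expect_equal(nrow(s), 2)
  expect_true(all(s$eti50_lo >= s$eti90_lo & s$eti50_hi <= s$eti90_hi))
  expect_equal(s$median[s$parameter == "a"], 1, tolerance = 0.15)
  expect_true(all(s$pd >= 0.5 & s$pd <= 1))
})
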