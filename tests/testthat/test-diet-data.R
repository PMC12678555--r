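test_that("frequency normalisation closes the composition", {
  expect_equal(normalize_frequencies(c(berries = 4)), c(berries = 1))
  expect_equal(normalize_frequencies(c(a = 2, b = 2)), c(a = 0.5, b = 0.5))
  expect_equal(normalize_frequencies(c(a = 3, b = 1, c = 4)),
               c(a = 0.375, b = 0.125, c = 0.5))
  expect_error(normalize_frequencies(c(a = 0, b = 0)), "invalid composition")
  expect_error(normalize_frequencies(c(a = -1, b = 2)), "non-negative")

  set.seed(42)
  for (i in 1:25) {
    x <- stats::rgamma(sample(2:20, 1), 1)
    expect_equal(sum(normalize_frequencies(x)), 1, tolerance = 1e-9)
  }
})

test_that("energy contribution applies Eq.-style correction and closes", {
  cats <- tibble::tibble(
    category = c("meat", "grass"),
    trophic_class = c("animal_vertebrate", "plant"),
    c_D = c(0.9, 0.3), c_E = c(2, 1)
  )
  d <- tibble::tibble(dataset_id = "j", category = c("meat", "grass"),
                      V = c(0.5, 0.5))
  out <- energy_contribution(d, cats)
  # hand arithmetic: 0.9*2*0.5 / (0.9*2*0.5 + 0.3*1*0.5) = 0.9/1.05
  expect_equal(out$E, c(0.9, 0.15) / 1.05, tolerance = 1e-12)
  expect_equal(unique(out$P), 0.9 / 1.05, tolerance = 1e-12)
  expect_equal(sum(out$E), 1, tolerance = 1e-12)

  # identity factors leave the composition unchanged
  cats1 <- dplyr::mutate(cats, c_D = 1, c_E = 1)
  out1 <- energy_contribution(d, cats1)
  expect_equal(out1$E, d$V)

  # absent prey gives P = 0
  d0 <- tibble::tibble(dataset_id = "j", category = c("meat", "grass"),
                       V = c(0, 1))
  expect_equal(unique(energy_contribution(d0, cats)$P), 0)

  expect_error(
    energy_contribution(
      tibble::tibble(dataset_id = "j", category = "krill", V = 1), cats),
    "krill")
  expect_error(
    energy_contribution(
      tibble::tibble(dataset_id = "j", category = "meat", V = 0.8), cats),
    "sum to 1")
})

test_that("energy contribution is invariant to uniform factor rescaling and
           class-preserving relabeling", {
  cats <- default_diet_categories()
  set.seed(7)
  picks <- sample(cats$category, 6)
  v <- normalize_frequencies(stats::runif(6))
  d <- tibble::tibble(dataset_id = "j", category = picks, V = as.numeric(v))
  base <- energy_contribution(d, cats)
  scaled <- energy_contribution(
    d, dplyr::mutate(cats, c_D = c_D * 3.7))
  expect_equal(base$E, scaled$E, tolerance = 1e-12)
  expect_equal(base$P, scaled$P, tolerance = 1e-12)

  # swapping factor assignments between two same-class categories, with the
  # volumes swapped too, leaves P unchanged
  anim <- cats$category[cats$trophic_class == "animal_vertebrate"][1:2]
  d2 <- tibble::tibble(dataset_id = "j", category = c(anim, "graminoids"),
                       V = c(0.3, 0.2, 0.5))
  d2_swap <- tibble::tibble(dataset_id = "j",
                            category = c(anim[2], anim[1], "graminoids"),
                            V = c(0.3, 0.2, 0.5))
  cats_uniform <- dplyr::mutate(
    cats, c_D = ifelse(trophic_class == "animal_vertebrate", 0.9, c_D),
    c_E = ifelse(trophic_class == "animal_vertebrate", 2, c_E))
  expect_equal(unique(energy_contribution(d2, cats_uniform)$P),
               unique(energy_contribution(d2_swap, cats_uniform)$P))
})

test_that("probit compression is monotone, invertible and hits its anchors", {
  expect_equal(probit_compress(0.5, 210), 0)
  expect_equal(probit_compress(0, 210), stats::qnorm(0.5 / 210))
  expect_equal(stats::qnorm(0.5 / 210), -2.82, tolerance = 1e-2)
  # large-n limit approaches the plain probit
  expect_equal(probit_compress(0.3, 1e8), stats::qnorm(0.3), tolerance = 1e-6)

  set.seed(1)
  p <- c(0, 1, stats::runif(50))
  for (n in c(2, 10, 210)) {
    y <- probit_compress(p, n)
    expect_true(all(is.finite(y)))
    expect_equal(probit_expand(y, n), p, tolerance = 1e-12)
    ord <- order(p)
    expect_true(all(diff(y[ord]) >= 0))
    expect_true(all(diff(y[ord][!duplicated(p[ord])]) > 0))
  }
  expect_error(probit_compress(1.2, 210), "\\[0, 1\\]")
  expect_error(probit_compress(-0.1, 210), "\\[0, 1\\]")
})

test_that("the diet reader validates schema, compositions and flags
           datasets lacking volumes", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(toy_diet_table(), path)
  out <- read_diet_table(path)
  expect_equal(length(unique(out$dataset_id)), 3)
  expect_equal(unique(out$needs_imputation[out$dataset_id == "d3"]), TRUE)
  expect_equal(unique(out$needs_imputation[out$dataset_id == "d1"]), FALSE)

  bad <- toy_diet_table()
  bad$F[1] <- 0.2  # d1 frequencies now sum to 0.8
  expect_error(validate_diet_table(bad), "sums to 0.8")

  expect_error(validate_diet_table(dplyr::select(toy_diet_table(), -npp)),
               "npp")
  bad2 <- toy_diet_table()
  bad2$category[1] <- "plankton"
  expect_error(validate_diet_table(bad2), "plankton")
  bad3 <- toy_diet_table()
  bad3$gsl[1:2] <- 13L
  expect_error(validate_diet_table(bad3), "gsl")
})
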