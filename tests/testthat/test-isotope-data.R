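test_that("collagen QC applies the preservation thresholds with hand-counted
           outcomes", {
  out <- qc_collagen(toy_isotope_qc())
  # s1 passes; s2 C/N low; s3 %C and %N at/below limits; s4 C/N 3.6 inclusive
  # passes; s5 C/N high; s6 missing field
  expect_equal(out$qc_pass, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_match(out$qc_reasons[2], "C/N below")
  expect_match(out$qc_reasons[3], "%C not above 8")
  expect_match(out$qc_reasons[3], "%N not above 3")
  expect_match(out$qc_reasons[6], "missing QC field")

  # deterministic and idempotent: re-screening the screened set changes nothing
  again <- qc_collagen(out)
  expect_equal(again$qc_pass, out$qc_pass)
  expect_equal(again$qc_reasons, out$qc_reasons)
})

test_that("time-bin assignment uses half-open bins, the dating gap and the
           oldest boundary", {
  expect_equal(assign_period(10.0), "Greenlandian")
  expect_equal(assign_period(40.0), NA_character_)
  expect_equal(assign_period(11.7), "GS-1")      # boundary -> older bin
  expect_equal(assign_period(c(0, 4.2, 23.3, 54.2, 60)),
               c("Meghalayan", "Northgrippian", "GS-3 to GI-8", NA, NA))

  # partition property: every age maps to at most one bin
  set.seed(9)
  ages <- stats::runif(200, 0, 60)
  bins <- default_time_bins()
  manual <- vapply(ages, function(a)
    sum(a >= bins$lower & a < bins$upper), integer(1))
  got <- assign_period(ages)
  expect_equal(is.na(got), manual == 0)
  expect_true(all(manual <= 1))

  expect_error(assign_period(-1), ">= 0")
  overlapping <- tibble::tibble(period = c("a", "b"),
                                lower = c(0, 3), upper = c(5, 8))
  expect_error(assign_period(1, overlapping), "overlapping")
})

test_that("marine screen flags points in the expanded reference envelope
           and nothing terrestrial", {
  set.seed(10)
  marine <- tibble::tibble(d13C = stats::rnorm(15, -13, 1),
                           d15N = stats::rnorm(15, 15, 1.5))
  terrestrial <- tibble::tibble(sample_id = "t1", d13C = -20.5, d15N = 5)
  out <- marine_screen(terrestrial, marine)
  expect_false(out$samples$marine_flag)
  expect_equal(out$summary$flagged_fraction, 0)

  at_ref <- tibble::tibble(sample_id = "m1", d13C = mean(marine$d13C),
                           d15N = mean(marine$d15N))
  expect_true(marine_screen(at_ref, marine)$samples$marine_flag)

  # whole synthetic terrestrial set stays outside; centroid draws inside
  sim <- simulate_paleo(paleo_truth(n_bear = 40, n_deer = 40, seed = 2))
  scr <- marine_screen(sim$samples, sim$refs$marine)
  expect_equal(scr$summary$flagged_fraction, 0)
  at_centre <- sim$refs$marine |>
    dplyr::summarise(d13C = mean(d13C), d15N = mean(d15N)) |>
    dplyr::mutate(sample_id = "c")
  expect_equal(marine_screen(at_centre, sim$refs$marine)$summary$flagged_fraction, 1)
})

test_that("the isotope validator wires QC and binning together", {
  sim <- simulate_paleo(paleo_truth(n_bear = 30, n_deer = 30,
                                    contamination = 0.3, seed = 11))
  v <- validate_isotope_table(sim$samples)
  expect_true(all(c("qc_pass", "qc_reasons", "period") %in% names(v)))
  expect_equal(v$period, v$period_true)  # generator draws ages inside bins
  expect_true(any(!v$qc_pass))

  bad <- dplyr::mutate(sim$samples, taxon = replace(taxon, 1, "aurochs"))
  expect_error(validate_isotope_table(bad), "aurochs")
  bad2 <- dplyr::mutate(sim$samples, material = replace(material, 1, "antler"))
  expect_error(validate_isotope_table(bad2), "antler")
})
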