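test_that("case probability inverts the odds ratio exactly", {
  expect_equal(case_probability(0.5, 1), 0.5)
  expect_equal(case_probability(0.25, 3), 0.5)
  expect_equal(round(case_probability(0.305, 0.50), 3), 0.180)
  # round trip: OR(p0, p1) == theta
  p0 <- 0.29; theta <- 2.1
  p1 <- case_probability(p0, theta)
  expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), theta)
  expect_error(case_probability(0, 2), "inside")
  expect_error(case_probability(1, 2), "inside")
  expect_error(case_probability(0.5, -1), "positive")
})

test_that("the same seed reproduces the cohort byte for byte", {
  p <- study_preset()
  a <- simulate_cohort(n = c(control = 50, ALL = 50),
                       feature_specs = p$feature_specs, seed = 7)
  b <- simulate_cohort(n = c(control = 50, ALL = 50),
                       feature_specs = p$feature_specs, seed = 7)
  expect_identical(a, b)
  c <- simulate_cohort(n = c(control = 50, ALL = 50),
                       feature_specs = p$feature_specs, seed = 8)
  expect_false(identical(a, c))
})

test_that("constructed genotype classes agree with the classifier", {
  all_aa <- classify_kir_genotype(
    simulate_cohort(n = c(control = 80), aa_fraction = 1, seed = 2))
  expect_true(all(all_aa$kir_genotype == "AA"))
  all_bx <- classify_kir_genotype(
    simulate_cohort(n = c(control = 80), aa_fraction = 0, seed = 2))
  expect_true(all(all_bx$kir_genotype == "Bx"))
})

test_that("a null effect yields an empirical odds ratio near 1", {
  fs <- dplyr::bind_cols(feature_allele("3DL3*009", stratum = "all"),
                         tibble::tibble(p0 = 0.3, or = 1))
  cohort <- simulate_cohort(n = c(control = 1e5, case = 1e5),
                            aa_fraction = 0.5, feature_specs = fs, seed = 9)
  flags <- carries_kir_allele(cohort, "3DL3*009")
  tab <- tabulate_2x2(count_carriers(flags[cohort$cohort == "control"]),
                      count_carriers(flags[cohort$cohort == "case"]))
  or <- odds_ratio_woolf(tab$a, tab$b, tab$c, tab$d)$or
  expect_gt(or, 0.95)
  expect_lt(or, 1.05)
})

test_that("injected effects are recovered feature by feature", {
  p <- study_preset()
  cohort <- simulate_cohort(n = c(control = 12000, AML = 12000),
                            aa_fraction = 0.5,
                            feature_specs = p$feature_specs, seed = 10)
  cohort <- suppressWarnings(build_ligand_profile(classify_kir_genotype(cohort)))
  res <- kir_screen(cohort, p$features, test = "pearson")
  tg <- p$feature_specs
  got <- tibble::as_tibble(res)[res$case_cohort == "AML", ]
  # control carrier frequencies track p0 (large-sample, loose band)
  p0 <- tg$p0[match(got$feature, tg$feature)]
  expect_true(all(abs(got$pct_control / 100 - p0) < 0.02))
  # injected odds ratios recovered within 20% for the non-degenerate rows
  solid <- tg$p0 > 0.05
  or_t <- tg$or_AML[match(got$feature, tg$feature)]
  expect_true(all((abs(log(got$or / or_t)) < log(1.25))[solid[match(
    got$feature, tg$feature)]]))
})

test_that("simulated cohorts pass the input validator unchanged", {
  p <- study_preset()
  cohort <- simulate_cohort(n = c(control = 60, ALL = 60, AML = 60),
                            feature_specs = p$feature_specs, seed = 11)
  expect_equal(nrow(validate_genotype_table(cohort)), 0L)
})

test_that("specs on genes missing from the pool are rejected up front", {
  pool <- default_allele_pool()
  fs <- dplyr::bind_cols(feature_allele("2DL1*555"),
                         tibble::tibble(p0 = 0.2, or = 1))
  expect_error(simulate_cohort(n = c(control = 10), feature_specs = fs,
                               allele_pool = pool, seed = 1),
               "no counterpart")
  fs2 <- dplyr::bind_cols(feature_allele("2DL1*00201"),
                          tibble::tibble(p0 = 1.2, or = 1))
  expect_error(simulate_cohort(n = c(control = 10), feature_specs = fs2,
                               seed = 1), "p0")
})
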