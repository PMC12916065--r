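screen_fixture <- function(seed = 21, n = c(control = 150, ALL = 150,
                                            AML = 150)) {
  p <- study_preset()
  cohort <- simulate_cohort(n = n, aa_fraction = p$aa_fraction,
                            feature_specs = p$feature_specs, seed = seed)
  cohort <- suppressWarnings(build_ligand_profile(classify_kir_genotype(cohort)))
  list(cohort = cohort, preset = p,
       screen = kir_screen(cohort, p$features))
}

test_that("the screen produces one result per feature and case cohort", {
  fx <- screen_fixture()
  expect_s3_class(fx$screen, "kir_screen")
  expect_equal(nrow(fx$screen), nrow(fx$preset$features) * 2)
  expect_true(all(c("or", "ci_lo", "ci_hi", "p_pearson", "p_yates",
                    "p_fisher", "p_reported", "m", "p_corrected") %in%
                    names(fx$screen)))
})

test_that("carriers and non-carriers always sum to the stratum denominator", {
  fx <- screen_fixture()
  expect_equal(fx$screen$a + fx$screen$b, fx$screen$N_control)
  expect_equal(fx$screen$c + fx$screen$d, fx$screen$N_case)
  # AA/Bx stratification partitions the cohort
  g <- fx$cohort
  expect_equal(sum(g$kir_genotype == "AA") + sum(g$kir_genotype == "Bx"),
               nrow(g))
})

test_that("the per-gene Bonferroni family counts features on the same gene", {
  fx <- screen_fixture()
  m_of <- function(f) unique(fx$screen$m[fx$screen$feature == f])
  expect_equal(m_of("2DL1*00201"), 5L)  # 2 alleles + 3 interactions on 2DL1
  expect_equal(m_of("2DL3*00201"), 2L)
  expect_equal(m_of("C2"), 1L)
  fixed <- kir_screen(fx$cohort, fx$preset$features, m = 16L)
  expect_true(all(fixed$m == 16L))
  expect_equal(fixed$p_corrected, pmin(1, 16 * fixed$p_reported))
})

test_that("an empty feature list yields an empty result", {
  fx <- screen_fixture()
  empty <- kir_screen(fx$cohort, study_preset()$features[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("unknown feature references fail before any statistics run", {
  fx <- screen_fixture()
  bad <- study_preset()$features[1, ]
  bad$type <- "mystery"
  expect_error(kir_screen(fx$cohort, bad), "unknown feature type")
  bad2 <- feature_ligand("C2")
  bad2$ligand <- "Qx"
  expect_error(kir_screen(fx$cohort, bad2), "unknown ligand")
})

test_that("the report mirrors the published table layout", {
  fx <- screen_fixture()
  lines <- format_screen(fx$screen)
  expect_match(lines[1], "feature.*control n \\(%\\).*case n \\(%\\).*OR \\(95% CI\\).*P.*Pc")
  expect_match(lines[2], "^\\S+ +AA +\\S+ +\\d+ \\(\\d+\\.\\d\\) +\\d+ \\(\\d+\\.\\d\\)")
  out <- capture.output(print(fx$screen))
  expect_match(out[2], "test policy")
  expect_match(out[4], "reference tables:.*KIR3DL3_300")
})

test_that("tidy, glance and autoplot expose broom/ggplot interfaces", {
  fx <- screen_fixture()
  td <- tidy(fx$screen)
  expect_true(all(c("estimate", "conf.low", "conf.high", "p.value",
                    "p.adjusted") %in% names(td)))
  expect_equal(nrow(td), nrow(fx$screen))
  gl <- glance(fx$screen)
  expect_equal(gl$n_tests, nrow(fx$screen))
  pl <- ggplot2::autoplot(fx$screen)
  expect_s3_class(pl, "ggplot")
  expect_s3_class(plot_carrier_freq(fx$screen), "ggplot")
})

test_that("screening precomputed counts matches the table-level statistics", {
  counts <- tibble::tibble(feature = c("x", "y"),
                           a = c(48, 15), b = c(119, 152),
                           c = c(31, 4), d = c(131, 151))
  res <- screen_counts(counts, test = "pearson", m = 2L)
  expect_equal(round(res$or, 2), c(0.59, 0.27))
  expect_equal(res$p_corrected, pmin(1, 2 * res$p_pearson))
})
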