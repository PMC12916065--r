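test_that("odds ratios and Woolf intervals reproduce textbook values", {
  r <- odds_ratio_woolf(48, 119, 31, 131)
  expect_equal(round(r$or, 2), 0.59)
  expect_equal(round(r$ci_lo, 2), 0.35)
  expect_equal(round(r$ci_hi, 2), 0.98)
  expect_equal(round(odds_ratio_woolf(15, 152, 4, 151)$or, 2), 0.27)
  expect_equal(odds_ratio_woolf(10, 20, 10, 20)$or, 1)
  expect_false(r$zero_cell)
})

test_that("swapping case and control rows inverts the odds ratio", {
  set.seed(2)
  t <- random_tables(50)
  fwd <- odds_ratio_woolf(t$a, t$b, t$c, t$d)$or
  rev <- odds_ratio_woolf(t$c, t$d, t$a, t$b)$or
  expect_equal(fwd * rev, rep(1, 50))
})

test_that("zero cells trigger the Haldane policy and a flag", {
  r <- odds_ratio_woolf(0, 139, 9, 154)
  expect_true(r$zero_cell)
  expect_equal(r$or, (9.5 / 154.5) / (0.5 / 139.5))
  expect_true(is.na(odds_ratio_woolf(0, 10, 0, 10)$or))  # undefined
  expect_true(is.na(odds_ratio_woolf(0, 10, 5, 5, zero_policy = "none")$or))
})

test_that("the Pearson closed form matches the standard implementation", {
  r <- chisq_2x2(48, 119, 31, 131)
  expect_equal(round(r$chi2, 2), 4.16)
  expect_equal(round(r$p, 3), 0.041)
  expect_equal(chisq_2x2(10, 10, 10, 10)$p, 1)
  set.seed(3)
  t <- random_tables(200)
  mine <- chisq_2x2(t$a, t$b, t$c, t$d)
  ref <- vapply(seq_len(200), function(i) {
    suppressWarnings(stats::chisq.test(
      matrix(c(t$a[i], t$b[i], t$c[i], t$d[i]), 2, byrow = TRUE),
      correct = FALSE
    ))$statistic
  }, numeric(1))
  expect_equal(mine$chi2, unname(ref), tolerance = 1e-12)
})

test_that("the Yates correction matches and never exceeds Pearson", {
  expect_equal(round(chisq_2x2(0, 139, 9, 154, correct = TRUE)$p, 3), 0.013)
  expect_equal(chisq_2x2(10, 10, 10, 10, correct = TRUE)$p, 1)
  set.seed(4)
  t <- random_tables(200)
  ya <- chisq_2x2(t$a, t$b, t$c, t$d, correct = TRUE)
  pe <- chisq_2x2(t$a, t$b, t$c, t$d)
  expect_true(all(ya$chi2 <= pe$chi2 + 1e-12))
  ref <- vapply(seq_len(200), function(i) {
    suppressWarnings(stats::chisq.test(
      matrix(c(t$a[i], t$b[i], t$c[i], t$d[i]), 2, byrow = TRUE)
    ))$statistic
  }, numeric(1))
  expect_equal(ya$chi2, unname(ref), tolerance = 1e-12)
})

test_that("chi-square is invariant under transposition", {
  set.seed(5)
  t <- random_tables(50)
  expect_equal(chisq_2x2(t$a, t$b, t$c, t$d)$chi2,
               chisq_2x2(t$a, t$c, t$b, t$d)$chi2)
})

test_that("the chi-square p equals the normal-tail identity", {
  set.seed(6)
  t <- random_tables(100)
  r <- chisq_2x2(t$a, t$b, t$c, t$d)
  expect_equal(r$p, 2 * (1 - stats::pnorm(sqrt(r$chi2))), tolerance = 1e-10)
})

test_that("Fisher exact follows the point-probability rule", {
  expect_equal(fisher_2x2(2, 3, 3, 2), 1)
  expect_equal(fisher_2x2(5, 0, 0, 5), 2 / choose(10, 5))
  set.seed(7)
  t <- random_tables(100, max_cell = 40)
  mine <- fisher_2x2(t$a, t$b, t$c, t$d)
  oracle <- mapply(fisher_oracle, t$a, t$b, t$c, t$d)
  expect_equal(mine, oracle, tolerance = 1e-12)
  ref <- mapply(function(a, b, c, d) {
    stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  }, t$a, t$b, t$c, t$d)
  expect_equal(mine, ref, tolerance = 1e-7)
})

test_that("Bonferroni correction is min(1, m p)", {
  expect_equal(bonferroni_p(0.001, 16), 0.016)
  expect_equal(bonferroni_p(0.004, 15), 0.06)
  expect_equal(bonferroni_p(0.5, 10), 1)
  expect_error(bonferroni_p(0.05, 0), "m must be")
  expect_error(bonferroni_p(1.5, 2), "0, 1")
})

test_that("the auto policy reports Fisher for small expected counts", {
  small <- associate_2x2(1, 200, 8, 193)
  expect_equal(small$test_used, "fisher")
  expect_equal(small$p_reported, small$p_fisher)
  big <- associate_2x2(48, 119, 31, 131)
  expect_equal(big$test_used, "pearson")
  expect_equal(big$p_reported, big$p_pearson)
  forced <- associate_2x2(1, 200, 8, 193, test = "yates")
  expect_equal(forced$p_reported, forced$p_yates)
})

test_that("invalid tables are rejected", {
  expect_error(odds_ratio_woolf(-1, 5, 5, 5), "non-negative")
  expect_error(chisq_2x2(0, 0, 5, 5), "at least one sample")
})
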