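check_table <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0) || anyNA(c(a, b, c, d))) {
    rlang::abort("contingency cells must be non-negative counts")
  }
  if (any(a + b == 0) || any(c + d == 0)) {
    rlang::abort("both groups must contain at least one sample")
  }
}

#' Odds ratio with Woolf confidence interval
#'
#' Case-versus-control odds ratio for carrier 2x2 tables with cells
#' `a` = control carriers, `b` = control non-carriers, `c` = case
#' carriers, `d` = case non-carriers: OR = (c/d)/(a/b). The confidence
#' interval is Woolf's log construction
#' exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' With any zero cell the point estimate and interval are undefined; the
#' default policy adds 0.5 to every cell (Haldane-Anscombe) and sets the
#' `zero_cell` flag so such rows are never mistaken for exact results.
#' When carriers are absent from both groups the odds ratio is reported
#' as `NA`.
#'
#' @param a,b,c,d Integer vectors: control carriers/non-carriers, case
#'   carriers/non-carriers.
#' @param conf Confidence level (default 0.95).
#' @param zero_policy `"haldane"` (add 0.5 to all cells of affected
#'   tables) or `"none"` (return `NA` for affected tables).
#' @return A tibble with columns `or`, `ci_lo`, `ci_hi`, `zero_cell`.
#' @export
#' @examples
#' odds_ratio_woolf(48, 119, 31, 131)  # 0.59 (0.35-0.98)
odds_ratio_woolf <- function(a, b, c, d, conf = 0.95,
                             zero_policy = c("haldane", "none")) {
  zero_policy <- match.arg(zero_policy)
  check_table(a, b, c, d)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  undef <- a == 0 & c == 0
  aa <- as.numeric(a); bb <- as.numeric(b)
  cc <- as.numeric(c); dd <- as.numeric(d)
  if (zero_policy == "haldane") {
    aa[zero] <- a[zero] + 0.5
    bb[zero] <- b[zero] + 0.5
    cc[zero] <- c[zero] + 0.5
    dd[zero] <- d[zero] + 0.5
  }
  or <- (cc * bb) / (dd * aa)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  lo <- exp(log(or) - z * se)
  hi <- exp(log(or) + z * se)
  drop <- undef | (zero & zero_policy == "none")
  or[drop] <- lo[drop] <- hi[drop] <- NA_real_
  tibble::tibble(or = or, ci_lo = lo, ci_hi = hi, zero_cell = zero)
}

#' Chi-square tests for 2x2 tables
#'
#' Pearson's chi-square statistic in closed form,
#' chi2 = N (ad - bc)^2 / (r1 r2 c1 c2), with the p-value taken from the
#' chi-square survival function at 1 degree of freedom. With
#' `correct = TRUE` the Yates continuity correction replaces |ad - bc| by
#' max(0, |ad - bc| - N/2), which can only shrink the statistic. Tables
#' with a zero marginal have no defined statistic and return `NA`.
#'
#' @inheritParams odds_ratio_woolf
#' @param correct Apply the Yates continuity correction?
#' @return A tibble with columns `chi2`, `p`, `min_expected` (smallest
#'   expected cell count) and `small_expected` (`TRUE` when any expected
#'   count is below 5, the usual trigger for an exact test).
#' @export
#' @examples
#' chisq_2x2(48, 119, 31, 131)
chisq_2x2 <- function(a, b, c, d, correct = FALSE) {
  check_table(a, b, c, d)
  # marginal products overflow 32-bit integers even at modest cohort sizes
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  expected_min <- pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  num <- abs(a * d - b * c)
  if (correct) num <- pmax(0, num - n / 2)
  denom <- r1 * r2 * c1 * c2
  chi2 <- ifelse(denom > 0, n * num^2 / denom, NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  tibble::tibble(chi2 = chi2, p = p,
                 min_expected = ifelse(denom > 0, expected_min, NA_real_),
                 small_expected = expected_min < 5)
}

#' Two-sided Fisher exact test for 2x2 tables
#'
#' Exact p-value under the hypergeometric null with fixed marginals,
#' two-sided by the point-probability rule: the sum of the probabilities
#' of all tables whose point probability does not exceed that of the
#' observed table (a small relative tolerance absorbs floating-point
#' ties, matching conventional implementations).
#'
#' @inheritParams odds_ratio_woolf
#' @return Numeric vector of p-values.
#' @export
#' @examples
#' fisher_2x2(5, 0, 0, 5)  # 2 / choose(10, 5)
fisher_2x2 <- function(a, b, c, d) {
  check_table(a, b, c, d)
  vapply(seq_along(a), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]; k <- a[i] + c[i]
    supp <- max(0L, k - r2):min(k, r1)
    probs <- stats::dhyper(supp, r1, r2, k)
    obs <- probs[supp == a[i]]
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Bonferroni correction
#'
#' Multiplicity-corrected p-value Pc = min(1, m p) for a family of `m`
#' tests.
#'
#' @param p P-value(s) in \[0, 1\].
#' @param m Family size, integer >= 1.
#' @return Corrected p-value(s).
#' @export
#' @examples
#' bonferroni_p(0.001, 16)  # 0.016
bonferroni_p <- function(p, m) {
  if (any(m < 1) || any(m != as.integer(m))) {
    rlang::abort("family size m must be an integer >= 1")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  pmin(1, m * p)
}

#' Full association statistics for carrier 2x2 tables
#'
#' Combines [odds_ratio_woolf()], [chisq_2x2()] (plain and Yates),
#' [fisher_2x2()] and [bonferroni_p()] into one result row per table. The
#' reported p-value follows the selection policy: `"auto"` (the
#' SPSS-style rule: Fisher exact when any expected count is below 5,
#' Pearson otherwise) or a fixed test.
#'
#' @inheritParams odds_ratio_woolf
#' @param test `"auto"`, `"pearson"`, `"yates"` or `"fisher"`.
#' @param m Bonferroni family size applied to the reported p-value.
#' @return A tibble with the cells, carrier summaries, `or`/`ci_lo`/
#'   `ci_hi`, `chi2`, `p_pearson`, `p_yates`, `p_fisher`, `test_used`,
#'   `p_reported`, `m`, `p_corrected` and the `zero_cell`/
#'   `small_expected` flags.
#' @export
#' @examples
#' associate_2x2(48, 119, 31, 131, m = 10)
associate_2x2 <- function(a, b, c, d, conf = 0.95,
                          test = c("auto", "pearson", "yates", "fisher"),
                          m = 1L, zero_policy = "haldane") {
  test <- match.arg(test)
  orw <- odds_ratio_woolf(a, b, c, d, conf = conf, zero_policy = zero_policy)
  pe <- chisq_2x2(a, b, c, d, correct = FALSE)
  ya <- chisq_2x2(a, b, c, d, correct = TRUE)
  fi <- fisher_2x2(a, b, c, d)
  test_used <- switch(test,
    auto = ifelse(pe$small_expected | is.na(pe$p), "fisher", "pearson"),
    rep(test, length(a))
  )
  p_reported <- dplyr::case_when(
    test_used == "pearson" ~ pe$p,
    test_used == "yates" ~ ya$p,
    TRUE ~ fi
  )
  tibble::tibble(
    a = a, b = b, c = c, d = d,
    n_control = a, N_control = a + b,
    pct_control = round_half_up(100 * a / (a + b), 1),
    n_case = c, N_case = c + d,
    pct_case = round_half_up(100 * c / (c + d), 1),
    or = orw$or, ci_lo = orw$ci_lo, ci_hi = orw$ci_hi,
    chi2 = pe$chi2, p_pearson = pe$p, p_yates = ya$p, p_fisher = fi,
    test_used = test_used, p_reported = p_reported,
    m = as.integer(m), p_corrected = bonferroni_p(p_reported, m),
    zero_cell = orw$zero_cell, small_expected = pe$small_expected
  )
}
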