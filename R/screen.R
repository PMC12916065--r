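#' Carrier-frequency association screen
#'
#' Runs the case-control screen: for every feature and every case cohort,
#' samples of the feature's KIR genotype stratum are counted as carriers
#' and non-carriers, the 2x2 table is formed against controls, and the
#' association statistics (odds ratio with Woolf CI, Pearson/Yates
#' chi-square, Fisher exact, Bonferroni-corrected Pc) are computed.
#'
#' The Bonferroni family size defaults to `"per-gene"`: the number of
#' features screened on the same gene for the same case cohort (ligand
#' features form their own family). Pass an integer to fix `m` globally.
#'
#' @param data Cohort tibble with `cohort`, `kir_genotype`, allele-call
#'   and ligand-profile columns (i.e. after [classify_kir_genotype()] and
#'   [build_ligand_profile()]).
#' @param features Feature tibble (see [feature_allele()]).
#' @param control Label of the control cohort (default `"control"`).
#' @param test Reported-p selection policy, see [associate_2x2()].
#' @param m `"per-gene"` or an integer family size.
#' @param conf Confidence level for the Woolf interval.
#' @return A `kir_screen` tibble: one row per feature x case cohort with
#'   counts, percentages, OR (95% CI), all p-values, `m` and `Pc`.
#'   Attributes record the test policy, family policy and reference-table
#'   versions.
#' @export
#' @examples
#' preset <- study_preset()
#' cohort <- simulate_cohort(n = c(control = 120, AML = 120),
#'                           feature_specs = preset$feature_specs, seed = 7)
#' cohort <- build_ligand_profile(classify_kir_genotype(cohort))
#' kir_screen(cohort, preset$features)
kir_screen <- function(data, features, control = "control",
                       test = c("auto", "pearson", "yates", "fisher"),
                       m = "per-gene", conf = 0.95) {
  test <- match.arg(test)
  if (!"cohort" %in% names(data)) rlang::abort("data must have a 'cohort' column")
  if (!"kir_genotype" %in% names(data)) {
    rlang::abort("data must have a 'kir_genotype' column; run classify_kir_genotype()")
  }
  cohorts <- unique(data$cohort)
  if (!control %in% cohorts) {
    rlang::abort(paste0("no samples with control label '", control, "'"))
  }
  case_labels <- setdiff(cohorts, control)
  if (length(case_labels) == 0L) rlang::abort("no case cohorts in the data")
  if (nrow(features) == 0L) {
    return(new_kir_screen(tibble::tibble(), test, m, conf))
  }

  family_gene <- feature_family(features)
  fam_size <- table(family_gene)

  rows <- purrr::map(seq_len(nrow(features)), function(i) {
    frow <- features[i, ]
    in_stratum <- if (frow$stratum == "all") rep(TRUE, nrow(data)) else
      data$kir_genotype == frow$stratum
    flags <- feature_flags(data[in_stratum, ], frow)
    coh <- data$cohort[in_stratum]
    ctrl <- count_carriers(flags[coh == control])
    purrr::map(case_labels, function(k) {
      cas <- count_carriers(flags[coh == k])
      tab <- tabulate_2x2(ctrl, cas)
      m_i <- if (identical(m, "per-gene")) as.integer(fam_size[[family_gene[i]]])
             else as.integer(m)
      st <- associate_2x2(tab$a, tab$b, tab$c, tab$d, conf = conf,
                          test = test, m = m_i)
      dplyr::bind_cols(
        tibble::tibble(feature = frow$feature, stratum = frow$stratum,
                       case_cohort = k),
        st
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  new_kir_screen(rows, test, m, conf)
}

new_kir_screen <- function(rows, test, m_policy, conf) {
  out <- tibble::new_tibble(rows, class = "kir_screen")
  attr(out, "test_policy") <- test
  attr(out, "m_policy") <- if (identical(m_policy, "per-gene")) "per-gene"
                           else as.integer(m_policy)
  attr(out, "conf") <- conf
  attr(out, "reference_versions") <- reference_versions()
  out
}

#' Reference-table release tags
#'
#' @return Named character vector of the version tags of every packaged
#'   reference table, echoed in screen reports and CLI output.
#' @export
reference_versions <- function() {
  schemes <- vapply(names(allotype_scheme_files), function(s) {
    attr(kir_allotype_scheme(s), "version") %||% NA_character_
  }, character(1))
  c(schemes, hla_residues = attr(hla_residue_table(), "version") %||% NA_character_)
}

#' Screen precomputed carrier counts
#'
#' Runs the association statistics directly on a table of carrier counts
#' (one row per feature x case cohort), the entry point used for
#' published-count regressions and simulation calibrations where carrier
#' status is already summarized.
#'
#' @param counts Tibble with columns `feature`, `case_cohort` (optional),
#'   `a`, `b`, `c`, `d`.
#' @inheritParams kir_screen
#' @export
screen_counts <- function(counts, test = c("auto", "pearson", "yates", "fisher"),
                          m = 1L, conf = 0.95) {
  test <- match.arg(test)
  st <- associate_2x2(counts$a, counts$b, counts$c, counts$d,
                      conf = conf, test = test, m = m)
  keep <- intersect(c("feature", "stratum", "case_cohort"), names(counts))
  new_kir_screen(dplyr::bind_cols(counts[keep], st), test, m, conf)
}

#' @export
print.kir_screen <- function(x, ...) {
  cat("KIR-HLA carrier-frequency association screen\n")
  cat("  test policy:", attr(x, "test_policy"),
      "(auto = Fisher if any expected count < 5, else Pearson)\n")
  cat("  Bonferroni family:", format(attr(x, "m_policy")), "\n")
  vers <- attr(x, "reference_versions")
  cat("  reference tables:",
      paste(names(vers), vers, sep = "=", collapse = ", "), "\n\n")
  writeLines(format_screen(x))
  invisible(x)
}

fmt_p <- function(p) {
  ifelse(is.na(p), "-",
         ifelse(p < 0.001, formatC(p, format = "e", digits = 1),
                formatC(round_half_up(p, 3), format = "g", digits = 3)))
}

#' Format a screen as the published table layout
#'
#' One line per result in the layout of the published association tables:
#' `feature  n (%)  n (%)  OR (95% CI)  P  Pc`, with the control column
#' first. Zero-cell rows are marked so that their Haldane-corrected odds
#' ratio is not mistaken for an exact one.
#'
#' @param x A `kir_screen` result.
#' @return Character vector of report lines (header first).
#' @export
format_screen <- function(x) {
  if (nrow(x) == 0L) return("(empty screen)")
  or_txt <- ifelse(
    is.na(x$or), "-",
    sprintf("%.2f (%.2f-%.2f)%s", x$or, x$ci_lo, x$ci_hi,
            ifelse(x$zero_cell, "*", ""))
  )
  body <- sprintf(
    "%-24s %-8s %-6s %-12s %-12s %-20s %-8s %-8s m=%d",
    x$feature, x$stratum %||% "", x$case_cohort,
    sprintf("%d (%.1f)", x$n_control, x$pct_control),
    sprintf("%d (%.1f)", x$n_case, x$pct_case),
    or_txt, fmt_p(x$p_reported), fmt_p(x$p_corrected), x$m
  )
  header <- sprintf("%-24s %-8s %-6s %-12s %-12s %-20s %-8s %-8s %s",
                    "feature", "stratum", "case", "control n (%)",
                    "case n (%)", "OR (95% CI)", "P", "Pc", "")
  c(header, body,
    if (any(x$zero_cell)) "* zero cell: Haldane-Anscombe +0.5 applied")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a screen result
#'
#' @param x A `kir_screen` object.
#' @param ... Unused.
#' @return A plain tibble with one row per test: `feature`,
#'   `case_cohort`, `estimate` (odds ratio), `conf.low`, `conf.high`,
#'   `statistic` (Pearson chi-square), `p.value` (reported p) and
#'   `p.adjusted` (Bonferroni Pc).
#' @method tidy kir_screen
#' @export
tidy.kir_screen <- function(x, ...) {
  tibble::tibble(
    feature = x$feature,
    case_cohort = x$case_cohort,
    estimate = x$or,
    conf.low = x$ci_lo,
    conf.high = x$ci_hi,
    statistic = x$chi2,
    p.value = x$p_reported,
    p.adjusted = x$p_corrected
  )
}

#' Summarize a screen result
#'
#' @param x A `kir_screen` object.
#' @param alpha Significance threshold applied to the reported p-values.
#' @param ... Unused.
#' @return A one-row tibble: number of tests, number significant before
#'   and after Bonferroni correction, test and family policy.
#' @method glance kir_screen
#' @export
glance.kir_screen <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$p_reported < alpha, na.rm = TRUE),
    n_significant_corrected = sum(x$p_corrected < alpha, na.rm = TRUE),
    test_policy = attr(x, "test_policy"),
    m_policy = format(attr(x, "m_policy"))
  )
}

#' Forest plot of screen odds ratios
#'
#' @param object A `kir_screen` result.
#' @param ... Unused.
#' @return A ggplot: odds ratios with Woolf intervals on a log scale, one
#'   panel per case cohort; the dashed line marks no effect.
#' @method autoplot kir_screen
#' @export
autoplot.kir_screen <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$estimate), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$feature)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$case_cohort)) +
    ggplot2::labs(x = "odds ratio (case vs control, Woolf 95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Carrier-frequency comparison plot
#'
#' @param x A `kir_screen` result.
#' @return A ggplot of carrier percentages, controls vs each case cohort.
#' @export
plot_carrier_freq <- function(x) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("feature", "case_cohort", "pct_control", "pct_case")],
    c("pct_control", "pct_case"),
    names_to = "group", values_to = "pct"
  )
  df$group <- ifelse(df$group == "pct_control", "control", df$case_cohort)
  df <- dplyr::distinct(df, .data$feature, .data$group, .keep_all = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$pct,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "carrier frequency (%)", x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
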