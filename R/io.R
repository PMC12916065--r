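genotype_table_cols <- function() {
  c("sample_id", "cohort",
    presence_col(kir_loci()),
    allele_col(kir_a_haplotype_genes()),
    "hla_a1", "hla_a2", "hla_b1", "hla_b2", "hla_c1", "hla_c2")
}

#' Read and validate a genotype table
#'
#' The canonical genotype table is a TSV (CSV accepted) with one row per
#' sample and the columns: `sample_id`, `cohort`, sixteen 0/1 presence
#' columns `kir2dl1` ... `kir3dp1`, seven allele-call columns
#' `kir2dl1_alleles` ... `kir2ds4_alleles` (semicolon-separated allele
#' fields, `"."` or empty = untyped), and six HLA columns `hla_a1` ...
#' `hla_c2` (4-digit names, `"."` = missing).
#'
#' Missing required columns are fatal. Row-level problems -- allele calls
#' at a gene whose presence flag is 0, unparseable allele fields, missing
#' framework genes, absent cohort labels -- are collected per row and
#' reported; offending rows are dropped, the rest returned. The problem
#' summary is attached as the `"problems"` attribute and surfaced as a
#' warning.
#'
#' @param path File to read (`.tsv`/`.txt` tab-separated, `.csv` comma).
#' @return A validated genotype tibble.
#' @export
read_genotype_table <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv
            else readr::read_tsv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  need <- genotype_table_cols()
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("genotype table is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  for (cn in presence_col(kir_loci())) {
    raw[[cn]] <- suppressWarnings(as.integer(raw[[cn]]))
  }
  for (cn in c(allele_col(kir_a_haplotype_genes()),
               "hla_a1", "hla_a2", "hla_b1", "hla_b2", "hla_c1", "hla_c2")) {
    v <- raw[[cn]]
    v[is.na(v) | v == "."] <- ""
    raw[[cn]] <- v
  }
  problems <- validate_genotype_table(raw)
  if (nrow(problems) > 0L) {
    rlang::warn(paste0(
      nrow(problems), " validation problem(s) in ", path,
      "; offending rows dropped (see attr(x, 'problems'))"
    ))
    raw <- raw[!seq_len(nrow(raw)) %in% problems$row, ]
  }
  attr(raw, "problems") <- problems
  raw
}

#' Validate genotype table rows
#'
#' @param data A genotype tibble (canonical columns).
#' @return A tibble of problems: `row` (1-based data row), `sample_id`,
#'   `issue`. Zero rows means the table is clean.
#' @export
validate_genotype_table <- function(data) {
  probs <- list()
  note <- function(row, issue) {
    probs[[length(probs) + 1L]] <<- tibble::tibble(
      row = row, sample_id = as.character(data$sample_id[row]), issue = issue
    )
  }
  for (i in seq_len(nrow(data))) {
    if (is.na(data$cohort[i]) || !nzchar(data$cohort[i])) {
      note(i, "missing cohort label")
    }
    pres <- vapply(presence_col(kir_loci()),
                   function(cn) data[[cn]][i], integer(1))
    bad_pres <- is.na(pres) | !pres %in% c(0L, 1L)
    if (any(bad_pres)) {
      note(i, paste0("presence flags must be 0/1: ",
                     paste(names(pres)[bad_pres], collapse = ", ")))
      next
    }
    fw <- presence_col(kir_framework_genes())
    if (any(pres[fw] == 0L)) {
      note(i, paste0("framework gene absent: ",
                     paste(names(pres[fw])[pres[fw] == 0L], collapse = ", ")))
    }
    for (g in kir_a_haplotype_genes()) {
      calls <- split_allele_field(data[[allele_col(g)]][i])[[1]]
      calls <- calls[nzchar(calls)]
      if (length(calls) == 0L) next
      if (pres[presence_col(g)] == 0L) {
        note(i, paste0("allele call at absent gene KIR", g,
                       " (sample ", data$sample_id[i], ")"))
      }
      ok <- grepl("^[0-9]+$", calls) & nchar(calls) %in% c(3L, 5L, 7L)
      if (!all(ok)) {
        note(i, paste0("malformed allele field(s) at KIR", g, ": ",
                       paste(calls[!ok], collapse = ", ")))
      }
    }
  }
  if (length(probs) == 0L) {
    tibble::tibble(row = integer(), sample_id = character(),
                   issue = character())
  } else {
    dplyr::bind_rows(probs)
  }
}

#' Write a genotype table
#'
#' Writes the canonical tab-separated layout with `"."` for missing
#' values; [read_genotype_table()] round-trips it losslessly.
#'
#' @param data Genotype tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(data, path) {
  out <- data[intersect(genotype_table_cols(), names(data))]
  for (cn in names(out)) {
    if (is.character(out[[cn]])) {
      v <- out[[cn]]
      v[is.na(v) | v == ""] <- "."
      out[[cn]] <- v
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write screen results
#'
#' Writes a screen result as TSV, or as JSON carrying the run metadata
#' (test policy, Bonferroni family policy, reference-table versions)
#' alongside the result rows.
#'
#' @param x A `kir_screen` result.
#' @param path Output file; format chosen by extension (`.json` vs TSV).
#' @return `path`, invisibly.
#' @export
write_screen_results <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      metadata = list(
        test_policy = attr(x, "test_policy"),
        m_policy = format(attr(x, "m_policy")),
        conf = attr(x, "conf"),
        reference_versions = as.list(attr(x, "reference_versions"))
      ),
      results = tibble::as_tibble(x)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  }
  invisible(path)
}

#' Published association-table counts
#'
#' The carrier counts and printed statistics of the study's association
#' tables (allele screen and receptor-ligand interaction screen in the
#' KIR AA / Bx strata, plus the C2-ligand comparison), packaged as a
#' regression fixture. Each row holds the control and case carrier counts
#' (`a`/`b`/`c`/`d` reconstructable via `n`/`N`), the printed carrier
#' percentages, odds ratio with confidence bounds, p-value and corrected
#' p-value, and a `reproducible` flag marking rows whose printed
#' statistics are arithmetically consistent with the printed counts
#' (zero-cell rows and rows with count/percentage discrepancies are not).
#'
#' @return A tibble; `printed_p` is kept as character to preserve the
#'   published precision.
#' @export
published_counts <- function() {
  path <- kirscreen_extdata("published_counts.tsv")
  tab <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    na = "NA",
    col_types = readr::cols(
      printed_p = readr::col_character(),
      printed_pc = readr::col_character(),
      reproducible = readr::col_logical(),
      .default = readr::col_guess()
    )
  )
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  ver <- sub("^#\\s*version:\\s*", "", grep("version:", hdr, value = TRUE))
  attr(tab, "version") <- if (length(ver)) ver else NA_character_
  tab
}

#' Flag internally inconsistent published rows
#'
#' Recomputes each carrier percentage from its printed count and stratum
#' size and compares against the printed percentage. A deviation beyond
#' rounding slop (0.15 percentage points) flags the row: its printed
#' statistics follow the percentage, not the count, and must not be used
#' for exact regression.
#'
#' @param counts Tibble from [published_counts()].
#' @return `counts` with logical `pct_mismatch_control` /
#'   `pct_mismatch_case` and combined `pct_mismatch` columns.
#' @export
validate_published_counts <- function(counts = published_counts()) {
  dev_ctrl <- abs(round_half_up(100 * counts$control_n / counts$control_N, 1) -
                  counts$printed_pct_control)
  dev_case <- abs(round_half_up(100 * counts$case_n / counts$case_N, 1) -
                  counts$printed_pct_case)
  counts$pct_mismatch_control <- dev_ctrl > 0.15
  counts$pct_mismatch_case <- dev_case > 0.15
  counts$pct_mismatch <- counts$pct_mismatch_control | counts$pct_mismatch_case
  counts
}
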