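split_allele_field <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "."] <- ""
  stringr::str_split(x, ";")
}

#' Test per-sample carriage of a KIR allele
#'
#' A sample carries an allele if any of its calls at the gene, truncated
#' to the query's resolution, equals the query (so a query of `2DL1*002`
#' matches a call of `00201`). Samples untyped at the gene (empty allele
#' column) get `NA`, which downstream counting treats as
#' excluded-from-denominator -- distinct from a confirmed non-carrier.
#'
#' @param data Genotype tibble with per-gene allele-call columns such as
#'   `kir2dl1_alleles` (semicolon-separated allele fields).
#' @param allele Query allele name, e.g. `"2DL1*00201"`.
#' @return Logical vector (with `NA` for untyped samples).
#' @export
#' @examples
#' g <- simulate_cohort(n = c(control = 5), seed = 1)
#' carries_kir_allele(g, "2DL1*003")
carries_kir_allele <- function(data, allele) {
  q <- parse_kir_allele(allele)
  stopifnot(nrow(q) == 1L)
  col <- allele_col(q$gene)
  if (!col %in% names(data)) {
    rlang::abort(paste0("no allele-call column '", col, "' in the data"))
  }
  calls <- split_allele_field(data[[col]])
  vapply(calls, function(fields) {
    fields <- fields[nzchar(fields)]
    if (length(fields) == 0L) return(NA)
    any(field_matches(fields, q$field))
  }, logical(1))
}

# per-sample membership of an allotype group (any call in the group)
carries_kir_allotype <- function(data, scheme, group) {
  if (is.character(scheme)) scheme <- kir_allotype_scheme(scheme)
  gene <- attr(scheme, "gene")
  col <- allele_col(gene)
  calls <- split_allele_field(data[[col]])
  vapply(calls, function(fields) {
    fields <- fields[nzchar(fields)]
    if (length(fields) == 0L) return(NA)
    any(assign_kir_allotype(paste0(gene, "*", fields), scheme) == group)
  }, logical(1))
}

#' Call a KIR-HLA receptor-ligand interaction
#'
#' An interaction such as `2DL1*00201+C2` is positive for a sample iff it
#' carries the KIR allele (at the stated resolution) AND its ligand
#' profile carries the cognate HLA epitope. Samples untyped at the KIR
#' gene propagate `NA`.
#'
#' @param data Genotype tibble that already carries ligand-profile
#'   columns (see [build_ligand_profile()]).
#' @param allele KIR allele name, e.g. `"2DL1*00201"`.
#' @param ligand Ligand flag name: one of `"C1"`, `"C2"`, `"Bw4-80I"`,
#'   `"Bw4-80T"`, `"Bw6"`, `"A-Bw4"`, `"A3/11"` (or the corresponding
#'   `lig_*` column name).
#' @return Logical vector.
#' @export
call_interaction <- function(data, allele, ligand) {
  flag <- ligand_flag_col(ligand)
  if (!flag %in% names(data)) {
    rlang::abort(paste0(
      "no ligand column '", flag, "': run build_ligand_profile() first"
    ))
  }
  carries_kir_allele(data, allele) & data[[flag]]
}

ligand_flag_col <- function(ligand) {
  if (ligand %in% ligand_flags) return(ligand)
  hit <- epitope_to_flag[ligand]
  if (is.na(hit)) {
    rlang::abort(paste0(
      "unknown ligand '", ligand, "'; expected one of ",
      paste(names(epitope_to_flag), collapse = ", ")
    ))
  }
  unname(hit)
}

#' Count carriers of a feature in a stratum
#'
#' Observed (carrier) frequency: the number of feature-positive samples
#' divided by the number of samples evaluable for the feature (samples
#' untyped for the feature's gene are excluded from the denominator).
#' Percentages are rounded half-up to one decimal, the convention of the
#' published tables.
#'
#' @param flags Logical vector of per-sample feature calls (`NA` =
#'   untyped).
#' @return A one-row tibble with `n` (carriers), `N` (evaluable samples)
#'   and `pct`.
#' @export
#' @examples
#' count_carriers(c(TRUE, TRUE, FALSE, NA))
count_carriers <- function(flags) {
  N <- sum(!is.na(flags))
  if (N == 0L) rlang::abort("no evaluable samples in the stratum")
  n <- sum(flags, na.rm = TRUE)
  tibble::tibble(n = n, N = N, pct = round_half_up(100 * n / N, 1))
}

#' Build a 2x2 carrier contingency table
#'
#' Arranges control and case carrier counts into the cells used by the
#' association statistics: `a` = control carriers, `b` = control
#' non-carriers, `c` = case carriers, `d` = case non-carriers.
#'
#' @param controls,cases One-row tibbles from [count_carriers()] (or any
#'   list with `n` and `N`).
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' tabulate_2x2(count_carriers(rep(c(TRUE, FALSE), c(48, 119))),
#'              count_carriers(rep(c(TRUE, FALSE), c(31, 131))))
tabulate_2x2 <- function(controls, cases) {
  tibble::tibble(
    a = controls$n, b = controls$N - controls$n,
    c = cases$n, d = cases$N - cases$n
  )
}

#' Define screen features
#'
#' Helper constructors for the feature-definition tibble consumed by
#' [kir_screen()] and [simulate_cohort()]. A feature is one of:
#' \describe{
#'   \item{allele}{carriage of a KIR allele at a stated resolution;}
#'   \item{allotype}{carriage of any allele of an allotype group;}
#'   \item{ligand}{a ligand-profile flag;}
#'   \item{interaction}{a receptor-ligand pair (allele AND ligand).}
#' }
#'
#' @param allele KIR allele name.
#' @param ligand Ligand epitope name (e.g. `"C2"`).
#' @param scheme Allotype scheme name (e.g. `"KIR3DL3_300"`).
#' @param group Allotype group label (e.g. `"N300"`).
#' @param stratum KIR genotype stratum the feature is screened in:
#'   `"AA"`, `"Bx"` or `"all"`.
#' @param name Feature display name; a default is derived.
#' @return A one-row feature tibble; rows from several constructors are
#'   combined with [dplyr::bind_rows()].
#' @export
#' @examples
#' dplyr::bind_rows(
#'   feature_allele("3DL3*009"),
#'   feature_interaction("2DL1*00201", "C2")
#' )
feature_allele <- function(allele, stratum = "AA", name = allele) {
  allele <- parse_kir_allele(allele)$allele
  tibble::tibble(feature = name, type = "allele", gene = NA_character_,
                 allele = allele, scheme = NA_character_,
                 group = NA_character_, ligand = NA_character_,
                 stratum = stratum)
}

#' @rdname feature_allele
#' @export
feature_interaction <- function(allele, ligand, stratum = "AA",
                                name = paste0(allele, "+", ligand)) {
  allele <- parse_kir_allele(allele)$allele
  ligand_flag_col(ligand)  # validate
  tibble::tibble(feature = name, type = "interaction",
                 gene = NA_character_, allele = allele,
                 scheme = NA_character_, group = NA_character_,
                 ligand = ligand, stratum = stratum)
}

#' @rdname feature_allele
#' @export
feature_ligand <- function(ligand, stratum = "AA", name = ligand) {
  ligand_flag_col(ligand)
  tibble::tibble(feature = name, type = "ligand", gene = NA_character_,
                 allele = NA_character_, scheme = NA_character_,
                 group = NA_character_, ligand = ligand, stratum = stratum)
}

#' @rdname feature_allele
#' @export
feature_allotype <- function(scheme, group, stratum = "AA",
                             name = paste0(scheme, ":", group)) {
  tibble::tibble(feature = name, type = "allotype", gene = NA_character_,
                 allele = NA_character_, scheme = scheme, group = group,
                 ligand = NA_character_, stratum = stratum)
}

# evaluate one feature row -> per-sample logical flags
feature_flags <- function(data, frow) {
  switch(frow$type,
    allele = carries_kir_allele(data, frow$allele),
    allotype = carries_kir_allotype(data, frow$scheme, frow$group),
    ligand = data[[ligand_flag_col(frow$ligand)]],
    interaction = call_interaction(data, frow$allele, frow$ligand),
    rlang::abort(paste0("unknown feature type: ", frow$type))
  )
}

# gene a feature belongs to, for the per-gene Bonferroni family policy
feature_family <- function(features) {
  gene_of <- function(i) {
    f <- features[i, ]
    if (!is.na(f$allele)) parse_kir_allele(f$allele)$gene
    else if (!is.na(f$scheme)) attr(kir_allotype_scheme(f$scheme), "gene")
    else "ligand"
  }
  vapply(seq_len(nrow(features)), gene_of, character(1))
}

#' Add feature-call columns to a cohort
#'
#' Evaluates every feature of a definition tibble on every sample and
#' appends one logical column per feature (named by the feature). Flags
#' are recomputable at any time from the genotype and ligand profile; no
#' free-floating state is kept.
#'
#' @param data Classified cohort tibble (genotype + ligand profile).
#' @param features Feature tibble (see [feature_allele()]).
#' @return `data` with one logical column per feature.
#' @export
add_feature_flags <- function(data, features) {
  for (i in seq_len(nrow(features))) {
    data[[features$feature[i]]] <- feature_flags(data, features[i, ])
  }
  data
}
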