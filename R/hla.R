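#' Packaged HLA residue/epitope reference table
#'
#' The allele-to-residue map used for KIR-ligand epitope calling, compiled
#' for common Chinese-Han class I alleles and release-tagged (see the
#' `"version"` attribute). Columns: `locus`, `allele`, `res77`, `res80`
#' (amino acids at mature-protein positions 77 and 80) and `epitope`.
#'
#' @return A tibble; its `"version"` attribute carries the release tag.
#' @export
#' @examples
#' head(hla_residue_table())
hla_residue_table <- function() {
  read_reference_tsv(kirscreen_extdata("hla_kir_ligand_residues.tsv"))
}

parse_hla_allele <- function(x) {
  x <- stringr::str_trim(x)
  m <- stringr::str_match(x, "^(?:HLA-)?([ABC])\\*([0-9]{2,3})(?::([0-9]{2,3}))?$")
  tibble::tibble(
    raw = x,
    locus = m[, 2],
    group = ifelse(is.na(m[, 2]), NA, paste0(m[, 2], "*", m[, 3])),
    allele = ifelse(is.na(m[, 4]), NA,
                    paste0(m[, 2], "*", m[, 3], ":", m[, 4]))
  )
}

# shared lookup for B and C: 4-digit first, then 2-digit group consensus
# (used only when every 4-digit member of the group shares an epitope)
lookup_epitope <- function(parsed, residue_table, locus) {
  tab <- residue_table[residue_table$locus == locus, ]
  idx <- match(parsed$allele, tab$allele)
  epitope <- tab$epitope[idx]
  res77 <- tab$res77[idx]
  res80 <- tab$res80[idx]
  # 2-digit fallback
  miss <- which(is.na(epitope) & !is.na(parsed$group))
  if (length(miss) > 0L) {
    grp <- sub(":.*$", "", sub("^([ABC]\\*[0-9]+).*", "\\1", tab$allele))
    consensus <- tapply(tab$epitope, grp, function(e) {
      if (length(unique(e)) == 1L) unique(e) else NA_character_
    })
    hit <- consensus[parsed$group[miss]]
    epitope[miss] <- unname(hit)
  }
  unknown <- is.na(epitope)
  if (any(unknown)) {
    rlang::warn(
      paste0("HLA-", locus, " allele(s) not in the residue table, ",
             "classified as unknown: ",
             paste(unique(parsed$raw[unknown]), collapse = ", ")),
      class = "kirscreen_unknown_hla"
    )
    epitope[unknown] <- "unknown"
  }
  tibble::tibble(
    allele = parsed$raw, locus = locus, epitope = epitope,
    res77 = res77, res80 = res80
  )
}

#' Classify HLA class I alleles into KIR-ligand epitope groups
#'
#' `classify_hla_c()` assigns HLA-C alleles to the C1 (Asn at position 80)
#' or C2 (Lys80) ligand group; C1 is the ligand of KIR2DL2/3 and C2 of
#' KIR2DL1. `classify_hla_b()` assigns HLA-B alleles to Bw4-80I (Bw4
#' motif, Ile80), Bw4-80T (Bw4, Thr80) or Bw6; only Bw4 allotypes are
#' ligands of KIR3DL1, with Ile80 binding more strongly than Thr80.
#' `classify_hla_a()` is rule-based at the allele-group level: A*23, A*24
#' and A*32 carry the Bw4 motif (`A-Bw4`); A*03 and A*11 interact with
#' KIR3DL2 (`A3/11`); other A alleles are `none`.
#'
#' B and C lookups use the residue table at 4-digit resolution, falling
#' back to the 2-digit allele group when all its 4-digit members share an
#' epitope. Alleles still unresolved are classified `"unknown"` with a
#' warning, never an error.
#'
#' @param x Character vector of 4-digit allele names (e.g. `"C*07:02"`).
#' @param residue_table Residue reference, default [hla_residue_table()].
#' @return A tibble with columns `allele`, `locus`, `epitope`, `res77`,
#'   `res80` (residues are `NA` for rule-based A-locus calls).
#' @export
#' @examples
#' classify_hla_c(c("C*07:02", "C*04:01"))
#' classify_hla_b(c("B*51:01", "B*44:02", "B*07:02"))
#' classify_hla_a(c("A*24:02", "A*11:01", "A*02:01"))
classify_hla_c <- function(x, residue_table = hla_residue_table()) {
  p <- parse_hla_allele(x)
  if (any(is.na(p$locus) | p$locus != "C")) {
    rlang::abort("classify_hla_c() expects HLA-C allele names")
  }
  lookup_epitope(p, residue_table, "C")
}

#' @rdname classify_hla_c
#' @export
classify_hla_b <- function(x, residue_table = hla_residue_table()) {
  p <- parse_hla_allele(x)
  if (any(is.na(p$locus) | p$locus != "B")) {
    rlang::abort("classify_hla_b() expects HLA-B allele names")
  }
  lookup_epitope(p, residue_table, "B")
}

#' @rdname classify_hla_c
#' @export
classify_hla_a <- function(x) {
  p <- parse_hla_allele(x)
  if (any(is.na(p$locus) | p$locus != "A")) {
    rlang::abort("classify_hla_a() expects HLA-A allele names")
  }
  epitope <- dplyr::case_when(
    p$group %in% c("A*23", "A*24", "A*32") ~ "A-Bw4",
    p$group %in% c("A*03", "A*11") ~ "A3/11",
    TRUE ~ "none"
  )
  tibble::tibble(
    allele = p$raw, locus = "A", epitope = epitope,
    res77 = NA_character_, res80 = NA_character_
  )
}

ligand_flags <- c("lig_c1", "lig_c2", "lig_bw4_80i", "lig_bw4_80t",
                  "lig_bw6", "lig_a_bw4", "lig_a3_11")

epitope_to_flag <- c(
  "C1" = "lig_c1", "C2" = "lig_c2",
  "Bw4-80I" = "lig_bw4_80i", "Bw4-80T" = "lig_bw4_80t", "Bw6" = "lig_bw6",
  "A-Bw4" = "lig_a_bw4", "A3/11" = "lig_a3_11"
)

#' Build per-sample KIR-ligand profiles from HLA typing
#'
#' Derives the boolean ligand content of each sample -- `lig_c1`,
#' `lig_c2`, `lig_bw4_80i`, `lig_bw4_80t`, `lig_bw6`, `lig_a_bw4`,
#' `lig_a3_11` -- as the OR over the epitope calls of its 2-6 carried
#' class I alleles (homozygous typings behave like a single allele).
#' Alleles that cannot be classified contribute `FALSE` to every flag and
#' are counted in `hla_unknown_n`.
#'
#' @param data A tibble with columns `hla_a1`, `hla_a2`, `hla_b1`,
#'   `hla_b2`, `hla_c1`, `hla_c2` holding 4-digit allele names (`NA` or
#'   `"."` for an untyped slot). Every sample must have at least one B and
#'   one C allele.
#' @param residue_table Residue reference, default [hla_residue_table()].
#' @param c1_bearing_b If `TRUE`, B*46:01 and B*73:01 also contribute the
#'   C1 epitope. Off by default: the standard ligand definition keeps the
#'   C1/C2 split on HLA-C.
#' @return `data` with the seven logical ligand columns and
#'   `hla_unknown_n` appended.
#' @export
#' @examples
#' d <- tibble::tibble(sample_id = "s1",
#'   hla_a1 = "A*02:01", hla_a2 = "A*24:02",
#'   hla_b1 = "B*07:02", hla_b2 = "B*51:01",
#'   hla_c1 = "C*07:02", hla_c2 = "C*04:01")
#' build_ligand_profile(d)
build_ligand_profile <- function(data, residue_table = hla_residue_table(),
                                 c1_bearing_b = FALSE) {
  cols <- list(A = c("hla_a1", "hla_a2"), B = c("hla_b1", "hla_b2"),
               C = c("hla_c1", "hla_c2"))
  missing_cols <- setdiff(unlist(cols), names(data))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("missing HLA typing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  norm <- function(v) {
    v <- as.character(v)
    v[!is.na(v) & (v == "." | v == "")] <- NA
    v
  }
  typing <- lapply(unlist(cols), function(cn) norm(data[[cn]]))
  names(typing) <- unlist(cols)

  for (locus in c("B", "C")) {
    got <- !is.na(typing[[cols[[locus]][1]]]) | !is.na(typing[[cols[[locus]][2]]])
    if (!all(got)) {
      ids <- if ("sample_id" %in% names(data)) data$sample_id else seq_len(nrow(data))
      rlang::abort(paste0(
        "sample(s) without any HLA-", locus, " typing: ",
        paste(utils::head(ids[!got], 5L), collapse = ", ")
      ))
    }
  }

  # classify each distinct allele once
  call_locus <- function(locus) {
    alleles <- unique(stats::na.omit(unlist(typing[cols[[locus]]])))
    if (length(alleles) == 0L) {
      return(tibble::tibble(allele = character(), epitope = character()))
    }
    switch(locus,
      A = classify_hla_a(alleles),
      B = classify_hla_b(alleles, residue_table),
      C = classify_hla_c(alleles, residue_table)
    )[, c("allele", "epitope")]
  }
  calls <- dplyr::bind_rows(lapply(names(cols), call_locus))

  n <- nrow(data)
  flags <- matrix(FALSE, n, length(ligand_flags),
                  dimnames = list(NULL, ligand_flags))
  unknown_n <- integer(n)
  c1_b <- c("B*46:01", "B*73:01")
  for (cn in unlist(cols)) {
    ep <- calls$epitope[match(typing[[cn]], calls$allele)]
    hit <- !is.na(ep) & ep %in% names(epitope_to_flag)
    if (any(hit)) {
      flags[cbind(which(hit), match(epitope_to_flag[ep[hit]], ligand_flags))] <- TRUE
    }
    if (c1_bearing_b) {
      extra <- !is.na(typing[[cn]]) & typing[[cn]] %in% c1_b
      flags[extra, "lig_c1"] <- TRUE
    }
    unknown_n <- unknown_n + as.integer(!is.na(ep) & ep == "unknown")
  }
  out <- dplyr::bind_cols(data, tibble::as_tibble(flags))
  out$hla_unknown_n <- unknown_n
  out
}
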