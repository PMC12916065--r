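#' KIR locus symbols
#'
#' The sixteen loci of the KIR gene cluster on chromosome 19q13.4:
#' fourteen functional genes and the two pseudogenes (2DP1, 3DP1).
#' `kir_a_haplotype_genes()` returns the seven functional genes carried by
#' the A haplotype (whose only activating gene is 2DS4);
#' `kir_b_specific_genes()` the activating/inhibitory genes specific to B
#' haplotypes; `kir_framework_genes()` the four framework genes present on
#' virtually all haplotypes.
#'
#' @return A character vector of locus symbols (without the "KIR" prefix).
#' @export
#' @examples
#' kir_loci()
#' kir_a_haplotype_genes()
kir_loci <- function() {
  c("2DL1", "2DL2", "2DL3", "2DL4", "2DL5",
    "2DS1", "2DS2", "2DS3", "2DS4", "2DS5",
    "3DL1", "3DL2", "3DL3", "3DS1", "2DP1", "3DP1")
}

#' @rdname kir_loci
#' @export
kir_a_haplotype_genes <- function() {
  c("2DL1", "2DL3", "2DL4", "3DL1", "3DL2", "3DL3", "2DS4")
}

#' @rdname kir_loci
#' @export
kir_b_specific_genes <- function() {
  c("2DL2", "2DL5", "2DS1", "2DS2", "2DS3", "2DS5", "3DS1")
}

#' @rdname kir_loci
#' @export
kir_framework_genes <- function() {
  c("3DL3", "3DP1", "2DL4", "3DL2")
}

#' @rdname kir_loci
#' @export
kir_pseudogenes <- function() {
  c("2DP1", "3DP1")
}

#' Parse KIR allele names
#'
#' Parses IPD-KIR-style allele names such as `"KIR2DL1*00201"` or
#' `"3DL3*009"` into locus symbol and numeric allele field. The leading
#' `"KIR"` prefix and surrounding whitespace are optional; the numeric
#' field must have 3, 5 or 7 digits (allele group, protein, and coding
#' resolution respectively).
#'
#' @param x Character vector of allele names.
#' @return A tibble with one row per input: `raw` (input as given), `gene`
#'   (locus symbol), `field` (digit string), and `allele` (canonical form
#'   `"GENE*FIELD"`).
#' @export
#' @examples
#' parse_kir_allele(c("KIR2DL1*00201", "3DL3*009"))
parse_kir_allele <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  raw <- x
  x <- stringr::str_trim(x)
  if (any(!nzchar(x))) {
    rlang::abort("empty KIR allele name")
  }
  m <- stringr::str_match(x, "^(?:KIR)?([23]D[LSP][0-9])\\*([0-9]+)$")
  bad_shape <- is.na(m[, 1])
  if (any(bad_shape)) {
    rlang::abort(paste0(
      "cannot parse KIR allele name(s): ",
      paste(unique(raw[bad_shape]), collapse = ", ")
    ))
  }
  gene <- m[, 2]
  field <- m[, 3]
  unknown <- !(gene %in% kir_loci())
  if (any(unknown)) {
    rlang::abort(paste0(
      "unknown KIR locus symbol(s): ",
      paste(unique(gene[unknown]), collapse = ", ")
    ))
  }
  badlen <- !(nchar(field) %in% c(3L, 5L, 7L))
  if (any(badlen)) {
    rlang::abort(paste0(
      "invalid allele field length (must be 3, 5 or 7 digits): ",
      paste(unique(raw[badlen]), collapse = ", ")
    ))
  }
  tibble::tibble(
    raw = raw,
    gene = gene,
    field = field,
    allele = paste0(gene, "*", field)
  )
}

#' Truncate KIR allele resolution
#'
#' Truncates allele numeric fields to 3- or 5-digit resolution, e.g.
#' `2DL1*00201` at 3 digits is `2DL1*002` (the allele group encoding the
#' same protein change class). Truncating to the current length is the
#' identity; requesting more digits than present is an error (resolution
#' is never invented by padding).
#'
#' @param x Character vector of allele names (any accepted spelling).
#' @param digits Target resolution: 3 or 5.
#' @return Character vector of canonical truncated allele names.
#' @export
#' @examples
#' truncate_kir_allele("2DL1*00201", 3)
truncate_kir_allele <- function(x, digits) {
  stopifnot(length(digits) == 1L, digits %in% c(3L, 5L))
  p <- parse_kir_allele(x)
  short <- nchar(p$field) < digits
  if (any(short)) {
    rlang::abort(paste0(
      "cannot truncate to ", digits, " digits (field is shorter): ",
      paste(unique(p$allele[short]), collapse = ", ")
    ))
  }
  paste0(p$gene, "*", substr(p$field, 1L, digits))
}

# does each call field match the query field at the query's resolution?
# (calls shorter than the query cannot be confirmed -> FALSE)
field_matches <- function(call_field, query_field) {
  nq <- nchar(query_field)
  nchar(call_field) >= nq & substr(call_field, 1L, nq) == query_field
}
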