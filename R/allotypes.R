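allotype_scheme_files <- c(
  KIR3DL3_300 = "allotype_kir3dl3_300.tsv",
  KIR2DL1_245 = "allotype_kir2dl1_245.tsv",
  KIR2DL1_114 = "allotype_kir2dl1_114_synthetic.tsv",
  KIR3DL1_expr = "allotype_kir3dl1_expr.tsv"
)

#' Load a KIR allotype grouping scheme
#'
#' Allotype schemes group KIR alleles by a functional protein dimorphism:
#' \describe{
#'   \item{`KIR3DL3_300`}{residue at mature-protein position 300 in the
#'     transmembrane domain: N300 (e.g. *001, *006), H300 (e.g. *002,
#'     *008, *009) or Y300 (e.g. *003, *004; absent in Chinese Hans).}
#'   \item{`KIR2DL1_245`}{transmembrane residue 245: R245 alleles (e.g.
#'     *001, *002, *003) are functionally stronger inhibitors than C245
#'     alleles (e.g. *004, *007).}
#'   \item{`KIR2DL1_114`}{residue 114 (P114/L114). The packaged grouping
#'     is a synthetic placeholder (see the file header): use it to
#'     exercise the machinery, not as a curated reference.}
#'   \item{`KIR3DL1_expr`}{surface-expression class: high, low (e.g.
#'     *005, *007) or null (*004).}
#' }
#' Tables are shipped as versioned TSVs (one per scheme); the release tag
#' is attached as the `"version"` attribute and echoed in reports.
#' Alleles absent from a table are classified `"unassigned"`, never
#' silently defaulted.
#'
#' @param name Scheme name, one of the four above.
#' @return A tibble with columns `gene`, `allele_field`, `group`,
#'   `residue`, `position`, plus `gene`/`position`/`version` attributes.
#' @export
#' @examples
#' kir_allotype_scheme("KIR3DL3_300")
kir_allotype_scheme <- function(name = names(allotype_scheme_files)) {
  name <- match.arg(name)
  tab <- read_reference_tsv(kirscreen_extdata(allotype_scheme_files[[name]]))
  tab$allele_field <- sprintf("%03d", as.integer(tab$allele_field))
  attr(tab, "scheme") <- name
  attr(tab, "gene") <- tab$gene[1]
  tab
}

#' Assign KIR alleles to allotype groups
#'
#' Looks each allele up in an allotype scheme at the scheme's resolution
#' (alleles are truncated to 3 digits first, so `2DL1*00201` is grouped
#' with the `002` allele group). Alleles not covered by the table are
#' returned as `"unassigned"`.
#'
#' @param x Character vector of allele names; every allele must belong to
#'   the scheme's gene.
#' @param scheme A scheme tibble from [kir_allotype_scheme()], or a scheme
#'   name.
#' @return Character vector of group labels (e.g. `"N300"`, `"C245"`,
#'   `"unassigned"`).
#' @export
#' @examples
#' assign_kir_allotype(c("3DL3*001", "3DL3*009"), "KIR3DL3_300")
assign_kir_allotype <- function(x, scheme) {
  if (is.character(scheme) && length(scheme) == 1L) {
    scheme <- kir_allotype_scheme(scheme)
  }
  p <- parse_kir_allele(x)
  gene <- attr(scheme, "gene")
  off <- p$gene != gene
  if (any(off)) {
    rlang::abort(paste0(
      "allele(s) do not belong to the ", attr(scheme, "scheme"),
      " scheme gene KIR", gene, ": ",
      paste(unique(p$allele[off]), collapse = ", ")
    ))
  }
  key <- substr(p$field, 1L, 3L)
  idx <- match(key, scheme$allele_field)
  out <- scheme$group[idx]
  out[is.na(out)] <- "unassigned"
  out
}
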