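presence_col <- function(gene) paste0("kir", tolower(gene))
allele_col <- function(gene) paste0("kir", tolower(gene), "_alleles")

#' Classify KIR genotypes as AA or Bx
#'
#' Individuals homozygous for KIR A haplotypes carry exactly the fixed
#' A-haplotype gene content -- the seven functional genes 2DL1, 2DL3,
#' 2DL4, 3DL1, 3DL2, 3DL3 and 2DS4 (the only activating gene) -- and none
#' of the B-haplotype-specific genes (2DL2, 2DL5, 2DS1, 2DS2, 2DS3, 2DS5,
#' 3DS1). Such samples are classified `AA`; anything else (AB or BB gene
#' content) is `Bx`. Pseudogenes (2DP1, 3DP1) are carried in the presence
#' map but ignored by the rule.
#'
#' The four framework genes (3DL3, 3DP1, 2DL4, 3DL2) are present on
#' virtually all haplotypes; a sample missing one is rejected as a
#' data-quality error rather than classified.
#'
#' @param data A genotype tibble with one row per sample carrying the 16
#'   presence columns `kir2dl1` ... `kir3dp1` (0/1), e.g. as produced by
#'   [simulate_cohort()] or [read_genotype_table()].
#' @return `data` with a `kir_genotype` character column (`"AA"`/`"Bx"`)
#'   appended.
#' @export
#' @examples
#' g <- simulate_cohort(n = c(control = 20), seed = 1)
#' classify_kir_genotype(g) |> dplyr::count(kir_genotype)
classify_kir_genotype <- function(data) {
  need <- presence_col(setdiff(kir_loci(), kir_pseudogenes()))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0(
      "genotype table is missing presence column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }

  fw <- kir_framework_genes()
  fw_cols <- intersect(presence_col(fw), names(data))
  fw_mat <- as.matrix(data[fw_cols]) == 1
  if (anyNA(fw_mat) || !all(fw_mat)) {
    bad <- which(!fw_mat | is.na(fw_mat), arr.ind = TRUE)
    ids <- if ("sample_id" %in% names(data)) data$sample_id else seq_len(nrow(data))
    msgs <- unique(paste0(
      ids[bad[, 1]], " lacks framework gene ",
      toupper(sub("^kir", "KIR", fw_cols[bad[, 2]]))
    ))
    rlang::abort(c(
      "framework KIR genes must be present on every sample:",
      utils::head(msgs, 5L)
    ))
  }

  a_mat <- as.matrix(data[presence_col(kir_a_haplotype_genes())]) == 1
  b_mat <- as.matrix(data[presence_col(kir_b_specific_genes())]) == 1
  is_aa <- rowSums(a_mat) == ncol(a_mat) & rowSums(b_mat) == 0
  dplyr::mutate(data, kir_genotype = ifelse(is_aa, "AA", "Bx"))
}
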