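# builders for hand-crafted genotype rows in the canonical table layout

aa_presence <- function() {
  pres <- stats::setNames(rep(0L, 16), paste0("kir", tolower(kir_loci())))
  pres[paste0("kir", tolower(c(kir_a_haplotype_genes(), kir_pseudogenes())))] <- 1L
  pres
}

make_sample <- function(sample_id = "s1", cohort = "control",
                        presence = aa_presence(),
                        alleles = list(),
                        hla = c(hla_a1 = "A*02:01", hla_a2 = "A*24:02",
                                hla_b1 = "B*07:02", hla_b2 = "B*51:01",
                                hla_c1 = "C*07:02", hla_c2 = "C*04:01")) {
  row <- tibble::as_tibble(as.list(presence))
  for (g in kir_a_haplotype_genes()) {
    cn <- paste0("kir", tolower(g), "_alleles")
    row[[cn]] <- if (g %in% names(alleles)) paste(alleles[[g]], collapse = ";") else ""
  }
  dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id, cohort = cohort),
    row,
    tibble::as_tibble(as.list(hla))
  )
}

# independent Fisher oracle: exhaustive enumeration with binomial
# coefficients (no dhyper), point-probability rule
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  supp <- max(0, k - r2):min(k, r1)
  probs <- choose(r1, supp) * choose(r2, k - supp) / choose(n, k)
  obs <- probs[supp == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

random_tables <- function(n_tables, max_cell = 200) {
  tibble::tibble(
    a = sample.int(max_cell, n_tables, replace = TRUE),
    b = sample.int(max_cell, n_tables, replace = TRUE),
    c = sample.int(max_cell, n_tables, replace = TRUE),
    d = sample.int(max_cell, n_tables, replace = TRUE)
  )
}
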