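test_that("HLA-C alleles split into C1 and C2 by the residue at position 80", {
  calls <- classify_hla_c(c("C*07:02", "C*04:01"))
  expect_equal(calls$epitope, c("C1", "C2"))
  expect_equal(calls$res80, c("N", "K"))
  expect_equal(calls$res77, c("S", "N"))
})

test_that("HLA-B alleles split into Bw4-80I, Bw4-80T and Bw6", {
  calls <- classify_hla_b(c("B*51:01", "B*44:02", "B*07:02"))
  expect_equal(calls$epitope, c("Bw4-80I", "Bw4-80T", "Bw6"))
  expect_equal(calls$res80, c("I", "T", "N"))
})

test_that("HLA-A ligand groups are rule-based on the allele group", {
  calls <- classify_hla_a(c("A*24:02", "A*23:01", "A*32:01", "A*11:01",
                            "A*03:01", "A*02:01"))
  expect_equal(calls$epitope,
               c("A-Bw4", "A-Bw4", "A-Bw4", "A3/11", "A3/11", "none"))
  expect_error(classify_hla_a("B*07:02"), "HLA-A")
})

test_that("alleles absent from the residue table warn and classify unknown", {
  expect_warning(calls <- classify_hla_c("C*99:99"), "unknown")
  expect_equal(calls$epitope, "unknown")
})

test_that("2-digit fallback applies only when the group is epitope-consistent", {
  # all packaged C*07 alleles are C1; C*16 mixes C1 and C2
  expect_silent(calls <- classify_hla_c("C*07:99"))
  expect_equal(calls$epitope, "C1")
  expect_warning(calls <- classify_hla_c("C*16:99"), "unknown")
  expect_equal(calls$epitope, "unknown")
})

test_that("every packaged C allele is exactly one of C1/C2 and every B allele
           exactly one of Bw4-80I/Bw4-80T/Bw6", {
  tab <- hla_residue_table()
  expect_true(all(tab$epitope[tab$locus == "C"] %in% c("C1", "C2")))
  expect_true(all(tab$epitope[tab$locus == "B"] %in%
                    c("Bw4-80I", "Bw4-80T", "Bw6")))
  expect_equal(anyDuplicated(tab$allele), 0L)
})

test_that("table epitopes agree with re-derivation from the raw residue 80", {
  tab <- hla_residue_table()
  derived <- ifelse(tab$locus == "C",
                    ifelse(tab$res80 == "N", "C1",
                           ifelse(tab$res80 == "K", "C2", "?")),
                    ifelse(tab$res80 == "I", "Bw4-80I",
                           ifelse(tab$res80 == "T", "Bw4-80T",
                                  ifelse(tab$res80 == "N", "Bw6", "?"))))
  expect_equal(tab$epitope, derived)
  # and the classifiers reproduce the table over its full contents
  cc <- classify_hla_c(tab$allele[tab$locus == "C"])
  expect_equal(cc$epitope, tab$epitope[tab$locus == "C"])
  cb <- classify_hla_b(tab$allele[tab$locus == "B"])
  expect_equal(cb$epitope, tab$epitope[tab$locus == "B"])
})

test_that("ligand profiles are the OR over carried alleles", {
  d <- tibble::tibble(
    sample_id = "s1",
    hla_a1 = "A*02:01", hla_a2 = "A*24:02",
    hla_b1 = "B*07:02", hla_b2 = "B*51:01",
    hla_c1 = "C*07:02", hla_c2 = "C*04:01"
  )
  pr <- build_ligand_profile(d)
  expect_true(pr$lig_c1 & pr$lig_c2 & pr$lig_bw4_80i & pr$lig_bw6 & pr$lig_a_bw4)
  expect_false(pr$lig_a3_11 | pr$lig_bw4_80t)
  expect_equal(pr$hla_unknown_n, 0L)
})

test_that("homozygous typings behave like a single allele", {
  d <- make_sample(hla = c(hla_a1 = "A*02:01", hla_a2 = "A*02:01",
                           hla_b1 = "B*07:02", hla_b2 = "B*07:02",
                           hla_c1 = "C*07:02", hla_c2 = "C*07:02"))
  pr <- build_ligand_profile(d)
  expect_true(pr$lig_c1 & pr$lig_bw6)
  expect_false(pr$lig_c2 | pr$lig_bw4_80i | pr$lig_bw4_80t)
})

test_that("adding an allele can only turn ligand flags on", {
  base <- make_sample(hla = c(hla_a1 = "A*02:01", hla_a2 = ".",
                              hla_b1 = "B*07:02", hla_b2 = ".",
                              hla_c1 = "C*07:02", hla_c2 = "."))
  more <- make_sample(hla = c(hla_a1 = "A*02:01", hla_a2 = "A*11:01",
                              hla_b1 = "B*07:02", hla_b2 = "B*44:02",
                              hla_c1 = "C*07:02", hla_c2 = "C*04:01"))
  f0 <- unlist(build_ligand_profile(base)[paste0("lig_",
          c("c1", "c2", "bw4_80i", "bw4_80t", "bw6", "a_bw4", "a3_11"))])
  f1 <- unlist(build_ligand_profile(more)[names(f0)])
  expect_true(all(f1 >= f0))
})

test_that("unresolvable alleles count as unknown, profile otherwise false", {
  d <- make_sample(hla = c(hla_a1 = "A*98:99", hla_a2 = ".",
                           hla_b1 = "B*98:99", hla_b2 = ".",
                           hla_c1 = "C*98:99", hla_c2 = "."))
  expect_warning(expect_warning(pr <- build_ligand_profile(d)))
  expect_false(any(unlist(pr[c("lig_c1", "lig_c2", "lig_bw4_80i",
                               "lig_bw4_80t", "lig_bw6")])))
  expect_equal(pr$hla_unknown_n, 2L)  # B and C lookups; A is rule-based
})

test_that("samples without any B or C typing are rejected", {
  d <- make_sample(hla = c(hla_a1 = "A*02:01", hla_a2 = ".",
                           hla_b1 = ".", hla_b2 = ".",
                           hla_c1 = "C*07:02", hla_c2 = "C*04:01"))
  expect_error(build_ligand_profile(d), "HLA-B")
})

test_that("the C1-bearing B allele option is off by default", {
  d <- make_sample(hla = c(hla_a1 = "A*02:01", hla_a2 = ".",
                           hla_b1 = "B*46:01", hla_b2 = ".",
                           hla_c1 = "C*04:01", hla_c2 = "C*04:01"))
  expect_false(build_ligand_profile(d)$lig_c1)
  expect_true(build_ligand_profile(d, c1_bearing_b = TRUE)$lig_c1)
})
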