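Package: kirscreen
Title: KIR-HLA Immunogenetics Case-Control Association Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for killer-cell immunoglobulin-like receptor (KIR)
    immunogenetics case-control studies. Parses IPD-KIR-style allele names,
    classifies KIR genotypes as AA or Bx from gene content, maps alleles to
    functional allotype groups (e.g. KIR3DL3 N300/H300/Y300, KIR2DL1
    R245/C245), assigns HLA class I alleles to KIR-ligand epitope groups
    (C1/C2, Bw4-80I/80T/Bw6, A-Bw4, A3/11), calls receptor-ligand
    interactions, and runs carrier-frequency association screens with Woolf
    odds-ratio confidence intervals, Pearson/Yates chi-square and Fisher
    exact tests, and Bonferroni correction. Includes a synthetic cohort
    generator with configurable per-feature odds ratios for pipeline
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
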