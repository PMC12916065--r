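#' Case carrier probability implied by an odds ratio
#'
#' Inverts the case-versus-control odds ratio: given the control carrier
#' probability `p0` and the target odds ratio `or`, returns the case
#' carrier probability `p1` with odds(p1) = or * odds(p0), so that the
#' odds ratio recovered from (p0, p1) is exactly `or`.
#'
#' @param p0 Control carrier probability, strictly inside (0, 1).
#' @param or Odds ratio, > 0.
#' @return Case carrier probability.
#' @export
#' @examples
#' case_probability(0.305, 0.50)  # ~0.180
case_probability <- function(p0, or) {
  if (any(p0 <= 0 | p0 >= 1)) {
    rlang::abort("p0 must lie strictly inside (0, 1)")
  }
  if (any(or <= 0)) rlang::abort("odds ratio must be positive")
  o <- or * p0 / (1 - p0)
  o / (1 + o)
}

#' Default KIR allele frequency pool
#'
#' Background allele frequencies for the seven KIR A-haplotype genes used
#' by [simulate_cohort()], loosely shaped on Chinese Han allele spectra
#' (a single dominant allele at the centromeric 2DL1/2DL3, several
#' mid-frequency alleles at 3DL1/3DL2/3DL3). Frequencies are per-gene
#' sampling weights for allele calls, not estimates for any population.
#'
#' @return A tibble with columns `gene`, `field`, `freq`.
#' @export
default_allele_pool <- function() {
  tibble::tribble(
    ~gene, ~field, ~freq,
    "2DL1", "003", 0.50, "2DL1", "00302", 0.18, "2DL1", "00201", 0.16,
    "2DL1", "004", 0.08, "2DL1", "00101", 0.07, "2DL1", "069", 0.01,
    "2DL3", "001", 0.62, "2DL3", "00201", 0.17, "2DL3", "00101", 0.11,
    "2DL3", "005", 0.06, "2DL3", "007", 0.04,
    "2DL4", "00102", 0.35, "2DL4", "00103", 0.25, "2DL4", "005", 0.20,
    "2DL4", "008", 0.10, "2DL4", "011", 0.10,
    "3DL1", "01502", 0.28, "3DL1", "007", 0.18, "3DL1", "00101", 0.12,
    "3DL1", "00501", 0.12, "3DL1", "008", 0.10, "3DL1", "020", 0.10,
    "3DL1", "01501", 0.10,
    "3DL2", "001", 0.25, "3DL2", "002", 0.20, "3DL2", "007", 0.20,
    "3DL2", "010", 0.15, "3DL2", "00103", 0.20,
    "3DL3", "002", 0.30, "3DL3", "008", 0.25, "3DL3", "009", 0.17,
    "3DL3", "010", 0.18, "3DL3", "001", 0.055, "3DL3", "006", 0.045,
    "2DS4", "00101", 0.45, "2DS4", "003", 0.25, "2DS4", "004", 0.10,
    "2DS4", "006", 0.10, "2DS4", "010", 0.10
  )
}

#' Default HLA allele pools
#'
#' Class I allele sampling pools for [simulate_cohort()], restricted to
#' alleles covered by [hla_residue_table()] (plus rule-based A alleles)
#' and weighted toward common Chinese Han alleles.
#'
#' @return A tibble with columns `locus`, `allele`, `freq`, `epitope`.
#' @export
default_hla_pool <- function() {
  tibble::tribble(
    ~locus, ~allele, ~freq, ~epitope,
    "A", "A*11:01", 0.22, "A3/11", "A", "A*24:02", 0.17, "A-Bw4",
    "A", "A*02:01", 0.11, "none", "A", "A*33:03", 0.09, "none",
    "A", "A*02:03", 0.07, "none", "A", "A*02:06", 0.06, "none",
    "A", "A*30:01", 0.05, "none", "A", "A*02:07", 0.08, "none",
    "A", "A*01:01", 0.05, "none", "A", "A*26:01", 0.05, "none",
    "A", "A*31:01", 0.05, "none",
    "C", "C*01:02", 0.20, "C1", "C", "C*07:02", 0.18, "C1",
    "C", "C*03:04", 0.16, "C1", "C", "C*03:02", 0.13, "C1",
    "C", "C*08:01", 0.11, "C1", "C", "C*03:03", 0.08, "C1",
    "C", "C*12:02", 0.08, "C1", "C", "C*14:02", 0.06, "C1",
    "C", "C*06:02", 0.25, "C2", "C", "C*04:01", 0.22, "C2",
    "C", "C*15:02", 0.18, "C2", "C", "C*05:01", 0.12, "C2",
    "C", "C*02:02", 0.12, "C2", "C", "C*04:03", 0.11, "C2",
    "B", "B*40:01", 0.17, "Bw6", "B", "B*46:01", 0.15, "Bw6",
    "B", "B*15:02", 0.10, "Bw6", "B", "B*15:01", 0.08, "Bw6",
    "B", "B*35:01", 0.07, "Bw6", "B", "B*07:02", 0.06, "Bw6",
    "B", "B*54:01", 0.06, "Bw6", "B", "B*55:02", 0.05, "Bw6",
    "B", "B*27:05", 0.05, "Bw4-80T", "B", "B*37:01", 0.04, "Bw4-80T",
    "B", "B*44:03", 0.05, "Bw4-80T",
    "B", "B*58:01", 0.09, "Bw4-80I", "B", "B*13:02", 0.13, "Bw4-80I",
    "B", "B*13:01", 0.04, "Bw4-80I", "B", "B*51:01", 0.08, "Bw4-80I",
    "B", "B*52:01", 0.05, "Bw4-80I", "B", "B*38:02", 0.04, "Bw4-80I",
    "B", "B*57:01", 0.03, "Bw4-80I", "B", "B*59:01", 0.02, "Bw4-80I"
  )
}

draw_pool <- function(n, fields, freqs) {
  sample(fields, n, replace = TRUE, prob = freqs)
}

# redraw entries of `calls` that match any excluded field of their sample;
# excl_mat has one column per exclusion (NA = sample not excluded). All
# exclusions are checked jointly on every pass so a redraw can never
# reintroduce a field excluded by another spec.
redraw_excluded <- function(calls, excl_mat, fields, freqs) {
  if (ncol(excl_mat) == 0L) return(calls)
  for (iter in 1:200) {
    bad <- rep(FALSE, length(calls))
    for (k in seq_len(ncol(excl_mat))) {
      bad <- bad | field_matches_any(calls, excl_mat[, k])
    }
    if (!any(bad)) return(calls)
    calls[bad] <- draw_pool(sum(bad), fields, freqs)
  }
  rlang::abort("allele pool too small to satisfy carrier exclusions")
}

# calls, excl_fields: equal-length character vectors; does call match its
# sample's excluded field at the excluded field's resolution?
field_matches_any <- function(calls, excl_fields) {
  out <- logical(length(calls))
  has <- !is.na(excl_fields) & nzchar(excl_fields)
  out[has] <- field_matches(calls[has], excl_fields[has])
  out
}

#' Simulate a synthetic KIR-HLA case-control cohort
#'
#' Generates a genotype table with the statistical structure of a KIR
#' immunogenetics case-control study: per-sample KIR gene content
#' consistent with a sampled AA/Bx genotype class, allele calls for the
#' seven A-haplotype genes, and HLA-A/-B/-C typings whose epitope content
#' realizes the requested ligand carrier frequencies. Feature
#' specifications inject case-control effects: each spec states a feature
#' (allele, allotype, ligand or interaction, see [feature_allele()] and
#' friends), its control carrier probability `p0`, and an odds ratio per
#' case cohort; case carrier probabilities follow [case_probability()].
#'
#' Within a feature's stratum, carrier status is sampled so the feature's
#' carrier frequency matches its target exactly in expectation. Allele,
#' ligand and interaction specs naming the same allele/ligand are sampled
#' jointly so that all their targets hold simultaneously (an interaction
#' probability slightly exceeding its ligand's is clamped; a gross
#' inconsistency is an error). Features are otherwise independent: no
#' linkage disequilibrium between KIR genes or between KIR and HLA is
#' modelled.
#'
#' @param n Named integer vector of cohort sizes; the first label is
#'   conventionally the control cohort (default the study-scale
#'   `c(control = 306, ALL = 318, AML = 336)`).
#' @param aa_fraction Probability that a sample has the KIR AA genotype;
#'   a scalar or a vector named by cohort.
#' @param feature_specs A feature tibble (as from [feature_allele()]
#'   etc.) with an added `p0` column and odds-ratio columns: either `or`
#'   (all case cohorts) or `or_<cohort>` (e.g. `or_AML`). `NULL` for a
#'   pure background cohort.
#' @param ligand_freqs Baseline carrier probabilities for the ligand
#'   flags `C1`, `C2` and `Bw4-80I` where no ligand spec applies.
#' @param allele_pool Background KIR allele pool
#'   ([default_allele_pool()]).
#' @param hla_pool HLA allele pool ([default_hla_pool()]).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A genotype tibble in the canonical column layout (see
#'   [read_genotype_table()]), ready for [classify_kir_genotype()] and
#'   [build_ligand_profile()].
#' @export
#' @examples
#' simulate_cohort(n = c(control = 10, AML = 10), seed = 1)
simulate_cohort <- function(n = c(control = 306, ALL = 318, AML = 336),
                            aa_fraction = 0.5,
                            feature_specs = NULL,
                            ligand_freqs = c("C1" = 0.98, "C2" = 0.31,
                                             "Bw4-80I" = 0.40),
                            allele_pool = default_allele_pool(),
                            hla_pool = default_hla_pool(),
                            seed = NULL) {
  if (is.null(names(n)) || any(!nzchar(names(n)))) {
    rlang::abort("cohort sizes must be a named vector, e.g. c(control = 306)")
  }
  if (!is.null(seed)) set.seed(seed)
  control <- names(n)[1]
  ns <- sum(n)
  cohort <- rep(names(n), n)
  ids <- sprintf("S%05d", seq_len(ns))

  p_aa <- if (length(aa_fraction) == 1L) rep(aa_fraction, ns) else {
    miss <- setdiff(names(n), names(aa_fraction))
    if (length(miss) > 0L) {
      rlang::abort(paste0("aa_fraction missing cohort(s): ",
                          paste(miss, collapse = ", ")))
    }
    unname(aa_fraction[cohort])
  }
  is_aa <- stats::runif(ns) < p_aa
  stratum_of <- ifelse(is_aa, "AA", "Bx")

  specs <- prepare_specs(feature_specs, names(n), control, allele_pool)

  # per-sample target probability for each spec (NA = background)
  spec_p <- lapply(specs, function(s) {
    p <- rep(NA_real_, ns)
    in_str <- if (s$stratum == "all") rep(TRUE, ns) else stratum_of == s$stratum
    p[in_str & cohort == control] <- s$p0
    for (k in setdiff(names(n), control)) {
      p[in_str & cohort == k] <- case_probability(s$p0, s$or[[k]])
    }
    p
  })

  ## ---- ligand flags --------------------------------------------------
  lig_target <- function(lig_name) {
    p <- rep(unname(ligand_freqs[[lig_name]]), ns)
    for (j in seq_along(specs)) {
      s <- specs[[j]]
      if (s$type == "ligand" && s$ligand == lig_name) {
        hit <- !is.na(spec_p[[j]])
        p[hit] <- spec_p[[j]][hit]
      }
    }
    p
  }
  p_c2 <- lig_target("C2")
  p_c1 <- lig_target("C1")
  p_80i <- lig_target("Bw4-80I")

  f_c2 <- stats::runif(ns) < p_c2
  # HLA-C is a C1/C2 partition: non-C2 carriers always carry C1; the C1
  # marginal is met through the conditional among C2 carriers
  p_c1_given_c2 <- pmin(1, pmax(0, (p_c1 - (1 - p_c2)) / p_c2))
  f_c1 <- !f_c2 | stats::runif(ns) < p_c1_given_c2
  f_80i <- stats::runif(ns) < p_80i
  lig_flag <- list("C1" = f_c1, "C2" = f_c2, "Bw4-80I" = f_80i)
  lig_p <- list("C1" = p_c1, "C2" = p_c2, "Bw4-80I" = p_80i)

  ## ---- interaction indicators ---------------------------------------
  # I = allele AND ligand; sampled as Bern(p_int / p_lig) among ligand
  # carriers so the interaction frequency is exactly p_int
  spec_I <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    s <- specs[[j]]
    if (s$type != "interaction") next
    L <- lig_flag[[s$ligand]]
    pL <- lig_p[[s$ligand]]
    p_int <- spec_p[[j]]
    if (any(p_int > pL * 1.25, na.rm = TRUE)) {
      rlang::abort(paste0("interaction spec '", s$feature,
                          "' exceeds its ligand's carrier probability"))
    }
    cond <- pmin(1, p_int / pL)
    I <- rep(FALSE, ns)
    act <- !is.na(p_int) & L
    I[act] <- stats::runif(sum(act)) < cond[act]
    spec_I[[j]] <- I
  }

  ## ---- per-gene allele calls ----------------------------------------
  genes7 <- kir_a_haplotype_genes()
  forced <- excl <- stats::setNames(vector("list", length(genes7)), genes7)
  for (g in genes7) {
    forced[[g]] <- list()
    excl[[g]] <- matrix(NA_character_, ns, 0)
  }
  add_excl <- function(gene, mask, field) {
    v <- rep(NA_character_, ns)
    v[mask] <- field
    excl[[gene]] <<- cbind(excl[[gene]], v)
  }

  for (j in seq_along(specs)) {
    s <- specs[[j]]
    if (s$type == "ligand") next
    eligible <- !is.na(spec_p[[j]])
    if (s$type == "interaction") {
      I <- spec_I[[j]]
      L <- lig_flag[[s$ligand]]
      # a matching allele spec (same allele) supplies the allele marginal
      mate <- match_allele_spec(specs, spec_p, s, ns)
      if (is.null(mate)) {
        carrier <- I
        # among ligand carriers, non-I samples must not carry the allele;
        # ligand-negative samples keep background carriage (interaction
        # is false for them regardless)
        add_excl(s$gene, eligible & L & !I, s$field)
        forced[[s$gene]] <- c(forced[[s$gene]],
                              list(list(mask = I, field = s$field)))
      } else {
        pA <- mate; pI <- spec_p[[j]]; pL <- lig_p[[s$ligand]]
        pA_noL <- pmin(1, pmax(0, (pA - pI) / (1 - pL)))
        carrier <- I
        noL <- eligible & !L
        carrier[noL] <- stats::runif(sum(noL)) < pA_noL[noL]
        add_excl(s$gene, eligible & L & !I, s$field)
        add_excl(s$gene, noL & !carrier, s$field)
        forced[[s$gene]] <- c(forced[[s$gene]],
                              list(list(mask = carrier, field = s$field)))
      }
    } else if (s$type == "allele") {
      if (has_interaction_mate(specs, s)) next  # handled jointly above
      carrier <- rep(FALSE, ns)
      carrier[eligible] <- stats::runif(sum(eligible)) < spec_p[[j]][eligible]
      add_excl(s$gene, eligible & !carrier, s$field)
      forced[[s$gene]] <- c(forced[[s$gene]],
                            list(list(mask = carrier, field = s$field)))
    } else if (s$type == "allotype") {
      carrier <- rep(FALSE, ns)
      carrier[eligible] <- stats::runif(sum(eligible)) < spec_p[[j]][eligible]
      grp_fields <- s$group_fields
      pick <- sample(grp_fields, ns, replace = TRUE)
      forced[[s$gene]] <- c(forced[[s$gene]],
                            list(list(mask = carrier, field = NA,
                                      field_by_sample = pick)))
      for (f in grp_fields) add_excl(s$gene, eligible & !carrier, f)
    }
  }

  ## ---- KIR gene presence --------------------------------------------
  pres <- matrix(1L, ns, length(kir_loci()),
                 dimnames = list(NULL, presence_col(kir_loci())))
  b_freq <- c("2DL2" = 0.45, "2DL5" = 0.55, "2DS1" = 0.40, "2DS2" = 0.45,
              "2DS3" = 0.25, "2DS5" = 0.30, "3DS1" = 0.40)
  bx <- !is_aa
  for (g in names(b_freq)) {
    pres[, presence_col(g)] <- as.integer(bx & stats::runif(ns) < b_freq[g])
  }
  none_b <- bx & rowSums(pres[, presence_col(names(b_freq)), drop = FALSE]) == 0
  if (any(none_b)) {
    pick <- sample(names(b_freq), sum(none_b), replace = TRUE, prob = b_freq)
    pres[cbind(which(none_b), match(presence_col(pick), colnames(pres)))] <- 1L
  }
  # Bx haplotype pairs can lack some A-haplotype genes
  drop_p <- c("2DL3" = 0.10, "3DL1" = 0.06, "2DS4" = 0.15)
  for (g in names(drop_p)) {
    pres[, presence_col(g)] <- ifelse(bx & stats::runif(ns) < drop_p[g],
                                      0L, pres[, presence_col(g)])
  }
  # samples forced to carry an allele are necessarily typed at the gene
  for (g in genes7) {
    for (f in forced[[g]]) pres[f$mask, presence_col(g)] <- 1L
  }

  ## ---- assemble allele calls ----------------------------------------
  allele_cols <- list()
  for (g in genes7) {
    pg <- allele_pool[allele_pool$gene == g, ]
    if (nrow(pg) == 0L) rlang::abort(paste0("allele pool lacks gene ", g))
    d1 <- draw_pool(ns, pg$field, pg$freq)
    d2 <- draw_pool(ns, pg$field, pg$freq)
    d1 <- redraw_excluded(d1, excl[[g]], pg$field, pg$freq)
    d2 <- redraw_excluded(d2, excl[[g]], pg$field, pg$freq)
    slot_used <- rep(0L, ns)
    extra <- rep("", ns)
    for (f in forced[[g]]) {
      fld <- if (is.null(f$field_by_sample)) rep(f$field, ns) else f$field_by_sample
      w <- which(f$mask)
      first <- w[slot_used[w] == 0L]
      second <- w[slot_used[w] == 1L]
      more <- w[slot_used[w] >= 2L]
      d1[first] <- fld[first]
      d2[second] <- fld[second]
      extra[more] <- paste0(extra[more], ";", fld[more])
      slot_used[w] <- slot_used[w] + 1L
    }
    calls <- paste0(d1, ";", d2, extra)
    calls[pres[, presence_col(g)] == 0L] <- ""
    allele_cols[[allele_col(g)]] <- calls
  }

  ## ---- HLA typings realizing the ligand flags -----------------------
  pool_of <- function(locus, keep = NULL, drop = NULL) {
    p <- hla_pool[hla_pool$locus == locus, ]
    if (!is.null(keep)) p <- p[p$epitope %in% keep, ]
    if (!is.null(drop)) p <- p[!p$epitope %in% drop, ]
    p
  }
  c1p <- pool_of("C", keep = "C1"); c2p <- pool_of("C", keep = "C2")
  hla_c1 <- ifelse(f_c2, draw_pool(ns, c2p$allele, c2p$freq),
                   draw_pool(ns, c1p$allele, c1p$freq))
  hla_c2 <- ifelse(f_c2 & f_c1, draw_pool(ns, c1p$allele, c1p$freq),
                   ifelse(f_c2, draw_pool(ns, c2p$allele, c2p$freq),
                          draw_pool(ns, c1p$allele, c1p$freq)))
  bi <- pool_of("B", keep = "Bw4-80I"); bn <- pool_of("B", drop = "Bw4-80I")
  bf <- pool_of("B")
  hla_b1 <- ifelse(f_80i, draw_pool(ns, bi$allele, bi$freq),
                   draw_pool(ns, bn$allele, bn$freq))
  hla_b2 <- ifelse(f_80i, draw_pool(ns, bf$allele, bf$freq),
                   draw_pool(ns, bn$allele, bn$freq))
  ap <- pool_of("A")
  hla_a1 <- draw_pool(ns, ap$allele, ap$freq)
  hla_a2 <- draw_pool(ns, ap$allele, ap$freq)

  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = ids, cohort = cohort),
    tibble::as_tibble(pres),
    tibble::as_tibble(allele_cols),
    tibble::tibble(hla_a1 = hla_a1, hla_a2 = hla_a2,
                   hla_b1 = hla_b1, hla_b2 = hla_b2,
                   hla_c1 = hla_c1, hla_c2 = hla_c2)
  )
  out
}

# normalize feature_specs into a list of per-spec records
prepare_specs <- function(feature_specs, cohorts, control, allele_pool) {
  if (is.null(feature_specs) || nrow(feature_specs) == 0L) return(list())
  fs <- feature_specs
  if (!"p0" %in% names(fs)) rlang::abort("feature_specs needs a p0 column")
  if (any(fs$p0 <= 0 | fs$p0 >= 1)) {
    rlang::abort("feature spec p0 must lie strictly inside (0, 1)")
  }
  case_labels <- setdiff(cohorts, control)
  lapply(seq_len(nrow(fs)), function(i) {
    row <- fs[i, ]
    or <- lapply(case_labels, function(k) {
      cn <- paste0("or_", k)
      v <- if (cn %in% names(fs)) row[[cn]]
           else if ("or" %in% names(fs)) row[["or"]]
           else 1
      if (is.na(v)) v <- 1
      if (v <= 0) rlang::abort("feature spec odds ratios must be positive")
      v
    })
    names(or) <- case_labels
    rec <- list(feature = row$feature, type = row$type,
                stratum = row$stratum, p0 = row$p0, or = or,
                ligand = row$ligand)
    if (!is.na(row$allele %||% NA)) {
      p <- parse_kir_allele(row$allele)
      rec$gene <- p$gene
      rec$field <- p$field
      if (!any(field_matches(
        allele_pool$field[allele_pool$gene == p$gene], p$field
      )) && !any(field_matches(
        p$field, allele_pool$field[allele_pool$gene == p$gene]
      ))) {
        rlang::abort(paste0("feature allele ", row$allele,
                            " has no counterpart in the allele pool"))
      }
    }
    if (rec$type == "allotype") {
      scheme <- kir_allotype_scheme(row$scheme)
      rec$gene <- attr(scheme, "gene")
      pool_fields <- allele_pool$field[allele_pool$gene == rec$gene]
      in_group <- assign_kir_allotype(
        paste0(rec$gene, "*", pool_fields), scheme
      ) == row$group
      if (!any(in_group)) {
        rlang::abort(paste0("allele pool has no ", row$group,
                            " allele for gene ", rec$gene))
      }
      rec$group_fields <- pool_fields[in_group]
    }
    if (rec$type == "interaction" &&
        !rec$ligand %in% c("C1", "C2", "Bw4-80I")) {
      rlang::abort("interaction specs support ligands C1, C2 and Bw4-80I")
    }
    rec
  })
}

# per-sample allele-carrier target of the allele spec matching an
# interaction spec's allele, or NULL
match_allele_spec <- function(specs, spec_p, s, ns) {
  for (j in seq_along(specs)) {
    o <- specs[[j]]
    if (o$type == "allele" && identical(o$gene, s$gene) &&
        identical(o$field, s$field) && identical(o$stratum, s$stratum)) {
      return(spec_p[[j]])
    }
  }
  NULL
}

has_interaction_mate <- function(specs, s) {
  for (o in specs) {
    if (o$type == "interaction" && identical(o$gene, s$gene) &&
        identical(o$field, s$field) && identical(o$stratum, s$stratum)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Study-scale simulation preset
#'
#' Cohort sizes, AA-genotype fractions, screen feature definitions and
#' generator feature specs reproducing the carrier-frequency structure of
#' the published leukemia study: control/ALL/AML cohorts of 306/318/336
#' with roughly half of each in the KIR AA stratum, the five AA-stratum
#' allele signals, the four AA-stratum receptor-ligand interactions, the
#' C2 ligand effect, and the Bx-stratum 2DL1*004+C2 interaction. Control
#' carrier probabilities are the printed control frequencies; odds ratios
#' are the printed effect sizes (zero-cell rows, whose control frequency
#' is 0, use a small nonzero p0 with odds ratios chosen to land near the
#' printed case frequencies).
#'
#' @return A list with elements `n`, `aa_fraction`, `features` (screen
#'   definitions) and `feature_specs` (features plus `p0`, `or_ALL`,
#'   `or_AML`).
#' @export
#' @examples
#' p <- study_preset()
#' cohort <- simulate_cohort(n = p$n, aa_fraction = p$aa_fraction,
#'                           feature_specs = p$feature_specs, seed = 1)
study_preset <- function() {
  features <- dplyr::bind_rows(
    feature_allele("2DL1*00201"),
    feature_allele("2DL1*069"),
    feature_allele("2DL3*00201"),
    feature_allele("3DL3*001"),
    feature_allele("3DL3*009"),
    feature_interaction("2DL1*00201", "C2"),
    feature_interaction("2DL1*00302", "C2"),
    feature_interaction("2DL3*00201", "C1"),
    feature_interaction("3DL1*00501", "Bw4-80I"),
    feature_ligand("C2"),
    feature_interaction("2DL1*004", "C2", stratum = "Bx")
  )
  feature_specs <- dplyr::bind_cols(
    features,
    tibble::tribble(
      ~p0, ~or_ALL, ~or_AML,
      48 / 167, 0.70, 0.59,   # 2DL1*00201
      0.003, 11, 13,          # 2DL1*069 (printed control count is 0)
      47 / 167, 0.69, 0.56,   # 2DL3*00201
      14 / 167, 0.43, 0.14,   # 3DL3*001
      49 / 167, 1.95, 2.14,   # 3DL3*009
      15 / 167, 0.27, 0.46,   # 2DL1*00201+C2
      51 / 167, 0.76, 0.50,   # 2DL1*00302+C2
      47 / 167, 0.69, 0.56,   # 2DL3*00201+C1
      24 / 167, 0.64, 0.35,   # 3DL1*00501+Bw4-80I
      52 / 167, 1.00, 0.48,   # C2 ligand
      0.010, 5.7, 3.5         # 2DL1*004+C2 (Bx; printed control count 0)
    )
  )
  list(
    n = c(control = 306, ALL = 318, AML = 336),
    aa_fraction = c(control = 167 / 306, ALL = 155 / 318, AML = 162 / 336),
    features = features,
    feature_specs = feature_specs
  )
}
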