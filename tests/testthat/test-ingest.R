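mis <- function(gene = "G1", tx = "ENST1", mane = "NM_1.1") {
  paste("missense_variant", gene, tx, mane, sep = "|")
}

test_that("VCF loading decomposes genotype calls per alt allele", {
  path <- write_test_vcf(c(
    vline("chr1", 1000, "A", "G", paste0("AF=0.001;CSQ=", mis()), "0/1:60:10:3,7"),
    vline("chr1", 2000, "C", "T,G",
      paste0("AF=0.001,0.002;CSQ=", mis()), "1/2:60:30:0,14,16"
    ),
    vline("chr1", 3000, "A", "T", paste0("CSQ=", mis()), "0/0:60:30:30,0"),
    vline("chr1", 4000, "G", "C", paste0("CSQ=", mis()), "1/1:80:40:0,40")
  ))
  obs <- load_cohort_vcf(path, "P1")
  # hom-ref line contributes nothing; the 1/2 line contributes two records
  expect_equal(nrow(obs), 4)
  expect_equal(obs$allele_balance[1], 0.7)
  two <- obs[obs$pos == 2000, ]
  expect_equal(two$alt, c("T", "G"))
  expect_equal(two$ref, c("C", "C"))
  expect_equal(two$zygosity, c("het", "het"))
  expect_equal(two$global_af, c(0.001, 0.002))
  expect_equal(two$ad_alt, c(14L, 16L))
  hom <- obs[obs$pos == 4000, ]
  expect_equal(hom$zygosity, "hom_alt")
  expect_equal(hom$allele_balance, 1)
  # absent AF INFO is missing, not zero
  expect_true(is.na(obs$global_af[obs$pos == 4000]))
})

test_that("empty VCFs, missing header fields, and malformed input are handled", {
  empty <- write_test_vcf(character())
  expect_equal(nrow(load_cohort_vcf(empty, "P1")), 0)
  # annotation sub-field missing from the header declaration
  bad <- write_test_vcf(
    vline("chr1", 1, "A", "G", paste0("CSQ=", mis()), "0/1:60:10:3,7"),
    csq_format = "Consequence|SYMBOL|Feature"
  )
  expect_error(load_cohort_vcf(bad, "P1"), "MANE_SELECT")
  garbage <- tempfile(fileext = ".vcf")
  writeLines(c("not", "a vcf"), garbage)
  expect_error(
    suppressWarnings(load_cohort_vcf(garbage, "P1")),
    basename(garbage)
  )
})

test_that("missing QC sub-fields are flagged absent, never zero", {
  path <- write_test_vcf(c(
    paste("chr1", 1000, ".", "A", "G", "50", "PASS", paste0("CSQ=", mis()),
      "GT:DP:AD", "0/1:10:3,7",
      sep = "\t"
    ),
    paste("chr1", 2000, ".", "A", "G", "50", "PASS", paste0("CSQ=", mis()),
      "GT:GQ", "0/1:60",
      sep = "\t"
    )
  ))
  obs <- load_cohort_vcf(path, "P1")
  expect_true(is.na(obs$gq[1]))
  expect_equal(obs$allele_balance[1], 0.7)
  expect_true(is.na(obs$dp[2]) && is.na(obs$ad_alt[2]))
  filtered <- apply_genotype_filters(obs)
  expect_equal(filtered$reason, c("missing_qc", "missing_qc"))
})

test_that("genotype filters apply the inclusive bounds with first-failure reasons", {
  obs <- tibble::tibble(
    gq = c(39L, 40L, 99L, 39L, 50L),
    dp = c(50L, 10L, 9L, 9L, 20L),
    allele_balance = c(0.5, 0.2, 0.5, 0.1, 0.19)
  )
  filtered <- apply_genotype_filters(obs)
  expect_equal(filtered$keep, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(
    filtered$reason,
    c("genotype_quality", NA, "depth", "genotype_quality", "allele_balance")
  )
  # thresholds are configurable
  relaxed <- apply_genotype_filters(obs, qc_thresholds(min_gq = 20, min_dp = 5, min_ab = 0))
  expect_true(all(relaxed$keep))
})

test_that("missense selection honors the transcript-selection mode", {
  syn_mane <- paste("synonymous_variant", "G1", "ENST1", "NM_1.1", sep = "|")
  mis_alt <- paste("missense_variant", "G1", "ENST9", "", sep = "|")
  stop_alt <- paste("stop_gained", "G1", "ENST9", "", sep = "|")
  path <- write_test_vcf(c(
    # MANE missense
    vline("chr1", 1000, "A", "G", paste0("CSQ=", mis()), "0/1:60:30:15,15"),
    # MANE synonymous, alternative transcript missense
    vline("chr1", 2000, "A", "G", paste0("CSQ=", syn_mane, ",", mis_alt), "0/1:60:30:15,15"),
    # no MANE-flagged annotation at all
    vline("chr1", 3000, "A", "G", paste0("CSQ=", mis_alt), "0/1:60:30:15,15"),
    # missense present but outranked by stop_gained on another transcript
    vline("chr1", 4000, "A", "G", paste0("CSQ=", mis(), ",", stop_alt), "0/1:60:30:15,15")
  ))
  obs <- load_cohort_vcf(path, "P1")
  fields <- attr(obs, "csq_fields")

  mane <- select_missense(obs, "mane_select", fields)
  expect_equal(mane$keep, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(mane$reason, c(NA, "not_missense", "no_mane_transcript", NA))
  expect_equal(mane$transcript_id[1], "ENST1")
  expect_true(mane$is_mane[1])

  severe <- select_missense(obs, "most_severe", fields)
  # alternative-transcript missense is recovered; the stop_gained site is not
  expect_equal(severe$keep, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(severe$transcript_id[2], "ENST9")
  expect_false(severe$is_mane[2])
  # MANE preferred as tie-break when it carries the missense itself
  expect_equal(severe$transcript_id[1], "ENST1")
})

test_that("popmax is the maximum over non-excluded populations", {
  expect_equal(compute_popmax(c(afr = 0.02, nfe = 0.001, fin = 0.20)), 0.02)
  expect_equal(compute_popmax(c(fin = 0.20)), 0)
  expect_equal(compute_popmax(c(nfe = 0.0)), 0.0)
  expect_equal(compute_popmax(numeric(0)), 0)
  expect_equal(compute_popmax(c(FIN = 0.2, NFE = 0.01)), 0.01) # case-insensitive
  expect_equal(compute_popmax(c(fin = 0.2), excluded_populations = character()), 0.2)
  expect_error(compute_popmax(c(nfe = 1.2)), "outside")
})

test_that("the AF filter bounds both global and popmax frequency inclusively", {
  obs <- tibble::tibble(
    global_af = c(0.005, 0.01, NA, 0.02),
    popmax_af = c(0.012, 0.01, NA, 0.005)
  )
  f <- apply_af_filter(obs, max_af = 0.01)
  expect_equal(f$keep, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(f$reason[1], "allele_frequency")
})

test_that("score joins respect transcript specificity", {
  obs <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L, 300L), ref = "A", alt = "G",
    transcript_id = "ENST1"
  )
  tbl <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L, 200L), ref = "A", alt = "G",
    transcript = c("ENST1", "ENST9", "ENST9"),
    BayesDel = c(0.5, 0.3, 0.3), MutPred2 = c(0.9, 0.8, 0.8),
    REVEL = c(0.95, 0.7, 0.7), VEST4 = c(NA, NA, NA)
  )
  joined <- join_scores(obs, tbl)
  # all four attach on the matching transcript (VEST4 missing in the table)
  expect_equal(joined$score_REVEL[1], 0.95)
  expect_true(is.na(joined$score_VEST4[1]))
  # transcript-specific score on a non-selected transcript does not attach
  expect_true(is.na(joined$score_REVEL[2]))
  # but the variant-level BayesDel does
  expect_equal(joined$score_BayesDel[2], 0.3)
  # variant absent from the table: everything missing
  expect_true(all(is.na(unlist(joined[3, c(
    "score_BayesDel", "score_MutPred2", "score_REVEL", "score_VEST4"
  )]))))
  # conflicting duplicate keys are a data error
  tbl_bad <- tbl
  tbl_bad$BayesDel[3] <- 0.7
  expect_error(join_scores(obs, tbl_bad), "conflicting BayesDel")
})

test_that("gene joins restrict to curated disease genes only in disease scope", {
  obs <- tibble::tibble(gene_symbol = c("G1", "G2", "G3"))
  genes <- tibble::tibble(
    symbol = c("G1", "G3"), validity = c("Moderate", "Limited"),
    moi = c("AR_only", "AD_only")
  )
  dis <- join_genes(obs, genes, "disease_genes")
  expect_equal(dis$keep, c(TRUE, FALSE, FALSE))
  expect_equal(dis$moi[1], "AR_only")
  gw <- join_genes(obs, genes, "genome_wide")
  expect_true(all(gw$keep))
  expect_equal(gw$validity[2], "other_or_absent")
})

test_that("the filter chain matches a brute-force single-pass oracle and keeps exact counts", {
  co <- generate_cohort(cohort_config(n_probands = 2), seed = 301)
  expect_lte(nrow(co$variants), 250)
  fx <- write_fixtures(co, tempfile("oracle"))
  scores <- read_score_table(fx$scores)
  genes <- read_gene_table(fx$genes)
  ing <- ingest_cohort(fx$vcf_paths, scores, genes,
    mode = "mane_select", max_af = 0.01, scope = "disease_genes"
  )

  # brute force: one pass over raw observations, all predicates at once
  brute_keep <- function(path, proband) {
    raw <- load_cohort_vcf(path, proband)
    ann <- parse_annotations(raw, attr(raw, "csq_fields"))
    kept <- list()
    for (i in seq_len(nrow(raw))) {
      a <- ann[ann$.row == i & ann$is_mane, ]
      if (nrow(a) == 0 || !grepl("missense_variant", a$consequence[1])) next
      if (is.na(raw$gq[i]) || is.na(raw$dp[i]) || is.na(raw$allele_balance[i])) next
      if (raw$gq[i] < 40 || raw$dp[i] < 10 || raw$allele_balance[i] < 0.2) next
      g <- ifelse(is.na(raw$global_af[i]), 0, raw$global_af[i])
      pm <- compute_popmax(raw$pop_af[[i]])
      if (g > 0.01 || pm > 0.01) next
      gr <- genes[genes$symbol == a$gene_symbol[1], ]
      if (nrow(gr) == 0 || !gr$validity %in% c("Definitive", "Strong", "Moderate")) next
      kept[[length(kept) + 1]] <- paste(proband, raw$chrom[i], raw$pos[i],
        raw$ref[i], raw$alt[i],
        sep = ":"
      )
    }
    unlist(kept)
  }
  want <- sort(unlist(lapply(
    names(fx$vcf_paths),
    function(p) brute_keep(fx$vcf_paths[[p]], p)
  )))
  got <- sort(with(
    ing$observations,
    paste(proband_id, chrom, pos, ref, alt, sep = ":")
  ))
  expect_identical(got, want)

  # bookkeeping identity: raw = kept + sum of drops, per proband
  kept_by <- table(factor(ing$observations$proband_id, levels = names(ing$n_raw)))
  drop_by <- tapply(ing$drops$n, factor(ing$drops$proband_id, levels = names(ing$n_raw)), sum)
  drop_by[is.na(drop_by)] <- 0
  expect_equal(as.integer(kept_by + drop_by), unname(ing$n_raw))
})

test_that("tightening the AF threshold only shrinks the kept set", {
  co <- generate_cohort(cohort_config(n_probands = 4), seed = 302)
  fx <- write_fixtures(co, tempfile("afmono"))
  scores <- read_score_table(fx$scores)
  genes <- read_gene_table(fx$genes)
  key <- function(ing) {
    with(ing$observations, paste(proband_id, chrom, pos, ref, alt, sep = ":"))
  }
  at1 <- key(ingest_cohort(fx$vcf_paths, scores, genes, max_af = 0.01))
  at5 <- key(ingest_cohort(fx$vcf_paths, scores, genes, max_af = 0.05))
  expect_true(all(at1 %in% at5))
  expect_gt(length(at5), length(at1)) # the engineered 1-5% variants appear
})
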