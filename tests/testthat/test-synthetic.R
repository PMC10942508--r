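test_that("generation is deterministic and fixtures are byte-identical given a seed", {
  cfg <- cohort_config(n_probands = 5)
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a$variants, b$variants)
  expect_false(identical(
    a$variants, generate_cohort(cfg, seed = 12)$variants
  ))

  da <- tempfile("fxa")
  db <- tempfile("fxb")
  fa <- write_fixtures(a, da)
  fb <- write_fixtures(b, db)
  for (pair in list(
    c(fa$vcf_paths[[1]], fb$vcf_paths[[1]]),
    c(fa$scores, fb$scores), c(fa$truth, fb$truth)
  )) {
    expect_identical(readLines(pair[1]), readLines(pair[2]))
  }
})

test_that("degenerate configurations behave as constructed", {
  # zero probands: empty cohort
  empty <- generate_cohort(cohort_config(n_probands = 0), seed = 1)
  expect_equal(nrow(empty$variants), 0)

  # no deleterious component and a benign component confined far below every
  # Supporting threshold: no pathogenic-direction truth categories at all
  cfg <- cohort_config(
    n_probands = 5, deleterious_fraction = 0,
    score_model = list(REVEL = list(del = c(8, 1.5), ben = c(1, 400))),
    missingness = c(REVEL = 0)
  )
  co <- generate_cohort(cfg, seed = 2)
  expect_false(any(startsWith(co$variants$expected_REVEL, "PP3")))
})

test_that("truth categories agree with the classifier and the truth table is complete", {
  co <- generate_cohort(cohort_config(n_probands = 3), seed = 21)
  tables <- load_threshold_tables()
  for (tool in default_tools()) {
    expect_identical(
      co$variants[[paste0("expected_", tool)]],
      classify_score(co$variants[[paste0("score_", tool)]], tables[[tool]])
    )
  }
  fx <- write_fixtures(co, tempfile("truth"))
  truth <- readr::read_tsv(fx$truth, show_col_types = FALSE)
  expect_equal(nrow(truth), nrow(co$variants))
})

test_that("fixtures round-trip: kept observations are exactly the non-engineered ones", {
  co <- generate_cohort(cohort_config(n_probands = 8), seed = 31)
  fx <- write_fixtures(co, tempfile("rt"))
  ing <- ingest_cohort(
    fx$vcf_paths, read_score_table(fx$scores), read_gene_table(fx$genes)
  )
  v <- co$variants
  expect_equal(nrow(ing$observations), sum(v$status == "analyzable"))

  # engineered failures fall out with exactly the engineered reasons
  want <- c(
    qc_missing = "missing_qc", qc_gq = "genotype_quality", qc_dp = "depth",
    qc_ab = "allele_balance", af_common = "allele_frequency",
    not_missense = "not_missense", alt_missense = "not_missense"
  )
  drops <- tapply(ing$drops$n, ing$drops$reason, sum)
  for (status in names(want)) {
    n_status <- sum(v$status == status)
    if (n_status > 0) {
      expect_gte(drops[[want[[status]]]], n_status)
    }
  }
  by_reason <- table(want[v$status[v$status != "analyzable"]])
  expect_equal(
    sort(as.integer(drops)), sort(as.integer(by_reason)),
    info = "drop-reason histogram matches the engineered statuses"
  )

  # kept scores survive the text round trip bit-for-bit
  keyed <- with(
    ing$observations, paste(proband_id, chrom, pos, ref, alt, sep = ":")
  )
  truth_keyed <- with(
    v[v$status == "analyzable", ],
    paste(proband_id, chrom, pos, ref, alt, sep = ":")
  )
  m <- match(truth_keyed, keyed)
  expect_false(anyNA(m))
  expect_equal(
    ing$observations$score_REVEL[m],
    v$score_REVEL[v$status == "analyzable"]
  )

  # under most_severe the alternative-transcript missense variants come back
  ing_ms <- ingest_cohort(
    fx$vcf_paths, read_score_table(fx$scores), read_gene_table(fx$genes),
    mode = "most_severe"
  )
  expect_equal(
    nrow(ing_ms$observations),
    sum(v$status %in% c("analyzable", "alt_missense"))
  )
})

test_that("analytic expected yield integrates the mixtures correctly", {
  # uniform mixture against the toy table: PP3_Supporting mass is the
  # interval length
  cfg <- cohort_config(
    score_model = list(toy = list(del = c(1, 1), ben = c(1, 1))),
    missingness = c(toy = 0.25), deleterious_fraction = 0.5
  )
  ey <- expected_yield(cfg, tables = list(toy = toy_table()))
  expect_equal(ey$mass[ey$category == "PP3_Supporting"], 0.2)
  expect_equal(ey$mass[ey$category == "PP3_Strong"], 0.1)
  expect_equal(ey$mass[ey$category == "BP4_Moderate"], 0.1)
  expect_equal(ey$mass[ey$category == "Indeterminate"], 0.2)
  # scored masses obey the law of total probability; fractions add the
  # missingness back in
  expect_equal(sum(ey$mass, na.rm = TRUE), 1)
  expect_equal(sum(ey$fraction), 1)
  expect_equal(ey$fraction[ey$category == "NoScore"], 0.25)

  # a point-mass-like component (concentrated at 0.4, inside the toy
  # indeterminate interval) concentrates its category
  spike <- cohort_config(
    score_model = list(toy = list(del = c(1, 1), ben = c(4000, 6000))),
    missingness = c(toy = 0), deleterious_fraction = 0
  )
  eys <- expected_yield(spike, tables = list(toy = toy_table()))
  expect_gt(eys$mass[eys$category == "Indeterminate"], 0.999)

  # default preset: PP3_Strong mass sits in the tuned 1.0-1.3% band per tool
  ey0 <- expected_yield()
  strong <- ey0$mass[ey0$category == "PP3_Strong"]
  expect_true(all(strong > 0.010 & strong < 0.013))
})

test_that("NoScore rates in the tabulated yield match the configured missingness", {
  cfg <- cohort_config(n_probands = 60)
  co <- generate_cohort(cfg, seed = 41)
  obs <- classify_cohort(as_observations(co))
  yt <- tabulate_yield(obs)
  totals <- yt$per_proband |>
    dplyr::group_by(tool) |>
    dplyr::summarise(
      noscore = sum(n[category == "NoScore"]), total = sum(n)
    )
  for (tl in names(cfg$missingness)) {
    p <- cfg$missingness[[tl]]
    row <- totals[totals$tool == tl, ]
    se <- sqrt(p * (1 - p) / row$total)
    expect_lte(abs(row$noscore / row$total - p), max(3 * se, 1e-12))
  }
})
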