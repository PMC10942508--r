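test_that("yield tabulation counts exactly and summarizes across probands", {
  obs <- make_obs(rep("Indeterminate", 3))
  yt <- tabulate_yield(obs)
  row <- yt$summary[yt$summary$category == "Indeterminate", ]
  expect_equal(row$median, 3)
  expect_equal(row$sd, 0)
  # counts over all categories sum to the analyzable total
  expect_equal(sum(yt$per_proband$n), 3)

  # median of an even cohort is the midpoint of the two central values
  obs2 <- make_obs(rep("Indeterminate", 35),
    proband = rep(c("P1", "P2"), c(17, 18))
  )
  obs2$pos <- seq_len(35)
  yt2 <- tabulate_yield(obs2)
  expect_equal(
    yt2$summary$median[yt2$summary$category == "Indeterminate"], 17.5
  )

  # empty cohort: empty tables, no crash
  empty <- make_obs(character(0))
  expect_equal(nrow(tabulate_yield(empty)$per_proband), 0)

  # duplicated (proband, variant) pairs are a data error
  dup <- make_obs(c("Indeterminate", "Indeterminate"))
  dup$pos <- c(1L, 1L)
  expect_error(tabulate_yield(dup), "duplicated")
})

test_that("unique-variant counts deduplicate across probands and are idempotent", {
  obs <- make_obs(rep("PP3_Strong", 5),
    proband = c("P1", "P2", "P3", "P1", "P1")
  )
  # one variant seen in three probands + two singletons in one gene
  obs$pos <- c(10L, 10L, 10L, 20L, 30L)
  obs$gene_symbol <- c("G1", "G1", "G1", "G2", "G2")
  uc <- unique_variant_count(obs)
  strong <- uc[uc$category == "PP3_Strong", ]
  expect_equal(strong$n_variants, 3)
  expect_equal(strong$n_genes, 2)
  # repeating the cohort changes nothing
  uc2 <- unique_variant_count(dplyr::bind_rows(obs, obs))
  expect_equal(uc2, uc)
})

test_that("bootstrap proportions are reproducible and honor degenerate inputs", {
  obs <- make_obs(rep(c("PP3_Strong", "Indeterminate"), c(50, 50)))
  obs$pos <- seq_len(100)
  pred <- function(d) d$call_toy == "PP3_Strong"
  a <- proportion_with_bootstrap(obs, pred, seed = 5)
  b <- proportion_with_bootstrap(obs, pred, seed = 5)
  expect_identical(a, b)
  expect_equal(a$proportion, 0.5)
  expect_true(a$ci_low <= 0.5 && 0.5 <= a$ci_high)

  all_match <- make_obs(rep("PP3_Strong", 10))
  expect_equal(
    unlist(proportion_with_bootstrap(all_match, pred, seed = 1)[
      c("proportion", "ci_low", "ci_high")
    ]),
    c(proportion = 1, ci_low = 1, ci_high = 1)
  )
  none <- make_obs(rep("Indeterminate", 10))
  expect_equal(proportion_with_bootstrap(none, pred, seed = 1)$proportion, 0)
  expect_equal(proportion_with_bootstrap(none, pred, seed = 1)$ci_high, 0)
  expect_error(proportion_with_bootstrap(obs, pred, iterations = 0, seed = 1), "iterations")

  # proband-level resampling is available
  pb <- proportion_with_bootstrap(obs, pred, seed = 5, unit = "proband")
  expect_equal(pb$unit, "proband")
  expect_equal(pb$proportion, 0.5)
})

test_that("bootstrap CIs tighten as the cohort grows", {
  width <- function(n, seed) {
    obs <- make_obs(withr::with_seed(
      seed,
      sample(c("PP3_Strong", "Indeterminate"), n, replace = TRUE, prob = c(0.3, 0.7))
    ))
    obs$pos <- seq_len(n)
    ci <- proportion_with_bootstrap(obs, function(d) d$call_toy == "PP3_Strong",
      seed = 99
    )
    ci$ci_high - ci$ci_low
  }
  expect_lt(width(10000, 17), width(100, 17))
})

test_that("the AR/AD comparison equals full binomial enumeration", {
  # spec-style constructions with an overridden null
  obs1 <- make_obs(rep("PP3_Strong", 10), moi = rep(c("AR_only", "AD_only"), each = 5))
  obs1$pos <- seq_len(10)
  r1 <- compare_moi(obs1, "toy", strengths = "PP3_Strong", null_p0 = 0.5)
  expect_equal(r1$p_value, 1.0)

  obs2 <- make_obs(rep("PP3_Strong", 2), moi = rep("AR_only", 2))
  obs2$pos <- 1:2
  r2 <- compare_moi(obs2, "toy", strengths = "PP3_Strong", null_p0 = 0.5)
  expect_equal(r2$p_value, 0.5)

  # Bonferroni is multiplication capped at 1
  expect_equal(r2$p_adjusted, min(1, 0.5 * 4))

  # random cases vs the enumeration oracle, n <= 50
  withr::with_seed(23, {
    for (i in 1:25) {
      n <- sample(1:50, 1)
      k <- sample(0:n, 1)
      p0 <- runif(1, 0.05, 0.95)
      moi <- rep(c("AR_only", "AD_only"), c(k, n - k))
      obs <- make_obs(rep("PP3_Strong", n), moi = moi)
      obs$pos <- seq_len(n)
      got <- compare_moi(obs, "toy", strengths = "PP3_Strong", null_p0 = p0)$p_value
      expect_equal(got, oracle_binom_two_tailed(k, n, p0), tolerance = 1e-9)
    }
  })

  # default null: the AR share of all analyzed observations in the strata
  obs3 <- make_obs(
    c(rep("PP3_Strong", 4), rep("BP4_Moderate", 6)),
    moi = c(rep("AR_only", 4), rep("AR_only", 2), rep("AD_only", 4))
  )
  obs3$pos <- seq_len(10)
  r3 <- compare_moi(obs3, "toy")
  expect_equal(r3$null_p0, 0.6)
  expect_error(
    compare_moi(make_obs("Indeterminate", moi = "AR_only"), "toy"),
    "no observations"
  )
})

test_that("fold change is the per-tool ratio with its arithmetic mean", {
  fc <- fold_change(c(A = 260, B = 350), c(A = 100, B = 100))
  expect_equal(unname(fc$ratios), c(2.6, 3.5))
  expect_equal(fc$mean, 3.05)
  expect_equal(fold_change(c(A = 5), c(A = 5))$ratios[["A"]], 1)
  expect_equal(fold_change(c(A = 7), c(A = 2))$mean, 3.5)
  expect_error(fold_change(c(A = 1), c(A = 0)), "positive")
})

test_that("external concordance reports coverage and grouped class proportions", {
  vars <- tibble::tibble(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "G"
  )
  ext <- tibble::tibble(
    chrom = "chr1", pos = c(1L, 2L, 9L), ref = "A", alt = "G",
    class = c("P/LP", "Conflicting", "B/LB")
  )
  cc <- concordance(vars, ext)
  expect_equal(cc$coverage, 0.5)
  expect_equal(cc$n_reported, 2)
  expect_equal(sum(cc$proportions), 1)
  expect_equal(cc$proportions[["VUS/Conflicting"]], 0.5)

  none <- concordance(vars, ext[0, ])
  expect_equal(none$coverage, 0)
  expect_length(none$proportions, 0)

  all_plp <- concordance(vars[1, ], ext[1, ])
  expect_equal(all_plp$proportions[["P/LP"]], 1)

  bad <- ext
  bad$class[1] <- "Pathogenic"
  expect_error(concordance(vars, bad), "Pathogenic")
})
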