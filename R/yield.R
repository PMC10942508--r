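#' Tabulate per-proband evidence-strength yield
#'
#' Counts variants per proband x tool x category (the shape of a
#' per-proband evidence-yield table) and summarizes across probands with
#' median, range, mean, and sample standard deviation. Counts over all
#' categories, including `NoScore`, sum exactly to each proband's analyzable
#' variant total. The median of an even-sized cohort is the midpoint of the
#' two central values.
#'
#' @param obs Classified observations (one `call_<tool>` column per tool),
#'   one row per (proband, variant).
#' @param tools Tools to tabulate (default: every `call_` column).
#' @return A list of class `yield_table`: `per_proband` (proband_id / tool /
#'   category / n, complete grid) and `summary` (tool / category / median /
#'   min / max / mean / sd).
#' @export
tabulate_yield <- function(obs, tools = NULL) {
  if (is.null(tools)) {
    tools <- sub("^call_", "", grep("^call_", names(obs), value = TRUE))
  }
  if (nrow(obs) > 0) {
    dup <- obs |>
      dplyr::count(
        .data$proband_id, .data$chrom, .data$pos, .data$ref, .data$alt
      ) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      stop(
        "duplicated (proband, variant) pair(s), e.g. ", dup$proband_id[1],
        " ", dup$chrom[1], ":", dup$pos[1], dup$ref[1], ">", dup$alt[1],
        call. = FALSE
      )
    }
  }
  if (nrow(obs) == 0) {
    return(structure(
      list(
        per_proband = tibble::tibble(
          proband_id = character(), tool = character(),
          category = .category_factor(character()), n = integer()
        ),
        summary = tibble::tibble(
          tool = character(), category = .category_factor(character()),
          median = double(), min = double(), max = double(),
          mean = double(), sd = double()
        )
      ),
      class = "yield_table"
    ))
  }
  long <- obs |>
    dplyr::select(dplyr::all_of(c("proband_id", paste0("call_", tools)))) |>
    tidyr::pivot_longer(-"proband_id",
      names_to = "tool", names_prefix = "call_", values_to = "category"
    ) |>
    dplyr::mutate(category = .category_factor(.data$category))
  per_proband <- long |>
    dplyr::count(.data$proband_id, .data$tool, .data$category,
      .drop = FALSE, name = "n"
    )
  summary <- per_proband |>
    dplyr::group_by(.data$tool, .data$category) |>
    dplyr::summarise(
      median = stats::median(.data$n),
      min = min(.data$n), max = max(.data$n),
      mean = mean(.data$n),
      # sample sd (n-1); a single-proband cohort reports 0, not NA
      sd = dplyr::coalesce(stats::sd(.data$n), 0),
      .groups = "drop"
    )
  structure(list(per_proband = per_proband, summary = summary),
    class = "yield_table"
  )
}

#' @export
print.yield_table <- function(x, ...) {
  n <- length(unique(x$per_proband$proband_id))
  cat("<yield_table> ", n, " probands\n", sep = "")
  print(format_yield_summary(x), n = Inf)
  invisible(x)
}

#' Format a yield table as `median (range)` / `mean (sd)` text columns
#'
#' The presentation shape of a per-proband evidence-yield table: one row per
#' category, one `median (range)` and one `mean (sd)` column per tool.
#'
#' @param yt A `yield_table`.
#' @return A tibble, categories as rows.
#' @export
format_yield_summary <- function(yt) {
  fmt <- yt$summary |>
    dplyr::mutate(
      med_range = sprintf(
        "%s (%g-%g)", sub("\\.0$", "", sprintf("%.1f", .data$median)),
        .data$min, .data$max
      ),
      mean_sd = sprintf("%.1f (%.1f)", .data$mean, .data$sd)
    ) |>
    dplyr::select(dplyr::all_of(c("tool", "category", "med_range", "mean_sd")))
  tidyr::pivot_wider(fmt,
    names_from = "tool",
    values_from = c("med_range", "mean_sd"), names_vary = "slowest"
  )
}

#' Unique-variant and gene counts per tool x category
#'
#' Deduplicates observations by variant key (chrom, pos, ref, alt) across
#' probands and reports, per tool and category, the number of unique variants
#' and of distinct genes they fall in. Idempotent under repetition of the
#' cohort.
#'
#' @param obs Classified observations.
#' @param tools Tools to report (default: every `call_` column).
#' @return Tibble tool / category / n_variants / n_genes.
#' @export
unique_variant_count <- function(obs, tools = NULL) {
  if (is.null(tools)) {
    tools <- sub("^call_", "", grep("^call_", names(obs), value = TRUE))
  }
  obs |>
    dplyr::select(dplyr::all_of(c(
      "chrom", "pos", "ref", "alt", "gene_symbol", paste0("call_", tools)
    ))) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("call_", tools)),
      names_to = "tool", names_prefix = "call_", values_to = "category"
    ) |>
    dplyr::distinct() |>
    dplyr::mutate(category = .category_factor(.data$category)) |>
    dplyr::group_by(.data$tool, .data$category, .drop = FALSE) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_genes = dplyr::n_distinct(.data$gene_symbol[!is.na(.data$gene_symbol)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_genes = ifelse(.data$n_variants == 0, 0L, .data$n_genes))
}

#' Proportion of observations matching a predicate, with bootstrap CI
#'
#' Point estimate is matching/total; the 95% CI is the 2.5th and 97.5th
#' percentile of the statistic over `iterations` bootstrap resamples drawn
#' with replacement. The resampling unit is the observation (proband-variant
#' pair) by default — the unit that yields the very tight CIs seen on
#' cohort-scale variant counts — or whole probands.
#'
#' @param obs Observation tibble.
#' @param predicate Function taking `obs` and returning a logical vector
#'   (one element per row), e.g.
#'   `function(d) d$call_REVEL == "PP3_Strong"`.
#' @param iterations Bootstrap replicates (default 1000).
#' @param seed Integer seed; mandatory, so every CI is reproducible.
#' @param unit `"observation"` or `"proband"`.
#' @return A list of class `proportion_ci`: `proportion`, `ci_low`,
#'   `ci_high`, `iterations`, `seed`, `n`, `unit`.
#' @export
proportion_with_bootstrap <- function(obs, predicate, iterations = 1000,
                                      seed, unit = c("observation", "proband")) {
  unit <- match.arg(unit)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (nrow(obs) == 0) stop("no observations", call. = FALSE)
  match_vec <- predicate(obs)
  stopifnot(is.logical(match_vec), length(match_vec) == nrow(obs))
  p_hat <- mean(match_vec)
  stat <- withr::with_seed(seed, {
    if (unit == "observation") {
      n <- length(match_vec)
      vapply(
        seq_len(iterations),
        function(i) mean(match_vec[sample.int(n, n, replace = TRUE)]), 0
      )
    } else {
      ids <- unique(obs$proband_id)
      by_id <- split(match_vec, factor(obs$proband_id, levels = ids))
      vapply(seq_len(iterations), function(i) {
        take <- sample.int(length(ids), length(ids), replace = TRUE)
        mean(unlist(by_id[take]))
      }, 0)
    }
  })
  ci <- unname(quantile(stat, c(0.025, 0.975), type = 7))
  structure(
    list(
      proportion = p_hat, ci_low = ci[1], ci_high = ci[2],
      iterations = iterations, seed = seed, n = nrow(obs), unit = unit
    ),
    class = "proportion_ci"
  )
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf(
    "%.4g%% [95%% CI %.4g-%.4g] (n=%d, %d bootstrap iterations by %s)\n",
    100 * x$proportion, 100 * x$ci_low, 100 * x$ci_high,
    x$n, x$iterations, x$unit
  ))
  invisible(x)
}

#' Compare evidence frequency between AR-only and AD-only genes
#'
#' Exact two-tailed binomial test of whether variants at the given evidence
#' strengths are over-represented in autosomal-recessive-only genes relative
#' to autosomal-dominant-only genes. Successes k are observations at the
#' given strengths in AR-only genes, among n such observations in AR-only or
#' AD-only genes; the null proportion is the AR share of *all* analyzed
#' observations (any category) in those two strata, unless `null_p0`
#' overrides it (e.g. with a gene-count null). The two-tailed p-value is the
#' minimum-likelihood exact definition (sum of probabilities of all outcomes
#' no more probable than the observed one), Bonferroni-adjusted over
#' `n_tests` tests.
#'
#' @param obs Classified observations with a `moi` column.
#' @param tool Tool whose calls are tested.
#' @param strengths Categories counted as successes (default
#'   `PP3_Moderate` + `PP3_Strong`; add `PP3_Supporting` for sensitivity).
#' @param n_tests Bonferroni multiplier (default 4, one test per tool).
#' @param null_p0 Optional null proportion overriding the observation-level
#'   AR share.
#' @return A one-row tibble of class `moi_comparison`.
#' @export
compare_moi <- function(obs, tool,
                        strengths = c("PP3_Moderate", "PP3_Strong"),
                        n_tests = 4, null_p0 = NULL) {
  calls <- obs[[paste0("call_", tool)]]
  in_stratum <- obs$moi %in% c("AD_only", "AR_only")
  hit <- in_stratum & calls %in% strengths
  k <- sum(hit & obs$moi == "AR_only")
  n <- sum(hit)
  if (n == 0) {
    stop("no observations at the requested strengths in AR/AD-only genes",
      call. = FALSE
    )
  }
  p0 <- null_p0 %||% (sum(in_stratum & obs$moi == "AR_only") / sum(in_stratum))
  p <- stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
  structure(
    tibble::tibble(
      tool = tool, ar_observed = k, ad_observed = n - k, n = n,
      null_p0 = p0, p_value = p,
      p_adjusted = min(1, p * n_tests), method = "exact two-tailed binomial",
      n_tests = n_tests
    ),
    class = c("moi_comparison", "tbl_df", "tbl", "data.frame")
  )
}

#' Fold change of genome-wide over disease-gene counts
#'
#' @param count_genomewide,count_disease Named numeric vectors of counts per
#'   tool (same names). Disease counts must be positive.
#' @return List with `ratios` (per tool) and `mean` (arithmetic mean across
#'   tools).
#' @export
#' @examples
#' fold_change(c(A = 260, B = 350), c(A = 100, B = 100))
fold_change <- function(count_genomewide, count_disease) {
  stopifnot(setequal(names(count_genomewide), names(count_disease)))
  count_disease <- count_disease[names(count_genomewide)]
  if (any(count_disease <= 0)) {
    stop("disease-gene counts must be positive", call. = FALSE)
  }
  ratios <- count_genomewide / count_disease
  list(ratios = ratios, mean = mean(ratios))
}

#' Concordance of unique variants with an external classification table
#'
#' For a set of unique variants (e.g. those reaching PP3_Strong under one
#' tool), reports what fraction carry an external classification (coverage)
#' and, among those reported, the proportions in the grouped classes P/LP,
#' VUS/Conflicting, and B/LB.
#'
#' @param variants Tibble of unique variants with key columns chrom / pos /
#'   ref / alt.
#' @param external Tibble mapping variant keys to a `class` column with
#'   controlled vocabulary `P/LP`, `VUS`, `Conflicting`, `B/LB`.
#' @return A list of class `concordance_table`: `n_total`, `n_reported`,
#'   `coverage`, and `proportions` (named, summing to 1 over reported
#'   classes when any are reported).
#' @export
concordance <- function(variants, external) {
  vocab <- c("P/LP", "VUS", "Conflicting", "B/LB")
  bad <- setdiff(unique(external$class), vocab)
  if (length(bad) > 0) {
    stop(
      "unknown classification label(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  key <- c("chrom", "pos", "ref", "alt")
  variants <- dplyr::distinct(variants[key])
  hit <- dplyr::inner_join(variants, external, by = key)
  grouped <- dplyr::recode(hit$class,
    "VUS" = "VUS/Conflicting",
    "Conflicting" = "VUS/Conflicting"
  )
  props <- if (nrow(hit) > 0) {
    table(factor(grouped, levels = c("P/LP", "VUS/Conflicting", "B/LB")))
  } else {
    NULL
  }
  structure(
    list(
      n_total = nrow(variants), n_reported = nrow(hit),
      coverage = if (nrow(variants) > 0) nrow(hit) / nrow(variants) else 0,
      proportions = if (is.null(props)) {
        setNames(numeric(0), character(0))
      } else {
        setNames(as.numeric(props) / nrow(hit), names(props))
      }
    ),
    class = "concordance_table"
  )
}

#' Read an external variant-classification table
#'
#' TSV with columns chrom / pos / ref / alt / class, the `class` vocabulary
#' being `P/LP`, `VUS`, `Conflicting`, `B/LB` (a ClinVar snapshot collapsed
#' to these groups is the canonical instance).
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_classification_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    class = readr::col_character()
  ))
}
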