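#' Configuration of the synthetic rare-disease cohort generator
#'
#' The generator emulates the statistical structure of a rare-disease genome
#' cohort as the pipeline sees it: per-proband rare-missense counts,
#' two-component (deleterious/benign) predictor-score mixtures per tool,
#' per-population allele frequencies, genotype QC fields with engineered
#' failure fractions, and per-tool score missingness. Defaults are the
#' disease-gene-scope study conditions: 300 probands; a disease-gene set of
#' 1,004 AD-only, 1,903 AR-only and 517 other genes; negative-binomial
#' analyzable-variant counts with mean 75 per proband; per-tool score
#' mixtures tuned so the PP3_Strong probability mass lies at 1.1-1.3%
#' (about one strong-evidence variant per proband); and NoScore rates
#' matching the per-tool missingness of a dbNSFP-style annotation.
#'
#' Score mixtures are two Beta components on the unit interval, mapped
#' linearly onto each tool's score range (taken from the threshold tables,
#' so generator and classifier cannot disagree about ranges). Scores for one
#' variant share the variant's deleterious/benign label across tools —
#' inducing positive inter-tool correlation — but are conditionally
#' independent given the label.
#'
#' @param n_probands Number of probands (default 300).
#' @param genes List: `n_ad`, `n_ar`, `n_other` disease-gene counts,
#'   `n_nondisease` genes outside the curated set (0 in disease scope), and
#'   `validity_probs` for sampling Definitive/Strong/Moderate validity.
#' @param variants_per_proband List `mu`, `size`: negative-binomial
#'   parameters of the analyzable-variant count per proband.
#' @param deleterious_fraction Probability a variant's scores are drawn from
#'   the deleterious mixture component.
#' @param score_model Per-tool list of `del` and `ben` Beta shape pairs (on
#'   the normalized unit interval).
#' @param missingness Named per-tool probability of a missing score.
#' @param af List: `p_novel` (fraction absent from the frequency resource),
#'   `max_af` (cap for rare variants), `n_common_per_proband` (Poisson mean
#'   of engineered variants with popmax in `common_range`, which pass a 5%
#'   filter but fail 1%), `common_range`.
#' @param qc_fail Named per-reason probabilities of engineered genotype-QC
#'   failures (fractions of the analyzable count): `missing_qc`,
#'   `genotype_quality`, `depth`, `allele_balance`.
#' @param nonmissense_fraction Fraction of extra variants whose MANE
#'   annotation is synonymous (dropped by missense selection).
#' @param alt_missense_fraction Fraction of extra variants missense only on
#'   a non-MANE transcript (dropped under `mane_select`, kept under
#'   `most_severe`).
#' @param hom_alt_fraction Fraction of homozygous-alt genotypes.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_probands = 300,
                          genes = list(
                            n_ad = 1004, n_ar = 1903, n_other = 517,
                            n_nondisease = 0,
                            validity_probs = c(
                              Definitive = 0.5, Strong = 0.25, Moderate = 0.25
                            )
                          ),
                          variants_per_proband = list(mu = 75, size = 15),
                          deleterious_fraction = 0.05,
                          score_model = list(
                            BayesDel = list(del = c(6, 2), ben = c(2, 9)),
                            MutPred2 = list(del = c(8, 1.5), ben = c(2, 9)),
                            REVEL = list(del = c(8, 1.5), ben = c(2, 9)),
                            VEST4 = list(del = c(6, 2), ben = c(2, 9))
                          ),
                          missingness = c(
                            BayesDel = 0.004, MutPred2 = 0,
                            REVEL = 0.14, VEST4 = 0.077
                          ),
                          af = list(
                            p_novel = 0.4, max_af = 0.01,
                            n_common_per_proband = 4,
                            common_range = c(0.012, 0.05)
                          ),
                          qc_fail = c(
                            missing_qc = 0.005, genotype_quality = 0.02,
                            depth = 0.01, allele_balance = 0.01
                          ),
                          nonmissense_fraction = 0.02,
                          alt_missense_fraction = 0.02,
                          hom_alt_fraction = 0.05) {
  stopifnot(
    n_probands >= 0,
    deleterious_fraction >= 0, deleterious_fraction <= 1,
    all(missingness >= 0), all(missingness <= 1),
    all(qc_fail >= 0), all(qc_fail <= 1)
  )
  structure(
    list(
      n_probands = n_probands, genes = genes,
      variants_per_proband = variants_per_proband,
      deleterious_fraction = deleterious_fraction,
      score_model = score_model, missingness = missingness,
      af = af, qc_fail = qc_fail,
      nonmissense_fraction = nonmissense_fraction,
      alt_missense_fraction = alt_missense_fraction,
      hom_alt_fraction = hom_alt_fraction
    ),
    class = "cohort_config"
  )
}

#' Genome-wide preset of the generator configuration
#'
#' Scales the disease-scope defaults to the genome-wide analysis: about
#' five-fold more genes (the curated set plus non-disease genes), mean 321
#' analyzable variants per proband, and a deleterious fraction five-fold
#' lower — mirroring a genome-wide pathogenicity prior about five-fold below
#' the disease-gene prior.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
genome_wide_config <- function(...) {
  cfg <- cohort_config(
    genes = list(
      n_ad = 1004, n_ar = 1903, n_other = 517, n_nondisease = 13696,
      validity_probs = c(Definitive = 0.5, Strong = 0.25, Moderate = 0.25)
    ),
    variants_per_proband = list(mu = 321, size = 15),
    deleterious_fraction = 0.01,
    ...
  )
  cfg
}

# build the synthetic gene table: disease genes carry validity and moi;
# non-disease genes exist only as symbols (absent from the curated table)
.make_genes <- function(gcfg, seed) {
  n_dis <- gcfg$n_ad + gcfg$n_ar + gcfg$n_other
  symbols <- sprintf("GENE%05d", seq_len(n_dis))
  moi <- rep(c("AD_only", "AR_only", "other"),
    times = c(gcfg$n_ad, gcfg$n_ar, gcfg$n_other)
  )
  validity <- withr::with_seed(seed, {
    sample(names(gcfg$validity_probs), n_dis,
      replace = TRUE, prob = gcfg$validity_probs
    )
  })
  table <- tibble::tibble(symbol = symbols, validity = validity, moi = moi)
  all_symbols <- c(symbols, if (gcfg$n_nondisease > 0) {
    sprintf("NDG%05d", seq_len(gcfg$n_nondisease))
  })
  list(table = table, pool = all_symbols)
}

.map_to_range <- function(x, range) range[1] + x * (range[2] - range[1])

#' Generate a synthetic cohort with ground truth
#'
#' Deterministic given `seed` (one master seed is split into per-stage
#' sub-seeds — gene table, per-proband counts, variant layout, QC fields,
#' frequencies, scores — drawn in a fixed order). Every generated variant is
#' private to its proband, so per-observation statistics behave as
#' independent draws from the configured mixtures. Each variant carries a
#' status recording how the ingest chain must treat it: `analyzable`,
#' engineered QC failures (`qc_missing`, `qc_gq`, `qc_dp`, `qc_ab`), an
#' allele frequency above the 1% threshold (`af_common`), a synonymous MANE
#' annotation (`not_missense`), or missense only on a non-MANE transcript
#' (`alt_missense`).
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer master seed (mandatory).
#' @param tables Threshold tables supplying score ranges and the truth
#'   categories (default: the packaged calibration).
#' @return A list of class `synthetic_cohort`: `variants` (one row per
#'   generated variant, with QC, frequency, score and truth columns),
#'   `gene_table`, `cfg`, `seed`.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed,
                            tables = load_threshold_tables()) {
  stopifnot(inherits(cfg, "cohort_config"), !missing(seed))
  tools <- names(cfg$score_model)
  stopifnot(all(tools %in% names(tables)))
  # warn on an infeasible deleterious component (entirely below Supporting)
  for (tool in tools) {
    if (cfg$deleterious_fraction > 0) {
      rng <- tables[[tool]]$score_range
      sup <- (tables[[tool]]$pathogenic$Supporting - rng[1]) / diff(rng)
      d <- cfg$score_model[[tool]]$del
      if (pbeta(sup, d[1], d[2], lower.tail = FALSE) < 1e-6) {
        warning(
          "deleterious component for ", tool,
          " lies entirely below the Supporting threshold"
        )
      }
    }
  }
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 6))
  genes <- .make_genes(cfg$genes, sub_seeds[1])

  probands <- sprintf("P%04d", seq_len(cfg$n_probands))
  counts <- withr::with_seed(sub_seeds[2], {
    n_core <- rnbinom(cfg$n_probands,
      mu = cfg$variants_per_proband$mu,
      size = cfg$variants_per_proband$size
    )
    data.frame(
      core = n_core,
      qc_missing = rbinom(cfg$n_probands, n_core, cfg$qc_fail[["missing_qc"]]),
      qc_gq = rbinom(cfg$n_probands, n_core, cfg$qc_fail[["genotype_quality"]]),
      qc_dp = rbinom(cfg$n_probands, n_core, cfg$qc_fail[["depth"]]),
      qc_ab = rbinom(cfg$n_probands, n_core, cfg$qc_fail[["allele_balance"]]),
      af_common = rpois(cfg$n_probands, cfg$af$n_common_per_proband),
      not_missense = rbinom(cfg$n_probands, n_core, cfg$nonmissense_fraction),
      alt_missense = rbinom(cfg$n_probands, n_core, cfg$alt_missense_fraction)
    )
  })
  status_levels <- c(
    "analyzable", "qc_missing", "qc_gq", "qc_dp", "qc_ab",
    "af_common", "not_missense", "alt_missense"
  )
  per_proband <- cbind(analyzable = counts$core, counts[, -1, drop = FALSE])
  n_each <- rowSums(per_proband)
  v <- tibble::tibble(
    proband_id = rep(probands, n_each),
    status = unlist(lapply(seq_len(cfg$n_probands), function(i) {
      rep(status_levels, times = as.integer(per_proband[i, status_levels]))
    }), use.names = FALSE)
  )
  n <- nrow(v)
  if (n == 0) {
    v <- tibble::tibble(
      proband_id = character(), status = character(),
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), gene_symbol = character()
    )
    return(structure(
      list(variants = v, gene_table = genes$table, cfg = cfg, seed = seed),
      class = "synthetic_cohort"
    ))
  }

  # variant layout: gene, unique locus, alleles, transcripts
  v <- withr::with_seed(sub_seeds[3], {
    v$gene_symbol <- sample(genes$pool, n, replace = TRUE)
    gene_idx <- match(v$gene_symbol, genes$pool)
    v$chrom <- paste0("chr", (gene_idx %% 22L) + 1L)
    base <- 1e5 * gene_idx
    off <- stats::ave(rep(1L, n), gene_idx, FUN = seq_along)
    v$pos <- as.integer(base + 2L * off)
    v$ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    v$alt <- vapply(
      v$ref,
      function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
      character(1)
    )
    v$mane_transcript <- sprintf("ENST%08d", gene_idx)
    v$mane_flag <- sprintf("NM_%06d.1", gene_idx)
    v$alt_transcript <- sprintf("ENST9%07d", gene_idx)
    v
  })

  # genotype QC fields by status
  v <- withr::with_seed(sub_seeds[4], {
    v$gq <- sample(40:99, n, replace = TRUE)
    v$dp <- 10L + rpois(n, 25)
    hom <- runif(n) < cfg$hom_alt_fraction
    ad <- rbinom(n, v$dp, 0.5)
    ad <- pmax(ad, ceiling(0.2 * v$dp))
    ad[hom] <- v$dp[hom]
    v$zygosity <- ifelse(hom, "hom_alt", "het")
    # engineered failures overwrite the clean draws
    i <- v$status == "qc_gq"
    v$gq[i] <- sample(0:39, sum(i), replace = TRUE)
    i <- v$status == "qc_dp"
    v$dp[i] <- sample(1:9, sum(i), replace = TRUE)
    ad[i] <- pmax(1L, rbinom(sum(i), v$dp[i], 0.5))
    v$zygosity[i] <- "het"
    i <- v$status == "qc_ab"
    ad[i] <- pmax(1L, floor(0.15 * v$dp[i]))
    v$zygosity[i] <- "het"
    v$ad_alt <- as.integer(pmin(ad, v$dp))
    v$gq_missing <- v$status == "qc_missing"
    v
  })
  v$allele_balance <- v$ad_alt / v$dp

  # allele frequencies (rounded to the precision the fixtures print)
  pops <- c("afr", "amr", "eas", "nfe", "sas")
  v <- withr::with_seed(sub_seeds[5], {
    novel <- runif(n) < cfg$af$p_novel & v$status != "af_common"
    g <- signif(cfg$af$max_af * runif(n)^3, 6)
    pop_mat <- matrix(0, n, length(pops) + 1,
      dimnames = list(NULL, c(pops, "fin"))
    )
    for (p in colnames(pop_mat)) {
      pop_mat[, p] <- signif(pmin(g * runif(n, 0.5, 1.5), cfg$af$max_af), 6)
    }
    # an occasional bottlenecked-population blow-up, excluded from popmax
    fin_hi <- runif(n) < 0.02
    pop_mat[fin_hi, "fin"] <- signif(runif(sum(fin_hi), 0.05, 0.2), 6)
    i <- v$status == "af_common"
    target <- signif(runif(sum(i), cfg$af$common_range[1], cfg$af$common_range[2]), 6)
    pop_mat[i, "nfe"] <- target
    g[i] <- signif(target * runif(sum(i), 0.5, 0.9), 6)
    g[novel] <- NA_real_
    pop_mat[novel, ] <- NA_real_
    v$global_af <- g
    for (p in colnames(pop_mat)) v[[paste0("af_", p)]] <- pop_mat[, p]
    v
  })
  pop_cols <- paste0("af_", c(pops, "fin"))
  v$popmax_af <- apply(v[paste0("af_", pops)], 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) 0 else max(x)
  })

  # predictor scores: shared deleterious/benign label, per-tool Beta draws
  v <- withr::with_seed(sub_seeds[6], {
    v$deleterious <- runif(n) < cfg$deleterious_fraction
    for (tool in tools) {
      sm <- cfg$score_model[[tool]]
      x <- numeric(n)
      x[v$deleterious] <- rbeta(sum(v$deleterious), sm$del[1], sm$del[2])
      x[!v$deleterious] <- rbeta(sum(!v$deleterious), sm$ben[1], sm$ben[2])
      s <- round(.map_to_range(x, tables[[tool]]$score_range), 6)
      s[runif(n) < cfg$missingness[[tool]]] <- NA_real_
      s[v$status == "not_missense"] <- NA_real_
      v[[paste0("score_", tool)]] <- s
    }
    v
  })
  for (tool in tools) {
    v[[paste0("expected_", tool)]] <-
      classify_score(v[[paste0("score_", tool)]], tables[[tool]])
  }
  structure(
    list(variants = v, gene_table = genes$table, cfg = cfg, seed = seed),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "<synthetic_cohort> ", x$cfg$n_probands, " probands, ",
    nrow(x$variants), " variants (seed ", x$seed, ")\n",
    sep = ""
  )
  if (nrow(x$variants) > 0) print(table(x$variants$status))
  invisible(x)
}

#' Materialize a synthetic cohort as pipeline observations
#'
#' Returns the observations the ingest chain would keep under a MANE-Select
#' run at the given AF threshold, in the pipeline's observation schema
#' (useful for exercising classification and statistics without the file
#' round trip; [write_fixtures()] + [ingest_cohort()] is the full-fidelity
#' path).
#'
#' @param cohort A `synthetic_cohort`.
#' @param max_af AF threshold of the emulated run (default 0.01).
#' @return Observation tibble with gene records and `score_<tool>` columns.
#' @export
as_observations <- function(cohort, max_af = 0.01) {
  v <- cohort$variants
  keep <- v$status == "analyzable" |
    (v$status == "af_common" & v$popmax_af <= max_af &
      dplyr::coalesce(v$global_af, 0) <= max_af)
  v <- v[keep, , drop = FALSE]
  obs <- tibble::tibble(
    proband_id = v$proband_id, chrom = v$chrom, pos = v$pos,
    ref = v$ref, alt = v$alt, zygosity = v$zygosity,
    gq = v$gq, dp = v$dp, ad_alt = v$ad_alt,
    allele_balance = v$allele_balance,
    global_af = v$global_af, popmax_af = v$popmax_af,
    gene_symbol = v$gene_symbol, transcript_id = v$mane_transcript,
    consequence = "missense_variant", is_mane = TRUE
  )
  obs <- dplyr::left_join(obs, cohort$gene_table, by = c(gene_symbol = "symbol"))
  obs$validity[is.na(obs$validity)] <- "other_or_absent"
  for (col in grep("^score_", names(v), value = TRUE)) obs[[col]] <- v[[col]]
  obs
}

#' Analytic per-category probability masses of the score mixtures
#'
#' For each tool, the exact probability mass of the configured two-component
#' Beta mixture falling in each evidence category's score interval — the
#' analytic expectation against which empirical yields are compared. `mass`
#' conditions on a score being present (sums to 1 over scored categories);
#' `fraction` multiplies in the configured missingness (`NoScore` carries
#' the missingness itself) and sums to 1 over all categories.
#'
#' @param cfg A [cohort_config()].
#' @param tables Threshold tables (default: packaged calibration).
#' @return Tibble tool / category / mass / fraction.
#' @export
expected_yield <- function(cfg = cohort_config(), tables = load_threshold_tables()) {
  tools <- names(cfg$score_model)
  f <- cfg$deleterious_fraction
  out <- lapply(tools, function(tool) {
    tt <- tables[[tool]]
    sm <- cfg$score_model[[tool]]
    rng <- tt$score_range
    cdf <- function(x) {
      z <- pmin(pmax((x - rng[1]) / diff(rng), 0), 1)
      f * pbeta(z, sm$del[1], sm$del[2]) +
        (1 - f) * pbeta(z, sm$ben[1], sm$ben[2])
    }
    mass <- setNames(numeric(length(evidence_categories())), evidence_categories())
    pbp <- unlist(tt$pathogenic[intersect(.strength_levels, names(tt$pathogenic))])
    for (i in seq_along(pbp)) {
      hi <- if (i < length(pbp)) pbp[i + 1] else Inf
      mass[paste0("PP3_", names(pbp)[i])] <- cdf(min(hi, rng[2] + 1)) - cdf(pbp[i])
    }
    bbp <- unlist(tt$benign[intersect(.strength_levels, names(tt$benign))])
    for (i in seq_along(bbp)) {
      lo <- if (i < length(bbp)) bbp[i + 1] else -Inf
      mass[paste0("BP4_", names(bbp)[i])] <- cdf(bbp[i]) - cdf(max(lo, rng[1] - 1))
    }
    mass["Indeterminate"] <- cdf(min(pbp)) - cdf(max(bbp))
    mass["NoScore"] <- NA_real_
    miss <- cfg$missingness[[tool]]
    frac <- (1 - miss) * mass
    frac["NoScore"] <- miss
    tibble::tibble(
      tool = tool, category = .category_factor(names(mass)),
      mass = unname(mass), fraction = unname(frac)
    )
  })
  dplyr::bind_rows(out)
}

# ---- fixture emission ------------------------------------------------------

.fmt_af <- function(x) sprintf("%.8g", x)

.vcf_header <- function(proband_id, pops) {
  c(
    "##fileformat=VCFv4.2",
    "##source=evidenceyield synthetic cohort generator",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Global allele frequency\">",
    sprintf(
      "##INFO=<ID=AF_%s,Number=A,Type=Float,Description=\"%s allele frequency\">",
      pops, pops
    ),
    paste0(
      "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
      "annotations from Ensembl VEP. Format: Consequence|SYMBOL|Feature|MANE_SELECT\">"
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", proband_id
    ), collapse = "\t")
  )
}

.csq_string <- function(v) {
  mane_ann <- function(consequence) {
    paste(consequence, v$gene_symbol, v$mane_transcript, v$mane_flag, sep = "|")
  }
  ifelse(
    v$status == "not_missense",
    mane_ann("synonymous_variant"),
    ifelse(
      v$status == "alt_missense",
      paste(
        mane_ann("synonymous_variant"),
        paste("missense_variant", v$gene_symbol, v$alt_transcript, "", sep = "|"),
        sep = ","
      ),
      mane_ann("missense_variant")
    )
  )
}

#' Write a synthetic cohort as pipeline input fixtures
#'
#' Emits one single-sample VCF per proband (GT/GQ/DP/AD genotype fields,
#' AF + per-population AF INFO keys, VEP-style CSQ annotations with the
#' sub-field order declared in the header), a predictor score TSV, the
#' curated gene-list TSV, and a ground-truth TSV (one row per generated
#' variant). The fixture set round-trips through [ingest_cohort()] with no
#' drops other than the engineered ones.
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `vcf_paths` (named by proband), `scores`,
#'   `genes`, `truth` paths.
#' @export
write_fixtures <- function(cohort, out_dir) {
  v <- cohort$variants
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  pop_cols <- grep("^af_", names(v), value = TRUE)
  pops <- toupper(sub("^af_", "", pop_cols))

  csq_part <- paste0("CSQ=", .csq_string(v))
  af_part <- do.call(paste, c(
    list(paste0("AF=", .fmt_af(v$global_af))),
    lapply(pop_cols, function(p) {
      paste0("AF_", toupper(sub("^af_", "", p)), "=", .fmt_af(v[[p]]))
    }),
    sep = ";"
  ))
  info <- ifelse(is.na(v$global_af), csq_part, paste(af_part, csq_part, sep = ";"))
  gq_str <- ifelse(v$gq_missing, ".", as.character(v$gq))
  sample_str <- paste0(
    ifelse(v$zygosity == "hom_alt", "1/1", "0/1"), ":",
    gq_str, ":", v$dp, ":", v$dp - v$ad_alt, ",", v$ad_alt
  )
  lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, "50", "PASS", info,
    "GT:GQ:DP:AD", sample_str,
    sep = "\t"
  )

  probands <- unique(v$proband_id)
  vcf_paths <- setNames(
    file.path(out_dir, "vcf", paste0(probands, ".vcf")), probands
  )
  chrom_n <- as.integer(sub("^chr", "", v$chrom))
  for (p in probands) {
    i <- which(v$proband_id == p)
    i <- i[order(chrom_n[i], v$pos[i])]
    writeLines(c(.vcf_header(p, pops), lines[i]), vcf_paths[p])
  }

  score_cols <- grep("^score_", names(v), value = TRUE)
  scored <- v[v$status != "not_missense", , drop = FALSE]
  scores <- tibble::tibble(
    chrom = scored$chrom, pos = scored$pos, ref = scored$ref,
    alt = scored$alt,
    transcript = ifelse(scored$status == "alt_missense",
      scored$alt_transcript, scored$mane_transcript
    )
  )
  for (col in score_cols) {
    scores[[sub("^score_", "", col)]] <- ifelse(
      is.na(scored[[col]]), ".", sprintf("%.6f", scored[[col]])
    )
  }
  scores_path <- file.path(out_dir, "scores.tsv")
  readr::write_tsv(scores, scores_path)

  genes_path <- file.path(out_dir, "genes.tsv")
  readr::write_tsv(cohort$gene_table, genes_path)

  truth_path <- file.path(out_dir, "truth.tsv")
  truth <- v[, c(
    "proband_id", "chrom", "pos", "ref", "alt", "gene_symbol", "status",
    "deleterious", "popmax_af",
    grep("^expected_", names(v), value = TRUE)
  )]
  readr::write_tsv(truth, truth_path)

  invisible(list(
    vcf_paths = vcf_paths, scores = scores_path,
    genes = genes_path, truth = truth_path
  ))
}
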