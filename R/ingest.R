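#' Annotation and frequency field configuration for VCF ingest
#'
#' Describes where consequence annotations and allele frequencies live in the
#' VCF INFO column. The annotation sub-field order is taken from the VCF
#' header (the `Format:` clause of the INFO definition), as VEP writes it;
#' this spec only names the sub-fields the pipeline needs.
#'
#' @param info_key INFO key holding the per-transcript annotation string
#'   (default `CSQ`).
#' @param consequence,symbol,transcript,mane Sub-field names within the
#'   annotation string for the consequence term, gene symbol, transcript ID,
#'   and MANE Select flag (non-empty value = the transcript is MANE Select).
#' @param af_key INFO key for the global allele frequency (per alt allele).
#' @param pop_af_prefix Prefix of per-population AF INFO keys; keys
#'   `<prefix><pop>` are collected into the per-population frequency map.
#' @return A list of class `annotation_spec`.
#' @export
annotation_spec <- function(info_key = "CSQ",
                            consequence = "Consequence",
                            symbol = "SYMBOL",
                            transcript = "Feature",
                            mane = "MANE_SELECT",
                            af_key = "AF",
                            pop_af_prefix = "AF_") {
  structure(
    list(
      info_key = info_key, consequence = consequence, symbol = symbol,
      transcript = transcript, mane = mane, af_key = af_key,
      pop_af_prefix = pop_af_prefix
    ),
    class = "annotation_spec"
  )
}

#' Genotype-QC retention thresholds
#'
#' Defaults are the study thresholds: genotype quality >= 40, depth >= 10,
#' allele balance >= 0.2 (all bounds inclusive as printed; allele balance is
#' alt reads / depth and only its lower bound applies, for both heterozygous
#' and homozygous-alt genotypes).
#'
#' @param min_gq,min_dp,min_ab The three lower bounds.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_gq = 40, min_dp = 10, min_ab = 0.2) {
  structure(list(min_gq = min_gq, min_dp = min_dp, min_ab = min_ab),
    class = "qc_thresholds"
  )
}

#' Default excluded (bottlenecked) populations for popmax
#'
#' Population codes excluded from the population-max allele frequency, the
#' convention of gnomAD-style "popmax over non-bottlenecked populations":
#' Ashkenazi Jewish, Finnish, Amish, Middle Eastern, and Other.
#'
#' @return Character vector of lower-case population codes.
#' @export
bottlenecked_populations <- function() {
  c("asj", "fin", "ami", "mid", "oth")
}

# ---- VCF loading -----------------------------------------------------------

# Extract the declared sub-field order of the annotation INFO key from vcfR
# meta lines; errors if the key or any required sub-field is absent.
.csq_field_order <- function(vcf, spec) {
  meta <- vcf@meta
  pat <- paste0("^##INFO=<ID=", spec$info_key, ",")
  line <- meta[grepl(pat, meta)]
  if (length(line) != 1) {
    stop(
      "annotation INFO key '", spec$info_key,
      "' not declared (or declared twice) in VCF header",
      call. = FALSE
    )
  }
  m <- regmatches(line, regexpr("Format: ?[^\">]+", line))
  if (length(m) == 0) {
    stop(
      "INFO '", spec$info_key, "' header line carries no 'Format:' clause",
      call. = FALSE
    )
  }
  fields <- strsplit(sub("^Format: ?", "", m), "|", fixed = TRUE)[[1]]
  needed <- c(spec$consequence, spec$symbol, spec$transcript, spec$mane)
  missing <- setdiff(needed, fields)
  if (length(missing) > 0) {
    stop(
      "annotation sub-field(s) ", paste(missing, collapse = ", "),
      " absent from the '", spec$info_key, "' header declaration",
      call. = FALSE
    )
  }
  fields
}

# Parse one INFO string into a named list of values (flags become "TRUE").
.parse_info <- function(info) {
  if (is.na(info) || info == ".") {
    return(list())
  }
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  eq <- regexpr("=", parts, fixed = TRUE)
  keys <- ifelse(eq > 0, substr(parts, 1, eq - 1), parts)
  vals <- ifelse(eq > 0, substr(parts, eq + 1, nchar(parts)), "TRUE")
  setNames(as.list(vals), keys)
}

.int_or_na <- function(x) suppressWarnings(as.integer(x))
.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Load one proband's VCF into raw variant observations
#'
#' Reads a single-sample VCF and emits one raw observation per called
#' non-reference genotype per alt allele: multi-allelic sites are decomposed
#' into per-alt records sharing chrom/pos/ref. Genotype QC sub-fields (GQ,
#' DP, AD) that are absent are flagged as missing (`NA`), never coerced to
#' zero. Allele balance is computed as alt-supporting reads / depth. The
#' per-transcript annotation string is carried along verbatim (see
#' [parse_annotations()]); global and per-population allele frequencies are
#' parsed from INFO, with variants absent from the frequency resource
#' carrying `NA` (treated as novel, AF 0, by the frequency filter).
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param proband_id Proband identifier; defaults to the VCF sample name.
#' @param spec An [annotation_spec()].
#' @return A tibble of raw observations, one row per (variant, alt allele)
#'   with a called non-reference genotype.
#' @export
load_cohort_vcf <- function(path, proband_id = NULL, spec = annotation_spec()) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      stop("failed to parse VCF '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  if (ncol(vcf@gt) != 2) {
    stop(
      "expected a single-sample VCF at '", path, "', found ",
      ncol(vcf@gt) - 1, " sample columns",
      call. = FALSE
    )
  }
  if (is.null(proband_id)) proband_id <- colnames(vcf@gt)[2]
  field_order <- .csq_field_order(vcf, spec)
  empty <- tibble::tibble(
    proband_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(),
    zygosity = character(), gq = integer(), dp = integer(),
    ad_alt = integer(), allele_balance = double(),
    global_af = double(), pop_af = list(), csq = character()
  )
  if (nrow(vcf@fix) == 0) {
    return(structure(empty, csq_fields = field_order))
  }
  fix <- vcf@fix
  fmt <- strsplit(vcf@gt[, 1], ":", fixed = TRUE)
  smp <- strsplit(vcf@gt[, 2], ":", fixed = TRUE)
  field <- function(j, key) {
    i <- match(key, fmt[[j]])
    if (is.na(i) || i > length(smp[[j]])) NA_character_ else smp[[j]][i]
  }
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  info <- lapply(fix[, "INFO"], .parse_info)

  rows <- vector("list", nrow(fix))
  for (j in seq_len(nrow(fix))) {
    gt <- field(j, "GT")
    if (is.na(gt) || gt %in% c(".", "./.", ".|.")) next
    alleles <- strsplit(gt, "[/|]")[[1]]
    called <- unique(alleles[alleles != "0" & alleles != "."])
    if (length(called) == 0) next
    ai <- as.integer(called)
    if (anyNA(ai) || any(ai > length(alts[[j]]))) {
      stop("malformed genotype '", gt, "' at ", fix[j, "CHROM"], ":",
        fix[j, "POS"], " in '", path, "'",
        call. = FALSE
      )
    }
    gq <- .int_or_na(field(j, "GQ"))
    dp <- .int_or_na(field(j, "DP"))
    ad <- strsplit(field(j, "AD"), ",", fixed = TRUE)[[1]]
    ii <- info[[j]]
    af_all <- .num_or_na(strsplit(ii[[spec$af_key]] %||% NA_character_,
      ",",
      fixed = TRUE
    )[[1]])
    pop_keys <- names(ii)[startsWith(names(ii), spec$pop_af_prefix)]
    pop_vals <- lapply(pop_keys, function(k) {
      .num_or_na(strsplit(ii[[k]], ",", fixed = TRUE)[[1]])
    })
    pops <- tolower(substring(pop_keys, nchar(spec$pop_af_prefix) + 1))

    rows[[j]] <- lapply(ai, function(i) {
      ad_alt <- if (length(ad) >= i + 1) .int_or_na(ad[i + 1]) else NA_integer_
      ab <- if (!is.na(ad_alt) && !is.na(dp) && dp > 0) ad_alt / dp else NA_real_
      pop_af <- setNames(
        vapply(pop_vals, function(v) if (length(v) >= i) v[i] else NA_real_, 0),
        pops
      )
      list(
        proband_id = proband_id,
        chrom = fix[j, "CHROM"], pos = as.integer(fix[j, "POS"]),
        ref = fix[j, "REF"], alt = alts[[j]][i],
        zygosity = if (all(alleles[alleles != "."] == called[match(i, ai)])) {
          "hom_alt"
        } else {
          "het"
        },
        gq = gq, dp = dp, ad_alt = ad_alt, allele_balance = ab,
        global_af = if (length(af_all) >= i) af_all[i] else NA_real_,
        pop_af = pop_af,
        csq = ii[[spec$info_key]] %||% NA_character_
      )
    })
  }
  rows <- unlist(rows, recursive = FALSE)
  if (length(rows) == 0) {
    return(structure(empty, csq_fields = field_order))
  }
  col_chr <- function(k) vapply(rows, function(r) r[[k]], character(1))
  col_int <- function(k) vapply(rows, function(r) as.integer(r[[k]]), integer(1))
  col_dbl <- function(k) vapply(rows, function(r) as.double(r[[k]]), double(1))
  out <- tibble::tibble(
    proband_id = col_chr("proband_id"),
    chrom = col_chr("chrom"), pos = col_int("pos"),
    ref = col_chr("ref"), alt = col_chr("alt"),
    zygosity = col_chr("zygosity"),
    gq = col_int("gq"), dp = col_int("dp"), ad_alt = col_int("ad_alt"),
    allele_balance = col_dbl("allele_balance"),
    global_af = col_dbl("global_af"),
    pop_af = lapply(rows, function(r) r[["pop_af"]]),
    csq = col_chr("csq")
  )
  structure(out, csq_fields = field_order)
}

#' Expand annotation strings into per-transcript consequence records
#'
#' Splits each observation's VEP-style annotation string (one entry per
#' transcript, sub-fields in the order declared in the source VCF header)
#' into a long table of consequence annotations.
#'
#' @param obs Raw observations from [load_cohort_vcf()], with a `.row` ID
#'   column (added if absent).
#' @param field_order Character vector: the annotation sub-field order.
#' @param spec An [annotation_spec()].
#' @return A tibble with columns `.row`, `consequence`, `gene_symbol`,
#'   `transcript_id`, `is_mane`.
#' @export
parse_annotations <- function(obs, field_order, spec = annotation_spec()) {
  if (!".row" %in% names(obs)) obs$.row <- seq_len(nrow(obs))
  idx <- match(
    c(spec$consequence, spec$symbol, spec$transcript, spec$mane),
    field_order
  )
  entries <- strsplit(obs$csq, ",", fixed = TRUE)
  n <- lengths(entries)
  n[is.na(obs$csq)] <- 0L
  flat <- strsplit(unlist(entries[n > 0]), "|", fixed = TRUE)
  pick <- function(k) {
    vapply(flat, function(f) if (length(f) >= k) f[k] else "", character(1))
  }
  tibble::tibble(
    .row = rep(obs$.row[n > 0], n[n > 0]),
    consequence = pick(idx[1]),
    gene_symbol = pick(idx[2]),
    transcript_id = pick(idx[3]),
    is_mane = nzchar(pick(idx[4]))
  )
}

# ---- Filters ---------------------------------------------------------------

#' Apply genotype-quality retention filters
#'
#' Keeps observations meeting all three inclusive bounds (GQ, depth, allele
#' balance). Observations whose QC sub-fields could not be parsed are dropped
#' with reason `missing_qc`: a record that cannot demonstrate the bounds is
#' not retained. Otherwise the drop reason names the first failing criterion,
#' in the order genotype_quality, depth, allele_balance.
#'
#' @param obs Observation tibble with `gq`, `dp`, `allele_balance`.
#' @param qc A [qc_thresholds()].
#' @return `obs` with logical `keep` and character `reason` columns.
#' @export
apply_genotype_filters <- function(obs, qc = qc_thresholds()) {
  missing <- is.na(obs$gq) | is.na(obs$dp) | is.na(obs$allele_balance)
  reason <- rep(NA_character_, nrow(obs))
  reason[!missing & obs$allele_balance < qc$min_ab] <- "allele_balance"
  reason[!missing & obs$dp < qc$min_dp] <- "depth"
  reason[!missing & obs$gq < qc$min_gq] <- "genotype_quality"
  reason[missing] <- "missing_qc"
  obs$keep <- is.na(reason)
  obs$reason <- reason
  obs
}

#' Select missense observations under a transcript-selection mode
#'
#' `mane_select` keeps an observation iff the annotation on the MANE Select
#' transcript calls `missense_variant`; that annotation becomes the selected
#' annotation. `most_severe` keeps it iff missense is the most severe
#' consequence across all transcripts under the packaged severity ordering,
#' selecting the highest-priority missense-bearing transcript (MANE Select
#' preferred as tie-break). Drop reasons: `no_mane_transcript`,
#' `not_missense`.
#'
#' @param obs Raw observations (with `csq` annotation strings).
#' @param mode `"mane_select"` or `"most_severe"`.
#' @param field_order Annotation sub-field order from the VCF header.
#' @param spec An [annotation_spec()].
#' @param severity Severity ranking table, see [consequence_severity()].
#' @return `obs` with `keep`/`reason` plus selected-annotation columns
#'   `gene_symbol`, `transcript_id`, `consequence`, `is_mane`.
#' @export
select_missense <- function(obs, mode = c("mane_select", "most_severe"),
                            field_order, spec = annotation_spec(),
                            severity = consequence_severity()) {
  mode <- match.arg(mode)
  obs$.row <- seq_len(nrow(obs))
  sel <- tibble::tibble(
    .row = integer(), gene_symbol = character(),
    transcript_id = character(), consequence = character(),
    is_mane = logical()
  )
  reason <- rep("no_annotation", nrow(obs))
  if (nrow(obs) > 0) {
    ann <- parse_annotations(obs, field_order, spec)
    if (nrow(ann) > 0) {
      has_missense <- vapply(
        strsplit(ann$consequence, "&", fixed = TRUE),
        function(x) "missense_variant" %in% x, logical(1)
      )
      if (mode == "mane_select") {
        mane <- ann[ann$is_mane, , drop = FALSE]
        mane_missense <- mane[has_missense[ann$is_mane], , drop = FALSE]
        sel <- mane_missense[!duplicated(mane_missense$.row), ]
        reason[obs$.row %in% ann$.row] <- "no_mane_transcript"
        reason[obs$.row %in% mane$.row] <- "not_missense"
      } else {
        ann$rank <- .severity_rank(ann$consequence, severity)
        best <- tapply(ann$rank, ann$.row, min)
        missense_rank <- severity$rank[severity$consequence == "missense_variant"]
        ok_rows <- as.integer(names(best))[best == missense_rank]
        cand <- ann[ann$.row %in% ok_rows & has_missense &
          ann$rank == missense_rank, , drop = FALSE]
        cand <- cand[order(cand$.row, !cand$is_mane), ]
        sel <- cand[!duplicated(cand$.row), ]
        sel$rank <- NULL
        reason[obs$.row %in% ann$.row] <- "not_missense"
      }
    }
  }
  sel$consequence <- "missense_variant"
  obs <- dplyr::left_join(obs, sel, by = ".row")
  obs$keep <- obs$.row %in% sel$.row
  obs$reason <- ifelse(obs$keep, NA_character_, reason)
  obs$.row <- NULL
  obs
}

#' Population-max allele frequency over non-excluded populations
#'
#' @param pop_af Named numeric vector of per-population allele frequencies
#'   (codes matched case-insensitively).
#' @param excluded_populations Populations excluded from the maximum
#'   (bottlenecked populations by default). Returns 0 when no non-excluded
#'   population carries a frequency (the empty-max convention: such variants
#'   are treated as novel).
#' @return A single popmax AF in \[0, 1\].
#' @export
#' @examples
#' compute_popmax(c(afr = 0.02, nfe = 0.001, fin = 0.20))
compute_popmax <- function(pop_af, excluded_populations = bottlenecked_populations()) {
  if (length(pop_af) == 0) {
    return(0)
  }
  bad <- !is.na(pop_af) & (pop_af < 0 | pop_af > 1)
  if (any(bad)) {
    stop(
      "allele frequency outside [0, 1] for population(s): ",
      paste(names(pop_af)[bad], collapse = ", "),
      call. = FALSE
    )
  }
  keep <- !tolower(names(pop_af)) %in% tolower(excluded_populations)
  vals <- pop_af[keep]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    return(0)
  }
  max(vals)
}

#' Apply the rarity filter on global and popmax allele frequency
#'
#' Keeps observations with both global AF and popmax AF at or below
#' `max_af` (inclusive bound, as printed: "<= 1%"). Missing frequencies are
#' treated as 0 (absent from the frequency resource = novel), hence kept.
#'
#' @param obs Observation tibble with `global_af` and `popmax_af`.
#' @param max_af Maximum tolerated allele frequency (default 0.01).
#' @return `obs` with `keep`/`reason` (`allele_frequency`) columns.
#' @export
apply_af_filter <- function(obs, max_af = 0.01) {
  g <- ifelse(is.na(obs$global_af), 0, obs$global_af)
  p <- ifelse(is.na(obs$popmax_af), 0, obs$popmax_af)
  obs$keep <- g <= max_af & p <= max_af
  obs$reason <- ifelse(obs$keep, NA_character_, "allele_frequency")
  obs
}

# ---- Score and gene joins --------------------------------------------------

#' Read a predictor score table
#'
#' Tab-separated, one row per (chrom, pos, ref, alt, transcript); `"."` or
#' empty cells are missing scores.
#'
#' @param path Path to the TSV.
#' @param tools Tool column names expected in the file.
#' @return A tibble keyed by variant and transcript.
#' @export
read_score_table <- function(path, tools = default_tools()) {
  tbl <- readr::read_tsv(path,
    na = c(".", "", "NA"),
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      transcript = readr::col_character(), .default = readr::col_double()
    )
  )
  missing <- setdiff(tools, names(tbl))
  if (length(missing) > 0) {
    stop(
      "score table '", path, "' lacks column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tbl
}

#' The four packaged predictors
#'
#' @return Character vector of tool names with default threshold tables.
#' @export
default_tools <- function() c("BayesDel", "MutPred2", "REVEL", "VEST4")

# which packaged tools are looked up per transcript (vs per variant)
.transcript_specific <- c(
  BayesDel = FALSE, MutPred2 = TRUE, REVEL = TRUE, VEST4 = TRUE
)

#' Attach predictor scores to observations
#'
#' Transcript-specific predictors (MutPred2, REVEL, VEST4) are looked up for
#' the selected annotation's transcript; BayesDel is a variant-level score
#' looked up by (chrom, pos, ref, alt) alone. Variants (or transcripts)
#' absent from the table get `NA` scores. Duplicate keys carrying conflicting
#' scores are a data error.
#'
#' @param obs Observations with selected-annotation columns.
#' @param score_table Tibble from [read_score_table()].
#' @param tools Tools to attach.
#' @param transcript_specific Named logical, per-tool lookup granularity;
#'   defaults cover the packaged four, other tools default to
#'   transcript-specific.
#' @return `obs` with one `score_<tool>` column per tool.
#' @export
join_scores <- function(obs, score_table, tools = default_tools(),
                        transcript_specific = .transcript_specific) {
  key <- c("chrom", "pos", "ref", "alt")
  for (tool in tools) {
    ts <- if (tool %in% names(transcript_specific)) {
      transcript_specific[[tool]]
    } else {
      TRUE
    }
    cols <- if (ts) c(key, "transcript") else key
    sub <- score_table[!is.na(score_table[[tool]]), c(cols, tool)]
    dup <- sub |>
      dplyr::distinct() |>
      dplyr::count(dplyr::across(dplyr::all_of(cols))) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      stop(
        "conflicting ", tool, " scores for key(s): ",
        paste(utils::head(
          do.call(paste, c(dup[cols], sep = ":")), 3
        ), collapse = "; "),
        call. = FALSE
      )
    }
    sub <- dplyr::distinct(sub)
    names(sub)[names(sub) == tool] <- paste0("score_", tool)
    by <- if (ts) {
      c(key, "transcript_id")
    } else {
      key
    }
    names(by) <- c(key, if (ts) "transcript" else NULL)
    by <- setNames(names(by), by) # obs col -> table col
    obs <- dplyr::left_join(obs, sub, by = by)
  }
  obs
}

#' Read a gene-validity / mode-of-inheritance table
#'
#' Tab-separated with header columns `symbol`, `validity`
#' (Definitive/Strong/Moderate/other_or_absent), `moi`
#' (AD_only/AR_only/other).
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per gene symbol.
#' @export
read_gene_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("symbol", "validity", "moi")
  if (!all(need %in% names(tbl))) {
    stop("gene table '", path, "' must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(tbl$symbol)) {
    stop("gene table '", path, "' has duplicated symbols", call. = FALSE)
  }
  tbl
}

#' Attach gene validity/inheritance records; restrict to disease genes
#'
#' Under `scope = "disease_genes"` an observation is kept iff its gene has
#' curated validity Definitive, Strong, or Moderate; under `"genome_wide"`
#' everything is kept and the gene record attached where available (validity
#' `other_or_absent`, moi `NA` otherwise).
#'
#' @param obs Observations with a `gene_symbol` column.
#' @param gene_table Tibble from [read_gene_table()].
#' @param scope `"disease_genes"` or `"genome_wide"`.
#' @return `obs` with `validity`/`moi` and `keep`/`reason` columns.
#' @export
join_genes <- function(obs, gene_table, scope = c("disease_genes", "genome_wide")) {
  scope <- match.arg(scope)
  obs <- dplyr::left_join(obs, gene_table,
    by = c(gene_symbol = "symbol")
  )
  obs$validity[is.na(obs$validity)] <- "other_or_absent"
  disease <- obs$validity %in% c("Definitive", "Strong", "Moderate")
  obs$keep <- if (scope == "disease_genes") disease else rep(TRUE, nrow(obs))
  obs$reason <- ifelse(obs$keep, NA_character_, "not_disease_gene")
  obs
}

# ---- Full ingest chain -----------------------------------------------------

#' Ingest a cohort of per-proband VCFs into analyzable observations
#'
#' Runs the full filter chain — missense selection, genotype QC, allele
#' frequency, score and gene joins — over one VCF per proband, with exact
#' drop bookkeeping: for every proband, raw observations = kept + sum of
#' drops by reason.
#'
#' @param vcf_paths Character vector of VCF paths; names are proband IDs
#'   (defaults to file names without extension).
#' @param score_table Tibble from [read_score_table()].
#' @param gene_table Tibble from [read_gene_table()].
#' @param mode Transcript-selection mode, see [select_missense()].
#' @param max_af AF threshold, see [apply_af_filter()].
#' @param scope Gene scope, see [join_genes()].
#' @param qc [qc_thresholds()].
#' @param spec [annotation_spec()].
#' @param excluded_populations Passed to [compute_popmax()].
#' @param tools Predictors to attach.
#' @return A list of class `cohort_observations`: `observations` (kept rows,
#'   with scores and gene records), `drops` (tibble proband_id / stage /
#'   reason / n), `n_raw` (named integer per proband).
#' @export
ingest_cohort <- function(vcf_paths, score_table, gene_table,
                          mode = "mane_select", max_af = 0.01,
                          scope = "disease_genes",
                          qc = qc_thresholds(),
                          spec = annotation_spec(),
                          excluded_populations = bottlenecked_populations(),
                          tools = default_tools()) {
  if (is.null(names(vcf_paths))) {
    names(vcf_paths) <- sub("\\.vcf(\\.gz)?$", "", basename(vcf_paths))
  }
  raw <- vector("list", length(vcf_paths))
  orders <- vector("list", length(vcf_paths))
  for (i in seq_along(vcf_paths)) {
    raw[[i]] <- load_cohort_vcf(vcf_paths[i], names(vcf_paths)[i], spec)
    orders[[i]] <- attr(raw[[i]], "csq_fields")
  }
  field_order <- orders[[1]]
  if (length(orders) > 1 && !all(vapply(orders, identical, logical(1), field_order))) {
    stop("VCFs declare differing annotation sub-field orders", call. = FALSE)
  }
  obs <- dplyr::bind_rows(raw)
  n_raw <- table(factor(obs$proband_id, levels = names(vcf_paths)))

  drops <- list()
  take <- function(obs, stage) {
    d <- obs[!obs$keep, c("proband_id", "reason")]
    if (nrow(d) > 0) {
      d$stage <- stage
      drops[[length(drops) + 1]] <<- dplyr::count(d, .data$proband_id,
        .data$stage, .data$reason,
        name = "n"
      )
    }
    obs[obs$keep, setdiff(names(obs), c("keep", "reason"))]
  }

  obs <- take(select_missense(obs, mode, field_order, spec), "missense_selection")
  obs <- take(apply_genotype_filters(obs, qc), "genotype_qc")
  obs$popmax_af <- vapply(obs$pop_af, compute_popmax, 0,
    excluded_populations = excluded_populations
  )
  obs <- take(apply_af_filter(obs, max_af), "allele_frequency")
  obs <- join_scores(obs, score_table, tools)
  obs <- take(join_genes(obs, gene_table, scope), "gene_scope")

  structure(
    list(
      observations = obs,
      drops = if (length(drops) > 0) {
        dplyr::bind_rows(drops)
      } else {
        tibble::tibble(
          proband_id = character(), stage = character(),
          reason = character(), n = integer()
        )
      },
      n_raw = setNames(as.integer(n_raw), names(n_raw))
    ),
    class = "cohort_observations"
  )
}

#' @export
print.cohort_observations <- function(x, ...) {
  cat(
    "<cohort_observations> ", length(x$n_raw), " probands, ",
    sum(x$n_raw), " raw observations, ", nrow(x$observations), " kept\n",
    sep = ""
  )
  if (nrow(x$drops) > 0) {
    agg <- dplyr::count(x$drops, .data$stage, .data$reason,
      wt = .data$n, name = "n"
    )
    cat("drops:\n")
    print(as.data.frame(agg), row.names = FALSE)
  }
  invisible(x)
}

#' Classify every observation's scores under every tool
#'
#' Adds one `call_<tool>` category column per threshold table, applying
#' [classify_score()] to the matching `score_<tool>` column (absent score
#' columns yield `NoScore` throughout).
#'
#' @param obs Observation tibble with `score_<tool>` columns.
#' @param tables Named list of `threshold_table`s
#'   (default: [load_threshold_tables()]).
#' @return `obs` with `call_<tool>` columns.
#' @export
classify_cohort <- function(obs, tables = load_threshold_tables()) {
  for (tool in names(tables)) {
    sc <- paste0("score_", tool)
    s <- if (sc %in% names(obs)) obs[[sc]] else rep(NA_real_, nrow(obs))
    obs[[paste0("call_", tool)]] <- classify_score(s, tables[[tool]])
  }
  obs
}
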