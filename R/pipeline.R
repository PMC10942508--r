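#' Run configuration for an end-to-end evidence-yield analysis
#'
#' One run = one cell of the analysis grid: a transcript-selection mode,
#' an AF threshold, and a gene scope, over one set of input files.
#'
#' @param vcf_dir Directory of per-proband VCFs (`*.vcf` / `*.vcf.gz`).
#' @param scores Path to the predictor score TSV.
#' @param genes Path to the gene-list TSV.
#' @param thresholds Optional path to a threshold YAML (default: packaged
#'   calibration).
#' @param classifications Optional path to an external variant-classification
#'   TSV for concordance tables.
#' @param mode `"mane_select"` or `"most_severe"`.
#' @param max_af AF threshold (default 0.01).
#' @param scope `"disease_genes"` or `"genome_wide"`.
#' @param iterations Bootstrap iterations (default 1000).
#' @param seed Integer seed for all resampling.
#' @param n_tests Bonferroni multiplier for the AR/AD comparisons.
#' @param bootstrap_unit `"observation"` or `"proband"`.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf_dir, scores, genes, thresholds = NULL,
                       classifications = NULL,
                       mode = "mane_select", max_af = 0.01,
                       scope = "disease_genes",
                       iterations = 1000, seed = 1, n_tests = 4,
                       bootstrap_unit = "observation", out_dir = NULL) {
  cfg <- structure(
    list(
      vcf_dir = vcf_dir, scores = scores, genes = genes,
      thresholds = thresholds, classifications = classifications,
      mode = match.arg(mode, c("mane_select", "most_severe")),
      max_af = max_af,
      scope = match.arg(scope, c("disease_genes", "genome_wide")),
      iterations = iterations, seed = seed, n_tests = n_tests,
      bootstrap_unit = match.arg(bootstrap_unit, c("observation", "proband")),
      out_dir = out_dir
    ),
    class = "run_config"
  )
  for (p in c("vcf_dir", "scores", "genes")) {
    if (!file.exists(cfg[[p]])) {
      stop("configured ", p, " path does not exist: ", cfg[[p]], call. = FALSE)
    }
  }
  cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the evidence-yield pipeline end to end
#'
#' Ingest -> classify -> tabulate -> statistics, with per-stage count
#' bookkeeping. Identical configuration and seed give identical outputs.
#' When `cfg$out_dir` is set, writes `observations.tsv`, `yield_summary.tsv`,
#' `per_proband_counts.tsv`, `stats.json`, and `manifest.json`.
#'
#' @param cfg A [run_config()].
#' @return A list of class `run_bundle`: `observations`, `yield`
#'   (a `yield_table`), `unique_counts`, `pp3_strong_ci` (per tool),
#'   `moi_comparisons`, optional `concordance` (per tool), `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  vcfs <- list.files(cfg$vcf_dir, pattern = "\\.vcf(\\.gz)?$", full.names = TRUE)
  if (length(vcfs) == 0) {
    stop("no VCF files found under '", cfg$vcf_dir, "'", call. = FALSE)
  }
  score_table <- read_score_table(cfg$scores)
  gene_table <- read_gene_table(cfg$genes)
  tables <- load_threshold_tables(cfg$thresholds)

  ingest <- ingest_cohort(vcfs, score_table, gene_table,
    mode = cfg$mode, max_af = cfg$max_af, scope = cfg$scope
  )
  obs <- classify_cohort(ingest$observations, tables)
  yield <- tabulate_yield(obs)
  uniq <- unique_variant_count(obs)

  tools <- names(tables)
  pp3_strong_ci <- lapply(setNames(tools, tools), function(tool) {
    proportion_with_bootstrap(
      obs,
      function(d) d[[paste0("call_", tool)]] == "PP3_Strong",
      iterations = cfg$iterations, seed = cfg$seed, unit = cfg$bootstrap_unit
    )
  })
  moi <- dplyr::bind_rows(lapply(tools, function(tool) {
    tryCatch(compare_moi(obs, tool, n_tests = cfg$n_tests),
      error = function(e) NULL
    )
  }))
  conc <- NULL
  if (!is.null(cfg$classifications)) {
    ext <- read_classification_table(cfg$classifications)
    conc <- lapply(setNames(tools, tools), function(tool) {
      concordance(obs[obs[[paste0("call_", tool)]] == "PP3_Strong", ], ext)
    })
  }

  stage_counts <- list(
    raw = sum(ingest$n_raw),
    dropped = sum(ingest$drops$n),
    kept = nrow(obs)
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("evidenceyield")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_probands = length(ingest$n_raw),
    stage_counts = stage_counts,
    drops_by_reason = if (nrow(ingest$drops) > 0) {
      as.list(tapply(ingest$drops$n, ingest$drops$reason, sum))
    } else {
      list()
    }
  )
  bundle <- structure(
    list(
      observations = obs, yield = yield, unique_counts = uniq,
      pp3_strong_ci = pp3_strong_ci, moi_comparisons = moi,
      concordance = conc, drops = ingest$drops, manifest = manifest
    ),
    class = "run_bundle"
  )
  if (!is.null(cfg$out_dir)) write_run_bundle(bundle, cfg$out_dir)
  bundle
}

#' Write a run bundle's tables and manifest to disk
#'
#' @param bundle A `run_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output paths.
#' @export
write_run_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obs <- bundle$observations
  obs$pop_af <- NULL
  obs$csq <- NULL
  paths <- list(
    observations = file.path(out_dir, "observations.tsv"),
    yield = file.path(out_dir, "yield_summary.tsv"),
    per_proband = file.path(out_dir, "per_proband_counts.tsv"),
    stats = file.path(out_dir, "stats.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_tsv(obs, paths$observations)
  readr::write_tsv(format_yield_summary(bundle$yield), paths$yield)
  readr::write_tsv(bundle$yield$per_proband, paths$per_proband)
  stats <- list(
    pp3_strong_ci = lapply(bundle$pp3_strong_ci, unclass),
    moi_comparisons = bundle$moi_comparisons,
    concordance = lapply(bundle$concordance, unclass)
  )
  jsonlite::write_json(stats, paths$stats, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$manifest, paths$manifest,
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  invisible(paths)
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("<run_bundle>\n")
  cat(
    " probands:", x$manifest$n_probands,
    " raw:", x$manifest$stage_counts$raw,
    " kept:", x$manifest$stage_counts$kept, "\n"
  )
  print(x$yield)
  invisible(x)
}
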