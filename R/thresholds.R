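#' Construct a calibrated threshold table for one predictor
#'
#' A threshold table maps a predictor's raw score to a PP3/BP4
#' evidence-strength category by interval classification. Pathogenic
#' breakpoints are lower bounds (score `>=` breakpoint, inclusive toward the
#' stronger evidence) and must strictly increase with strength; benign
#' breakpoints are upper bounds (score `<=` breakpoint) and must strictly
#' decrease with strength. The gap between the weakest benign and weakest
#' pathogenic breakpoints is the indeterminate interval, which must be
#' non-empty.
#'
#' @param tool Predictor name, e.g. `"REVEL"`.
#' @param pathogenic Named numeric vector of pathogenic-direction breakpoints;
#'   names from `Supporting`, `Moderate`, `Strong`, `VeryStrong`. Strengths a
#'   tool cannot reach are simply omitted.
#' @param benign Named numeric vector of benign-direction breakpoints, same
#'   naming scheme.
#' @param score_range Length-2 numeric, the closed interval of valid scores.
#' @param source Free-text provenance of the numeric values.
#'
#' @return An object of class `threshold_table`.
#' @export
#' @examples
#' threshold_table("toy",
#'   pathogenic = c(Supporting = 0.5, Moderate = 0.7, Strong = 0.9),
#'   benign = c(Supporting = 0.3, Moderate = 0.1),
#'   score_range = c(0, 1)
#' )
threshold_table <- function(tool, pathogenic, benign, score_range,
                            source = NA_character_) {
  tt <- structure(
    list(
      tool = tool,
      direction = "higher_is_deleterious",
      pathogenic = as.list(pathogenic),
      benign = as.list(benign),
      score_range = as.numeric(score_range),
      source = source
    ),
    class = "threshold_table"
  )
  validate_threshold_table(tt)
  tt
}

#' @export
print.threshold_table <- function(x, ...) {
  cat("<threshold_table> ", x$tool, "\n", sep = "")
  cat("  score range: [", x$score_range[1], ", ", x$score_range[2], "]\n", sep = "")
  fmt <- function(b) paste(sprintf("%s=%g", names(b), unlist(b)), collapse = ", ")
  cat("  pathogenic (score >=):", fmt(x$pathogenic), "\n")
  cat("  benign     (score <=):", fmt(x$benign), "\n")
  invisible(x)
}

#' Validate a threshold table
#'
#' Checks the structural invariants: known strength labels, strictly
#' increasing pathogenic breakpoints, strictly decreasing benign breakpoints,
#' a non-empty indeterminate interval between the two directions, and all
#' breakpoints within the score range.
#'
#' @param tt A `threshold_table`.
#' @return `tt`, invisibly; errors (naming the tool) on violation.
#' @export
validate_threshold_table <- function(tt) {
  fail <- function(msg) {
    stop("invalid threshold table for tool '", tt$tool, "': ", msg, call. = FALSE)
  }
  if (length(tt$score_range) != 2 || diff(tt$score_range) <= 0) {
    fail("score_range must be an increasing length-2 interval")
  }
  for (side in c("pathogenic", "benign")) {
    bp <- tt[[side]]
    if (length(bp) == 0) fail(paste0("no ", side, " breakpoints"))
    if (!all(names(bp) %in% .strength_levels)) {
      fail(paste0("unknown strength label in ", side, " breakpoints"))
    }
    ord <- unlist(bp[intersect(.strength_levels, names(bp))])
    if (side == "pathogenic" && is.unsorted(ord, strictly = TRUE)) {
      fail("pathogenic breakpoints must strictly increase with strength")
    }
    if (side == "benign" && is.unsorted(rev(ord), strictly = TRUE)) {
      fail("benign breakpoints must strictly decrease with strength")
    }
    vals <- unlist(bp)
    if (any(vals < tt$score_range[1] | vals > tt$score_range[2])) {
      fail(paste0(side, " breakpoints outside score_range"))
    }
  }
  if (max(unlist(tt$benign)) >= min(unlist(tt$pathogenic))) {
    fail("benign and pathogenic intervals overlap; no indeterminate interval")
  }
  invisible(tt)
}

#' Load calibrated threshold tables from a YAML config
#'
#' Reads one `threshold_table` per tool from a structured config file and
#' validates every invariant on load. With no argument, loads the packaged
#' default tables for the four metapredictors able to reach PP3_Strong and
#' BP4_Moderate under the published interval calibration (BayesDel without
#' allele frequency, MutPred2, REVEL, VEST4).
#'
#' @param path Path to a YAML file; `NULL` (default) for the packaged config.
#' @return Named list of `threshold_table` objects, keyed by tool.
#' @export
#' @examples
#' tables <- load_threshold_tables()
#' names(tables)
load_threshold_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "thresholds_pejaver2022.yaml",
      package = "evidenceyield", mustWork = TRUE
    )
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tools) || length(cfg$tools) == 0) {
    stop("threshold config '", path, "' defines no tools", call. = FALSE)
  }
  tabs <- lapply(names(cfg$tools), function(tool) {
    tc <- cfg$tools[[tool]]
    threshold_table(
      tool = tool,
      pathogenic = unlist(tc$pathogenic),
      benign = unlist(tc$benign),
      score_range = unlist(tc$score_range),
      source = tc$source %||% NA_character_
    )
  })
  setNames(tabs, names(cfg$tools))
}

#' Classify raw scores into PP3/BP4 evidence-strength categories
#'
#' Interval classification of one predictor's scores against its calibrated
#' threshold table: the strongest pathogenic strength whose breakpoint the
#' score meets (`score >= breakpoint`) wins; failing that, the strongest
#' benign strength met (`score <= breakpoint`); failing both, `Indeterminate`.
#' Missing scores (`NA`) map to `NoScore`. Scores equal to a breakpoint take
#' the stronger evidence. Scores outside the table's `score_range` are a data
#' error, not silently clamped.
#'
#' @param score Numeric vector of raw scores (NA = missing).
#' @param table A `threshold_table`.
#' @return Character vector of categories, same length as `score`.
#' @export
#' @examples
#' tt <- threshold_table("toy",
#'   pathogenic = c(Supporting = 0.5, Moderate = 0.7, Strong = 0.9),
#'   benign = c(Supporting = 0.3, Moderate = 0.1), score_range = c(0, 1)
#' )
#' classify_score(c(0.95, 0.9, 0.4, NA, 0.05), tt)
classify_score <- function(score, table) {
  stopifnot(inherits(table, "threshold_table"))
  out <- rep(NA_character_, length(score))
  out[is.na(score)] <- "NoScore"
  present <- !is.na(score)
  s <- score[present]
  if (any(s < table$score_range[1] | s > table$score_range[2])) {
    bad <- s[s < table$score_range[1] | s > table$score_range[2]]
    stop(
      "score outside [", table$score_range[1], ", ", table$score_range[2],
      "] for tool '", table$tool, "': ", paste(head(bad, 3), collapse = ", "),
      call. = FALSE
    )
  }
  res <- rep("Indeterminate", length(s))
  # weakest to strongest so later (stronger) assignments win
  for (st in .strength_levels) {
    b <- table$benign[[st]]
    if (!is.null(b)) res[s <= b] <- paste0("BP4_", st)
  }
  for (st in .strength_levels) {
    p <- table$pathogenic[[st]]
    if (!is.null(p)) res[s >= p] <- paste0("PP3_", st)
  }
  out[present] <- res
  out
}

#' Classify a variant's scores under every tool
#'
#' Applies [classify_score()] per tool to a named score vector; tools absent
#' from the vector (or present as `NA`) yield `NoScore`. Calls for different
#' tools are independent: a variant may be `PP3_Strong` under one predictor
#' and `Indeterminate` under another.
#'
#' @param scores Named numeric vector (names are tool names), possibly
#'   missing some tools.
#' @param tables Named list of `threshold_table`s, one per requested tool.
#' @return Named character vector, one category per table in `tables`.
#' @export
classify_variant <- function(scores, tables) {
  vapply(names(tables), function(tool) {
    s <- if (tool %in% names(scores)) scores[[tool]] else NA_real_
    classify_score(s, tables[[tool]])
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
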