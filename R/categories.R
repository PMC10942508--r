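#' The ordered PP3/BP4 evidence-strength scale
#'
#' Categories run from strongest computational evidence of pathogenicity
#' (`PP3_VeryStrong`) through the indeterminate interval to strongest evidence
#' of benignity (`BP4_VeryStrong`); `NoScore` marks variants the predictor did
#' not score. The ordering is used for factor levels in all yield tables and
#' for the monotonicity guarantees of the interval classifier.
#'
#' @return Character vector of the ten categories, pathogenic end first.
#' @export
#' @examples
#' evidence_categories()
evidence_categories <- function() {
  c(
    "PP3_VeryStrong", "PP3_Strong", "PP3_Moderate", "PP3_Supporting",
    "Indeterminate",
    "BP4_Supporting", "BP4_Moderate", "BP4_Strong", "BP4_VeryStrong",
    "NoScore"
  )
}

# strength labels in increasing order of evidence weight
.strength_levels <- c("Supporting", "Moderate", "Strong", "VeryStrong")

.category_factor <- function(x) {
  factor(x, levels = evidence_categories())
}

#' VEP consequence severity ranking
#'
#' Returns the packaged consequence-severity table (the ordering published by
#' the Ensembl Variant Effect Predictor, rank 1 = most severe), used to decide
#' whether missense is the most severe consequence across transcripts.
#'
#' @return A tibble with columns `consequence` and `rank`.
#' @export
consequence_severity <- function() {
  path <- system.file("extdata", "vep_consequence_rank.tsv",
    package = "evidenceyield", mustWork = TRUE
  )
  readr::read_tsv(path, col_types = readr::cols(
    consequence = readr::col_character(), rank = readr::col_integer()
  ))
}

# rank lookup for a vector of (possibly "&"-joined) consequence strings;
# unknown terms rank below every known term rather than erroring
.severity_rank <- function(consequence, rank_table) {
  ranks <- setNames(rank_table$rank, rank_table$consequence)
  worst <- max(rank_table$rank) + 1L
  vapply(strsplit(consequence, "&", fixed = TRUE), function(terms) {
    r <- ranks[terms]
    r[is.na(r)] <- worst
    as.integer(min(r))
  }, integer(1))
}
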