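#' Configuration for the Bayesian point-based ACMG/AMP combiner
#'
#' The point-based adaptation of the ACMG/AMP framework maps evidence
#' strengths to exponentially weighted points (Supporting 1, Moderate 2,
#' Strong 4, VeryStrong 8; benign evidence negative) and converts a summed
#' point total to a posterior probability of pathogenicity through
#'
#' \deqn{O_{post} = O_{VSt}^{\,points/8} \times \frac{prior}{1-prior}, \qquad
#'       P_{post} = O_{post}/(1+O_{post})}
#'
#' where \eqn{O_{VSt}} is the odds of pathogenicity assigned to one
#' VeryStrong evidence line. Defaults are the published framework constants:
#' prior 0.1, odds 350, and class bounds Pathogenic >= 10, Likely Pathogenic
#' 6..9, VUS 0..5, Likely Benign -6..-1, Benign <= -7.
#'
#' Two named priors are exposed for context-specific posterior computations:
#' `"disease_genes"` (0.045, the approximate prior for rare missense variants
#' in disease-associated genes) and `"genome_wide"` (0.01, roughly five-fold
#' lower, matching the genome having about five-fold more genes than are
#' covered by disease-gene classification).
#'
#' @param prior Prior probability of pathogenicity, in (0, 1), or one of the
#'   preset names `"disease_genes"` / `"genome_wide"`.
#' @param odds_very_strong Odds of pathogenicity for one VeryStrong line.
#' @param point_values Named integer vector, points per strength.
#' @param class_bounds Named list of inclusive point intervals
#'   `c(lower, upper)` per classification; must partition the integers.
#' @return An object of class `bayes_config`.
#' @export
#' @examples
#' cfg <- bayes_config()
#' posterior_probability(10, cfg)
bayes_config <- function(prior = 0.1,
                         odds_very_strong = 350,
                         point_values = c(
                           Supporting = 1L, Moderate = 2L,
                           Strong = 4L, VeryStrong = 8L
                         ),
                         class_bounds = list(
                           Pathogenic = c(10, Inf),
                           Likely_Pathogenic = c(6, 9),
                           VUS = c(0, 5),
                           Likely_Benign = c(-6, -1),
                           Benign = c(-Inf, -7)
                         )) {
  if (is.character(prior)) {
    prior <- switch(prior,
      disease_genes = 0.045,
      genome_wide = 0.01,
      stop("unknown prior preset '", prior, "'", call. = FALSE)
    )
  }
  stopifnot(prior > 0, prior < 1, odds_very_strong > 1)
  if (!setequal(names(point_values), .strength_levels)) {
    stop("point_values must name exactly ", paste(.strength_levels, collapse = ", "),
      call. = FALSE
    )
  }
  # class bounds must tile the integer line with no overlap
  iv <- do.call(rbind, class_bounds)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (any(iv[-1, 1] != iv[-nrow(iv), 2] + 1)) {
    stop("class_bounds overlap or leave gaps on the integer point scale",
      call. = FALSE
    )
  }
  structure(
    list(
      prior = prior, odds_very_strong = odds_very_strong,
      point_values = point_values, class_bounds = class_bounds
    ),
    class = "bayes_config"
  )
}

#' Build an evidence profile from code/strength/direction triples
#'
#' @param code Character vector of ACMG/AMP code labels (e.g. `"PP3"`).
#' @param strength Character vector of strengths
#'   (`Supporting`/`Moderate`/`Strong`/`VeryStrong`).
#' @param direction `"pathogenic"` or `"benign"` per entry. Defaults to
#'   benign for codes starting `B`, pathogenic otherwise.
#' @return A tibble with class `evidence_profile`. At most one PP3-family or
#'   BP4-family entry is allowed: computational evidence for and against
#'   pathogenicity is mutually exclusive for a variant.
#' @export
#' @examples
#' evidence_profile(c("PP3", "PM2"), c("Strong", "Supporting"))
evidence_profile <- function(code = character(), strength = character(),
                             direction = NULL) {
  if (is.null(direction)) {
    direction <- ifelse(startsWith(code, "B"), "benign", "pathogenic")
  }
  stopifnot(
    length(code) == length(strength),
    length(code) == length(direction),
    all(direction %in% c("pathogenic", "benign"))
  )
  bad <- !strength %in% .strength_levels
  if (any(bad)) {
    stop("unknown strength label: ", paste(unique(strength[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  comp <- code %in% c("PP3", "BP4")
  if (sum(comp) > 1) {
    stop("at most one PP3/BP4 entry per profile: computational evidence for ",
      "and against pathogenicity is mutually exclusive",
      call. = FALSE
    )
  }
  structure(
    tibble::tibble(code = code, strength = strength, direction = direction),
    class = c("evidence_profile", "tbl_df", "tbl", "data.frame")
  )
}

#' Parse a compact code string into an evidence profile
#'
#' Accepts the CLI syntax `"PP3:Strong,PM2:Supporting,BS1:Strong"`.
#'
#' @param x A single string; empty string gives an empty profile.
#' @return An `evidence_profile`.
#' @export
parse_evidence_codes <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  x <- trimws(x)
  if (!nzchar(x)) {
    return(evidence_profile())
  }
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("expected 'CODE:Strength' entries, got '", x, "'", call. = FALSE)
  }
  evidence_profile(
    code = trimws(vapply(parts, `[`, character(1), 1)),
    strength = trimws(vapply(parts, `[`, character(1), 2))
  )
}

#' Sum evidence points over a profile
#'
#' Signed sum of the configured point values: pathogenic entries count
#' positive, benign entries negative. Invariant under permutation of entries.
#'
#' @param profile An `evidence_profile`.
#' @param cfg A `bayes_config`.
#' @return Integer point total.
#' @export
#' @examples
#' total_points(evidence_profile("PP3", "Strong")) # 4
total_points <- function(profile, cfg = bayes_config()) {
  stopifnot(inherits(cfg, "bayes_config"))
  if (nrow(profile) == 0) {
    return(0L)
  }
  pts <- cfg$point_values[profile$strength]
  if (anyNA(pts)) {
    stop("unknown strength label in profile", call. = FALSE)
  }
  as.integer(sum(ifelse(profile$direction == "benign", -pts, pts)))
}

#' Posterior probability of pathogenicity from a point total
#'
#' Closed-form posterior under the exponential point scale: posterior odds
#' equal `odds_very_strong^(points/8)` times the prior odds. At zero points
#' the posterior equals the prior exactly.
#'
#' @param points Numeric vector of point totals.
#' @param cfg A `bayes_config`.
#' @return Numeric vector of posterior probabilities in (0, 1).
#' @export
#' @examples
#' posterior_probability(c(0, 6, 10), bayes_config())
posterior_probability <- function(points, cfg = bayes_config()) {
  stopifnot(inherits(cfg, "bayes_config"))
  odds <- cfg$odds_very_strong^(points / 8) * cfg$prior / (1 - cfg$prior)
  odds / (1 + odds)
}

#' Classify a point total and attach its posterior
#'
#' @param points Integer point total (scalar).
#' @param cfg A `bayes_config`.
#' @return A list of class `combination_result` with `total_points`,
#'   `posterior`, and `classification` (one of Pathogenic, Likely_Pathogenic,
#'   VUS, Likely_Benign, Benign).
#' @export
#' @examples
#' classify_combination(4) # a lone PP3_Strong: VUS
classify_combination <- function(points, cfg = bayes_config()) {
  stopifnot(inherits(cfg, "bayes_config"), length(points) == 1)
  cls <- NULL
  for (nm in names(cfg$class_bounds)) {
    b <- cfg$class_bounds[[nm]]
    if (points >= b[1] && points <= b[2]) {
      cls <- nm
      break
    }
  }
  if (is.null(cls)) {
    stop("point total ", points, " matches no classification interval", call. = FALSE)
  }
  structure(
    list(
      total_points = as.integer(points),
      posterior = posterior_probability(points, cfg),
      classification = cls
    ),
    class = "combination_result"
  )
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf(
    "%d points -> %s (posterior %.4f)\n",
    x$total_points, x$classification, x$posterior
  ))
  invisible(x)
}

#' Combine evidence codes end to end
#'
#' Convenience wrapper: profile -> points -> posterior + classification.
#'
#' @param profile An `evidence_profile` (or compact string accepted by
#'   [parse_evidence_codes()]).
#' @param cfg A `bayes_config`.
#' @return A `combination_result`.
#' @export
#' @examples
#' combine_evidence("PP3:Strong,PM2:Moderate,PP1:Supporting")
combine_evidence <- function(profile, cfg = bayes_config()) {
  if (is.character(profile)) profile <- parse_evidence_codes(profile)
  classify_combination(total_points(profile, cfg), cfg)
}
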