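---
title: "Counting calibrated PP3/BP4 evidence in rare-disease cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting calibrated PP3/BP4 evidence in rare-disease cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evidenceyield)
```

## The question the package answers

Clinical variant classification under the ACMG/AMP framework admits
computational (in silico) predictions as evidence for (PP3) or against (BP4)
a deleterious effect. Interval calibrations of missense metapredictors assign
each tool score ranges corresponding to Supporting, Moderate, Strong, and in
some cases Very Strong evidence, replacing the older convention that capped
computational evidence at Supporting. A natural worry follows: if a
predictor can now contribute Strong evidence, how many variants per patient
will actually receive it? If the answer were "dozens," calibrated PP3 could
flood classification pipelines with spurious Likely Pathogenic calls.

`evidenceyield` answers this *evidence-yield* question operationally. It
ingests a cohort of annotated single-sample genome VCFs, restricts to rare
missense variants that pass genotype-level quality control, classifies each
variant's predictor scores (BayesDel without allele frequency, MutPred2,
REVEL, VEST4) into the ordered evidence scale

> PP3_VeryStrong > PP3_Strong > PP3_Moderate > PP3_Supporting >
> Indeterminate > BP4_Supporting > ... > BP4_VeryStrong, plus NoScore,

and tabulates per-proband counts by tool and category, with cohort summary
statistics, bootstrap confidence intervals, exact binomial comparisons
between inheritance strata, and external-classification concordance. A
companion module implements the Bayesian point-based adaptation of the
ACMG/AMP framework, so the downstream consequence of any evidence profile —
its point total, posterior probability of pathogenicity, and five-tier
classification — is computable in the same package.

## The filter chain

Observations flow through fixed, auditable stages; every drop carries a
reason, and per proband the identity *raw = kept + dropped* holds exactly.

1. **Missense selection.** Two transcript-selection modes. `mane_select`
   keeps a variant iff its annotation on the MANE Select transcript calls
   `missense_variant`. `most_severe` keeps it iff missense is the most
   severe consequence across all transcripts under the packaged VEP severity
   ordering, preferring the MANE transcript as tie-break; this recovers
   variants that are missense only on alternative transcripts.
2. **Genotype QC.** Inclusive lower bounds: genotype quality >= 40 (phred),
   depth >= 10 reads, allele balance >= 0.2 (alt reads / depth, applied to
   het and hom-alt genotypes alike; only the lower bound is enforced).
   Records whose QC sub-fields are absent are dropped as `missing_qc`: a
   record that cannot demonstrate the bounds is not retained.
3. **Rarity.** Both the global allele frequency and the population-max
   ("popmax") frequency over non-bottlenecked populations must be at or
   below the threshold (default 1%, with 5% as the standard sensitivity
   setting). Excluded bottlenecked populations default to
   {ASJ, FIN, AMI, MID, OTH}. Variants absent from the frequency resource
   count as allele frequency 0 (novel) and are kept; the popmax of an
   empty set is 0 by the same convention.
4. **Scores.** Transcript-specific predictors (MutPred2, REVEL, VEST4) are
   looked up on the selected transcript; BayesDel is variant-level. A score
   on a non-selected transcript does not attach.
5. **Gene scope.** `disease_genes` keeps only genes with curated
   gene-disease validity Definitive, Strong, or Moderate; `genome_wide`
   keeps everything and attaches the gene record where available.

Boundary semantics everywhere are inclusive exactly as written: a GQ of 40
passes, an AF equal to the threshold passes.

## Interval classification and its conventions

Each tool's calibrated thresholds live in a packaged YAML table
(`inst/extdata/thresholds_pejaver2022.yaml`, transcribed from the published
interval calibration, with the source cited per tool). The classifier takes
the strongest pathogenic strength whose breakpoint the score meets
(`score >= breakpoint`), else the strongest benign strength met
(`score <= breakpoint`), else `Indeterminate`; missing scores are `NoScore`.

Two deliberate conventions:

- **Ties favor the stronger evidence.** A score exactly at a breakpoint
  takes that breakpoint's category. The calibration's interval-closure
  convention is not restated in most secondary sources, so this package
  fixes one, documents it, and applies it consistently; with continuous
  scores at full input precision the choice affects only exact-boundary
  values.
- **Out-of-range scores are data errors**, not clamped: a REVEL score of
  1.2 indicates a broken upstream join, and silently clamping it would hide
  that.

Strengths a tool cannot reach are simply absent from its table, which makes
impossible categories structurally impossible: BayesDel and VEST4 cannot
emit BP4_Strong or deeper, MutPred2 cannot emit BP4_VeryStrong, and none of
the four reaches PP3_VeryStrong. The test suite asserts this by sampling the
full score range.

## The Bayesian point combiner

The point-based adaptation maps strengths to exponentially weighted points
(Supporting 1, Moderate 2, Strong 4, VeryStrong 8; benign negative) and
computes

$$O_{post} = O_{VSt}^{\,points/8}\cdot\frac{prior}{1-prior},\qquad
  P_{post}=\frac{O_{post}}{1+O_{post}}$$

with defaults $O_{VSt}=350$ and prior 0.1, and class bounds Pathogenic
>= 10 points, Likely Pathogenic 6–9, VUS 0–5, Likely Benign −6…−1, Benign
<= −7. Under these defaults the minimal Pathogenic total gives a posterior
of `r sprintf("%.2f%%", 100 * posterior_probability(10))` and the minimal
Likely Pathogenic total
`r sprintf("%.2f%%", 100 * posterior_probability(6))` — the familiar 99%/90%
anchors — and a lone PP3_Strong (4 points) lands in VUS. Because the
appropriate prior differs by context, two named presets are exposed:
`"disease_genes"` (0.045) and `"genome_wide"` (0.01, about five-fold lower,
matching the genome having roughly five-fold more genes than the curated
disease set). The sentence "99% or 90% posterior" is prior-dependent; the
engine therefore never fixes a prior silently — it is an explicit,
inspectable part of the configuration.

The combiner deliberately implements *only* the point arithmetic. ACMG/AMP
code-applicability semantics (when PM2 may be claimed, double-counting
between predictors and domain-based codes, and so on) are curation policy,
not arithmetic, and enforcing them here would give a false sense of
automation. At most one PP3/BP4-family entry is allowed per profile, since
computational evidence for and against pathogenicity is mutually exclusive
for one variant.

## Cohort statistics

- **Summaries.** Per tool and category: median (midpoint interpolation for
  even cohorts, so a median of 17.5 is representable), min, max, mean, and
  sample standard deviation (n−1; a single-proband cohort reports 0 rather
  than NA).
- **Bootstrap CIs.** Percentile intervals (2.5/97.5) over 1,000 resamples
  with replacement by default. The default resampling unit is the
  observation (proband-variant pair): at cohort scale (~10^4–10^5
  observations) this is what produces sub-0.01-percentage-point CI widths
  on category proportions. Proband-level resampling is available via
  `unit = "proband"` for statistics where between-proband variance is the
  question. Seeds are mandatory arguments — there is no hidden global
  randomness anywhere in the package.
- **AR vs AD enrichment.** `compare_moi()` tests whether variants at given
  strengths (default Moderate+Strong; add Supporting for sensitivity) are
  over-represented in AR-only genes. The null proportion defaults to the
  AR share of *all* analyzed observations in the AR-only/AD-only strata
  (a gene-count null can be supplied via `null_p0`). The exact two-tailed
  p-value uses the minimum-likelihood definition — the sum of probabilities
  of all outcomes no more probable than the observed one — which is what
  `stats::binom.test()` computes; the test suite verifies it against full
  outcome enumeration for n <= 50. Bonferroni correction multiplies by the
  number of tests (default 4, one per tool).
- **Concordance.** Unique variants at a category are matched against a
  user-supplied variant→class snapshot (vocabulary P/LP, VUS, Conflicting,
  B/LB; VUS and Conflicting are reported as one group). Coverage and
  within-reported proportions are returned; there is no live database
  access.

Proportions of "all analyzed variants" are reported against the observation
denominator; `unique_variant_count()` provides the deduplicated-variant
denominator alongside, since either reading can be wanted.

## What the synthetic cohort emulates — and what it does not

Real rare-disease cohort genotypes cannot be redistributed, so the
package ships a generator whose output has the statistical structure the
analysis consumes, in the exact input formats (per-proband VCFs with
GT/GQ/DP/AD, AF and per-population AF INFO keys, VEP-style CSQ annotations
with header-declared sub-field order; a score TSV; a gene-list TSV), plus a
ground-truth table.

Default conditions (one decision each, fixed up front):

- **300 probands**; analyzable variants per proband negative-binomial with
  mean 75, size 15 (disease-gene scope; the long right tail of a
  negative binomial matches per-proband count dispersion in outbred
  cohorts). The genome-wide preset uses mean 321 and a five-fold larger
  gene pool.
- **Gene strata** 1,004 AD-only : 1,903 AR-only : 517 other, with curated
  validity sampled 50/25/25% Definitive/Strong/Moderate (the validity split
  does not enter any statistic; only membership does).
- **Scores**: per tool, a two-component mixture of Beta distributions on
  the normalized score range — benign component Beta(2, 9) for all tools,
  deleterious components Beta(6, 2) (BayesDel, VEST4) and Beta(8, 1.5)
  (MutPred2, REVEL) — with a shared per-variant deleterious label at
  fraction 0.05. Sharing the label induces positive inter-tool correlation;
  given the label, tools are conditionally independent (a correlation knob
  is deliberately out of scope). These shapes were tuned once so the
  analytic PP3_Strong mass per tool lands at 1.1–1.3% of scored variants —
  the order reported for rare missense variants in disease-associated
  genes — and are documented as a tuned emulation, not as ground truth
  about real score distributions.
- **Missingness** per tool 0.4% / 0% / 14% / 7.7% (BayesDel / MutPred2 /
  REVEL / VEST4), the NoScore structure of a dbNSFP-style annotation.
- **Engineered edge cases**: fixed fractions of variants that fail exactly
  one QC bound (or lack QC sub-fields entirely), carry popmax AF in
  (1.2%, 5%] (dropped at 1%, kept at 5%), are synonymous on the MANE
  transcript, or are missense only on an alternative transcript. Each
  carries its status in the truth table, so round-trip tests can assert
  drops with exactly the engineered reasons.
- **Allele frequencies**: 40% of variants are novel (absent from the
  frequency resource); the rest draw a global AF skewed toward 0 with
  per-population jitter, including occasional large Finnish frequencies
  that the popmax exclusion must ignore.

Randomness flows from one master seed split into six documented per-stage
sub-seeds (gene table, counts, layout, QC, frequencies, scores), drawn in a
fixed order; identical seeds give byte-identical fixtures. Every variant is
private to its proband: with no recurrent variants, per-observation
statistics behave as independent draws from the configured mixtures, which
is what makes the 3-standard-error parameter-recovery bound in the test
suite well calibrated. Recurrence, linkage, pedigree structure, haplotypes,
sequencing artifacts beyond the QC fields, and realistic site spectra are
all *not* modeled — so passing tests demonstrate that the pipeline measures
what the generator encodes, not that real cohorts look like the generator.

`expected_yield()` is the generator's analytic counterpart: the exact
probability mass of each tool's mixture in each category interval, against
which the empirical pipeline output is compared. On the default
configuration the full pipeline (fixtures written to disk, re-ingested,
classified, tabulated) recovers every tool x category fraction within
three binomial standard errors, and the per-proband PP3_Strong median is 0
or 1 — about one strong-evidence variant per proband at ~75 rare missense
variants each, an order of magnitude that makes clear why calibrated
PP3_Strong does not flood classification.

## Numerical and degenerate-input choices

- Scores are compared at full input precision; the generator rounds drawn
  scores to 6 decimals *before* computing truth categories, so the text
  fixtures round-trip bit-for-bit.
- Allele frequencies are written with 6 significant digits; truth popmax is
  computed after rounding for the same reason.
- Indels survive ingest and per-alt decomposition but can never be selected
  (missense requires an SNV consequence); no left-alignment or
  normalization is attempted — inputs are assumed normalized upstream.
- Hemizygous/X genotypes are not special-cased; a `1` genotype is treated
  as hom-alt for the allele-balance bound.
- Multi-allelic sites decompose into one observation per called alt allele,
  sharing chrom/pos/ref; annotations without an allele sub-field apply to
  every alt of the line.
- An empty VCF, an empty cohort, and an all-excluded popmax all return
  well-defined empty/zero results rather than erroring.
- `fold_change()` refuses a zero denominator; `concordance()` refuses
  unknown class labels, naming them.

## Problem sizes

The shipped tests run the full pipeline at the default study scale (300
probands, ~24,000 generated variants, all four tools) for the
parameter-recovery and order-of-magnitude checks, and smaller cohorts
(2–60 probands) for structural, oracle, and round-trip properties; the
complete suite finishes in about a minute on one core. Oracle comparisons
use 10,000 uniformly sampled scores per tool and full binomial enumeration
up to n = 50.

## Known limitations

- The threshold YAML is a transcription of published calibration values;
  users applying other predictor versions must supply their own table (any
  tool with a valid table is accepted).
- The AR/AD comparison assumes observations are independent under the
  null; recurrent variants in real cohorts mildly violate this.
- Concordance requires a pre-built classification snapshot; no versioning
  or download logic is included.
- The package counts evidence; it does not classify variants end-to-end
  and must not be read as automating curation.
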