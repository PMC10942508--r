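# Calibrated PP3/BP4 evidence-strength thresholds for missense metapredictors.
#
# Values transcribed from the interval calibration of Pejaver et al. (2022),
# "Calibration of computational tools for missense variant pathogenicity
# classification and ClinGen recommendations for PP3/BP4 criteria",
# Am J Hum Genet 109(12):2163-2177 (Table 2 point thresholds).
#
# Convention (documented, auditable): a score equal to a breakpoint takes the
# stronger evidence, i.e. pathogenic categories use score >= breakpoint and
# benign categories use score <= breakpoint. Pathogenic breakpoints are
# ordered Supporting < Moderate < Strong; benign breakpoints Supporting >
# Moderate > Strong > VeryStrong. Strengths a tool cannot reach are omitted.
#
# All four tools are oriented higher-is-deleterious. BayesDel is the
# no-allele-frequency variant of the score and is signed; the other three
# live on the unit interval.
tools:
  BayesDel:
    source: "Pejaver et al. 2022, AJHG 109:2163-2177 (BayesDel_noAF)"
    direction: higher_is_deleterious
    score_range: [-1.30, 0.76]
    pathogenic:
      Supporting: 0.13
      Moderate: 0.27
      Strong: 0.50
    benign:
      Supporting: -0.18
      Moderate: -0.36
  MutPred2:
    source: "Pejaver et al. 2022, AJHG 109:2163-2177"
    direction: higher_is_deleterious
    score_range: [0.0, 1.0]
    pathogenic:
      Supporting: 0.737
      Moderate: 0.829
      Strong: 0.932
    benign:
      Supporting: 0.391
      Moderate: 0.197
      Strong: 0.031
  REVEL:
    source: "Pejaver et al. 2022, AJHG 109:2163-2177"
    direction: higher_is_deleterious
    score_range: [0.0, 1.0]
    pathogenic:
      Supporting: 0.644
      Moderate: 0.773
      Strong: 0.932
    benign:
      Supporting: 0.290
      Moderate: 0.183
      Strong: 0.016
      VeryStrong: 0.003
  VEST4:
    source: "Pejaver et al. 2022, AJHG 109:2163-2177"
    direction: higher_is_deleterious
    score_range: [0.0, 1.0]
    pathogenic:
      Supporting: 0.449
      Moderate: 0.764
      Strong: 0.861
    benign:
      Supporting: 0.302
      Moderate: 0.149
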