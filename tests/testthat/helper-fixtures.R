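# shared fixtures: a toy threshold table and an inline VCF writer

toy_table <- function() {
  threshold_table("toy",
    pathogenic = c(Supporting = 0.5, Moderate = 0.7, Strong = 0.9),
    benign = c(Supporting = 0.3, Moderate = 0.1),
    score_range = c(0, 1)
  )
}

# write a small single-sample VCF; body rows are given as ready-made
# tab-joined variant lines (CHROM..INFO FORMAT SAMPLE)
write_test_vcf <- function(body, path = tempfile(fileext = ".vcf"),
                           sample = "S1",
                           csq_format = "Consequence|SYMBOL|Feature|MANE_SELECT") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=AF_NFE,Number=A,Type=Float,Description=\"NFE AF\">",
    "##INFO=<ID=AF_AFR,Number=A,Type=Float,Description=\"AFR AF\">",
    "##INFO=<ID=AF_FIN,Number=A,Type=Float,Description=\"FIN AF\">",
    paste0(
      "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
      "annotations from Ensembl VEP. Format: ", csq_format, "\">"
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
      "INFO", "FORMAT", sample
    ), collapse = "\t")
  )
  writeLines(c(header, body), path)
  path
}

vline <- function(chrom, pos, ref, alt, info, gt) {
  paste(chrom, pos, ".", ref, alt, "50", "PASS", info, "GT:GQ:DP:AD", gt,
    sep = "\t"
  )
}
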