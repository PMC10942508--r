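# independent brute-force oracles, deliberately written as linear scans

# strongest-first linear scan over every breakpoint of a threshold table
oracle_classify <- function(score, tt) {
  if (is.na(score)) {
    return("NoScore")
  }
  for (st in c("VeryStrong", "Strong", "Moderate", "Supporting")) {
    p <- tt$pathogenic[[st]]
    if (!is.null(p) && score >= p) {
      return(paste0("PP3_", st))
    }
  }
  for (st in c("VeryStrong", "Strong", "Moderate", "Supporting")) {
    b <- tt$benign[[st]]
    if (!is.null(b) && score <= b) {
      return(paste0("BP4_", st))
    }
  }
  "Indeterminate"
}

# exact two-tailed binomial by full outcome enumeration: sum the
# probabilities of all outcomes no more probable than the observed one
# (with the conventional relative slack for floating-point ties)
oracle_binom_two_tailed <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
}

# a minimal classified-observation table for statistics tests
make_obs <- function(calls, moi = NULL, proband = NULL, tool = "toy") {
  n <- length(calls)
  out <- tibble::tibble(
    proband_id = if (is.null(proband)) rep("P1", n) else proband,
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
    gene_symbol = paste0("G", seq_len(n))
  )
  out[[paste0("call_", tool)]] <- calls
  if (!is.null(moi)) out$moi <- moi
  out
}
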