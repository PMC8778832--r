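# Independent brute-force oracles and small fixture builders. These
# deliberately recompute definitions from first principles, without reusing
# the package's code paths.

# standard-code synonymous families, built here independently from Biostrings
oracle_families <- local({
  gc <- Biostrings::GENETIC_CODE
  fam <- split(names(gc), gc)
  fam[["*"]] <- NULL
  fam[["M"]] <- NULL
  fam[["W"]] <- NULL
  fam
})

# brute-force RSCU: per codon, count / (family total / family size)
oracle_rscu <- function(counts_dna) {
  out <- numeric(0)
  for (fam in oracle_families) {
    tot <- sum(counts_dna[fam])
    for (cd in fam)
      out[[cd]] <- if (tot == 0) NA_real_
                   else counts_dna[[cd]] / (tot / length(fam))
  }
  out
}

# brute-force codon homozygosity for one family's count vector
oracle_F <- function(cnt) {
  n <- sum(cnt)
  if (n < 2) return(NA_real_)
  p <- cnt / n
  (n * sum(p^2) - 1) / (n - 1)
}

# full Wright ENC recomputed independently (same estimator, separate code)
oracle_enc <- function(counts_dna) {
  sizes <- vapply(oracle_families, length, integer(1))
  Fs <- vapply(oracle_families, function(fam) oracle_F(counts_dna[fam]), 0)
  cls <- function(k) mean(Fs[sizes == k], na.rm = TRUE)
  f2 <- cls(2); f3 <- cls(3); f4 <- cls(4); f6 <- cls(6)
  if (is.nan(f3)) f3 <- mean(c(f2, f4))
  min(61, 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6)
}

# Spearman rho via the classic sum-of-squared-rank-differences formula
# (valid for untied data)
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# random codon-count vector over all 64 DNA codons
random_counts_dna <- function(lambda = 8) {
  all64 <- names(Biostrings::GENETIC_CODE)
  setNames(stats::rpois(64, lambda), all64)
}

# wrap a DNA count vector into the package's codon_counts container
as_codon_counts <- function(counts_dna) {
  seqstr <- paste(rep(names(counts_dna), counts_dna), collapse = "")
  count_codons(coding_sequence(seqstr, id = "synthetic"))
}

# a small in-frame CDS with start and stop, valid for every metric
demo_cds <- function(id = "demo") {
  coding_sequence(paste0("ATG", "AAACCCGGGTTTGATGACCTGCTA", "TAA"), id = id)
}
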