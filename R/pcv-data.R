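# Bundled reference data: published RSCU profiles of porcine circovirus
# ORF12 coding sequences and their swine host.

#' Published PCV ORF12 RSCU profiles and the Sus scrofa reference
#'
#' Per-codon RSCU values (59 degenerate-family codons, two-decimal precision)
#' for the pooled ORF1-ORF2 coding sequences of the four porcine circovirus
#' species circulating in Chinese swine herds (PCV-1 to PCV-4) together with
#' the host (*Sus scrofa*) reference column, as published for this dataset.
#' These columns drive the codon-classification worked examples: preferred,
#' over-represented (RSCU > 1.6) and under-represented (RSCU < 0.6) codons
#' per species, and the preferred codons each virus shares with its host.
#'
#' @return data.frame with columns `aa`, `codon` (RNA alphabet) and RSCU
#'   columns `PCV1`, `PCV2`, `PCV3`, `PCV4`, `Sus_scrofa`, 59 rows.
#' @examples
#' tab <- pcv_rscu_profiles()
#' classify_rscu(setNames(tab$PCV1, tab$codon))
#' @export
pcv_rscu_profiles <- function() {
  path <- system.file("extdata", "pcv_orf12_rscu.tsv",
                      package = "codonusage", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Host reference usage table from the bundled Sus scrofa RSCU column
#'
#' Convenience wrapper building a [reference_table()] (units `"rscu"`) from
#' the *Sus scrofa* column of [pcv_rscu_profiles()], suitable for CAI and for
#' preferred-codon tie-breaking.
#'
#' @inheritParams reference_table
#' @return a `ref_usage` data.frame.
#' @export
sus_scrofa_reference <- function(zero_w = 0.01) {
  tab <- pcv_rscu_profiles()
  reference_table(setNames(tab$Sus_scrofa, tab$codon), units = "rscu",
                  zero_w = zero_w)
}
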