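Package: codonusage
Title: Codon Usage Bias Analysis for Viral Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synonymous codon usage bias analysis of coding
    sequences, built around the workflow used to study virus-host codon
    adaptation: nucleotide composition summaries, relative synonymous codon
    usage (RSCU) with preferred/over-/under-represented codon classification,
    Wright's effective number of codons (ENC) and the ENC-GC3s expected
    curve, the codon adaptation index (CAI) against a host reference usage
    table, parity rule 2 (PR2) bias coordinates, neutrality-plot regression
    of GC12 on GC3 with a mutation-pressure versus natural-selection
    contribution split, principal component analysis of RSCU vectors,
    Spearman correlation matrices and nonparametric group comparisons.
    Includes a synthetic coding-sequence generator with controllable codon
    usage structure so the full pipeline can be exercised without external
    data, and a single-call pipeline that writes all tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    graphics,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
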