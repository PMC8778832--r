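---
title: "Methods: codon usage bias statistics and their simulation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias statistics and their simulation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonusage)
```

## Scope and model

`codonusage` implements the analysis workflow used to characterize
synonymous codon usage bias in small viral genomes and its relationship to
the host — here shaped around porcine circoviruses (PCV-1 to PCV-4), whose
two major open reading frames (ORF1, replicase; ORF2, capsid) are
concatenated into a single ORF12 coding unit per strain. All statistics use
the standard nuclear genetic code, with Leu, Ser and Arg treated as single
six-codon families (the CodonW convention). That yields 18 degenerate
synonymous families over 59 codons once Met, Trp and stops are excluded;
every RSCU vector in the package lives in this fixed 59-dimensional space,
ordered by amino acid (Phe..Gly) and alphabetically within family so that
loadings and tables are comparable across runs.

The analysis decomposes into:

* **Composition** — whole-CDS nucleotide percentages; third-position
  percentages computed over synonymous codons only (A3s..G3s, which then sum
  to 100); positional GC1/GC2/GC3 over all codons; GC12 = (GC1+GC2)/2; and
  both GC3 variants (all-codon GC3 and synonymous-only GC3s).
* **RSCU** — `RSCU(c) = count(c) * n / N` for a family of `n` codons with
  total `N`; preferred = family argmax, over-represented strictly > 1.6,
  under-represented strictly < 0.6.
* **ENC** — Wright's estimator from per-family codon homozygosity
  `F = (n * sum(p^2) - 1) / (n - 1)`, averaged within the 2-/3-/4-/6-fold
  degeneracy classes, `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at 61.
  The expected curve under pure compositional pressure is
  `2 + s + 29/(s^2 + (1 - s)^2)` with `s` = GC3s.
* **CAI** — Sharp–Li geometric mean of relative-adaptiveness weights
  `w = RSCU/RSCU_max` from a host reference table.
* **PR2** — `A3/(A3+U3)` against `G3/(G3+C3)`, center (0.5, 0.5).
* **Neutrality plot** — OLS of GC12 on GC3; the slope magnitude is read as
  the mutation-pressure share, `(1 - min(|slope|, 1)) * 100` being the
  natural-selection contribution in percent.
* **PCA** of RSCU vectors; **Spearman** correlation screens; pairwise
  **Mann–Whitney** comparison of CAI across species with a compact letter
  display.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| RSCU over/under thresholds | 1.6 / 0.6 (strict) | RSCU | the conventional cutoffs for over-/under-representation; boundary values excluded |
| zero-usage reference weight | 0.01 | relative adaptiveness | keeps the CAI log-mean defined when a host table lacks a codon; configurable in `reference_table()` |
| outlier rule (neutrality) | Tukey 1.5 IQR, per margin | — | robust, assumption-light screen; `"sd3"` and `"none"` selectable, removals always reported |
| neutrality regression | OLS of GC12 on GC3 | — | the regression the field draws on neutrality plots; reduced major axis available as `method = "rma"` since both axes are measured |
| CAI comparison alpha | 0.05, unadjusted | — | pairwise Mann–Whitney p-values are reported raw; Benjamini–Hochberg available via `adjust = "BH"` |
| PCA preprocessing | center only, no scaling | — | RSCU values already share a common scale; scaling is a flag, not the default |
| ENC short-sequence warning | < 100 codons | codons | Wright's estimator is noisy for short CDS |

Open choices resolved as package policy:

* **Which GC3 feeds which plot.** Third-position *synonymous* frequencies
  (A3s..G3s, GC3s) drive PR2 and the ENC-plot abscissa; the *all-codon*
  GC3 and GC12 drive the neutrality regression. Both are always emitted and
  the neutrality choice is a config flag (`gc3 = "all"`/`"synonymous"`).
* **Preferred-codon ties.** At two-decimal table precision ties occur (e.g.
  a two-fold family at 1.00/1.00). With a host reference supplied the tie
  breaks toward the codon the host prefers; otherwise alphabetically. This
  keeps published preferred-codon listings reproducible from their rounded
  RSCU tables.
* **Correlation type on the neutrality plot.** Both Pearson and Spearman
  are computed and reported side by side.
* **ENC missing classes.** Families with fewer than 2 observed codons are
  excluded from class means; an empty Ile class mean is replaced by the
  average of the 2- and 4-fold means; any other empty class is an error
  naming the class. The value is capped at 61.
* **Expected-ENC formula.** Implemented in Wright's standard form
  `2 + s + 29/(s^2 + (1-s)^2)`; renderings of this curve that drop the
  division are typographic artifacts.
* **Degenerate inputs.** A CDS with no synonymous codon yields flagged `NA`
  third-position summaries; PR2 denominators of zero yield flagged `NA`
  coordinates, never silent zeros; constant GC3 makes the neutrality
  regression an error rather than a meaningless fit.

## The synthetic-data generator

The real study data are GenBank sequences; the package instead ships a
generator so that every stage is exercised by construction:

* `usage_spec()` / `biased_usage()` fix per-family codon probability
  vectors. `biased_usage()` draws them from a Dirichlet whose mean places
  total mass `gc3_target` on each family's G/C-ending codons, so the
  expected synonymous GC3 equals the target for any amino-acid composition;
  `concentration` controls how far individual families stray from that mean.
* `generate_cds_set()` samples amino acids i.i.d. from the composition
  vector and codons from the family vectors — an exchangeable-codon model.
* `generate_neutrality_set()` realizes a prescribed linear GC12–GC3
  relationship. Rather than greedy search with rejection, each sequence is
  assembled from two amino acids picked for their codon-position GC content:
  Ala (GCN — positions 1 and 2 fully G/C, third free) and Lys (AAR —
  positions 1 and 2 fully A/T, third free). The Ala fraction equals the
  target GC12 and the G/C third-position fraction the target GC3, each
  matched by rounding to within `1/(2L)` for `L` codons — exact by
  construction, with no retry loop.

All generators run on a private seeded RNG stream and never touch the
caller's `.Random.seed`; identical seeds give byte-identical FASTA output.

What the generator emulates: controllable per-family codon probabilities,
controllable GC3, a linear GC12–GC3 law with Gaussian noise, and
multi-population mixtures with distinct usage profiles. What it does not
emulate: phylogenetic correlation between sequences, recombination,
substitution processes, amino-acid composition drift along a genome, or
length variation. Tests passing on generated data therefore validate the
statistics and their implementation, not any claim about real viral
evolution — with i.i.d. sequences, for instance, regression standard errors
are honest, which is not guaranteed for phylogenetically dependent strains.

Default study conditions used by the test-bench scenarios: neutrality
recovery uses `GC12 = 0.2 + 0.3 GC3 + N(0, 0.005)` over `GC3 ~ U(0.3, 0.7)`
with n = 500 sequences of 300 codons; GC3-tilt recovery targets 0.9 with
concentration 100 over 40 x 500-codon sequences; the two-population PCA
scenario opposes GC3 targets 0.85 and 0.15 at concentration 200. These
sizes make the sampling error comfortably smaller than the assertion bands
while keeping the whole suite in seconds.

## Bundled reference table

`pcv_rscu_profiles()` returns the published pooled ORF12 RSCU columns for
the four PCV species and the *Sus scrofa* host reference at their printed
two-decimal precision. They serve as worked-example inputs for the
classification operations (preferred / over- / under-represented codons,
host-shared preferred codons) and, via `sus_scrofa_reference()`, as a CAI
reference. Because the values are rounded to two decimals, quantities
derived from them inherit that precision — which is exactly why the
preferred-codon tie rule above exists.

## Numerical notes

* RSCU, CAI and PR2 are ratio statistics: exactly invariant to scaling all
  counts. ENC is invariant only asymptotically (its `F` depends on the
  family totals `n`), which the tests assert as a drift bound rather than
  equality.
* CAI is computed in log space and exponentiated once, avoiding underflow
  on long genes.
* The PCA sign convention (largest-magnitude loading of each component made
  positive) removes the eigenvector sign ambiguity so scores are
  reproducible across BLAS implementations.
* The compact letter display uses insert-and-absorb over the pairwise
  significance graph, processing groups in decreasing-mean order; an
  untestable pair (NA p-value) is treated as not-significant rather than
  propagating NA.

## Limitations

* Only the standard nuclear genetic code is supported.
* Six-fold families are never split into their 2+4 sub-families; tools that
  split them will give slightly different ENC and RSCU groupings.
* The selection/mutation "contribution" split is the conventional reading
  of the neutrality-plot slope, not a causal estimate; no dN/dS or
  phylogenetic selection test is attempted.
* Recombination screening and ORF extraction from circular genomes are out
  of scope; the pipeline starts from in-frame CDS records.
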