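# codonusage

Synonymous codon usage bias analysis for viral coding sequences, written for
molecular virologists and molecular-evolution researchers who want the
classic virus–host codon-adaptation workflow — the one routinely applied to
small DNA viruses such as the porcine circoviruses (PCV-1…PCV-4) and their
swine host — as reproducible, scriptable R functions instead of a chain of
separate desktop tools.

Given in-frame CDS records (e.g. concatenated ORF1–ORF2 units of circovirus
strains) the package computes:

* **Composition**: A/C/U/G%, synonymous third-position A3s…G3s%,
  GC1/GC2/GC3, GC12 = (GC1+GC2)/2, GC3s.
* **RSCU**: RSCU(c) = x_c / (N_aa / n_aa) — the observed count over the
  count expected under uniform synonymous use; preferred codons (family
  argmax), over-represented (RSCU > 1.6) and under-represented (RSCU < 0.6)
  sets, and preferred codons shared with a host.
* **ENC** (Wright): per-family homozygosity F̂ = (nΣp̂² − 1)/(n − 1),
  ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆ ∈ [20, 61], and the expected curve
  ENC(s) = 2 + s + 29/(s² + (1−s)²) for the ENC–GC3s plot.
* **CAI** (Sharp–Li): exp(Σ x_c ln w_c / Σ x_c) with w = RSCU/RSCU_max from
  a host reference usage table (e.g. *Sus scrofa*).
* **PR2**: A3/(A3+U3) vs G3/(G3+C3) parity coordinates.
* **Neutrality plot**: OLS of GC12 on GC3 with outlier screening; the slope
  splits into mutation-pressure share |b|·100% and natural-selection share
  (1 − min(|b|, 1))·100%.
* **PCA** of 59-dimensional RSCU vectors, Spearman correlation matrices,
  and pairwise Mann–Whitney comparison of CAI across species with a compact
  letter display.

A synthetic coding-sequence generator (`usage_spec()`, `biased_usage()`,
`generate_cds_set()`, `generate_neutrality_set()`, `simulate_preset()`)
produces sequence sets with controllable codon-usage structure, so the whole
pipeline runs and is tested without any external data. The bundled
`pcv_rscu_profiles()` table carries published pooled ORF12 RSCU values for
the four PCV species plus the *Sus scrofa* host column.

## Worked example

Classify the published PCV-4 RSCU column against its host, then analyze a
simulated two-population sequence set end to end:

```r
library(codonusage)

tab <- pcv_rscu_profiles()           # 59 codons x {PCV1..PCV4, Sus_scrofa}
ref <- sus_scrofa_reference()        # host reference with CAI weights

classify_rscu(setNames(tab$PCV4, tab$codon), reference = ref)
#> <rscu_classification>
#>  preferred (18): UUC CUG AUC GUG AGC CCC ACU GCC UAU CAC CAG AAC AAG GAC GAG UGU AGA GGA
#>  over-represented (4): CUG GUG AGC AGA
#>  under-represented (13): CUA UUA GUA GUU UCA UCG CCU ACG GCA UGC CGA CGU GGU
```

PCV-4 uses 4 over-represented and 13 under-represented codons, and 13 of its
18 preferred codons are also preferred by the host — the strongest host
overlap of the four species, the usual reading being better adaptation to
the swine translational machinery.

```r
seqs <- simulate_preset("two-pop", seed = 1, n_seq = 10, length_codons = 300)
m <- codon_metrics(seqs, ref = ref)  # per-sequence composition, ENC, CAI, ...
round(head(m[, c("GC3", "GC12", "GC3s", "ENC", "CAI")], 3), 3)
#>      GC3   GC12   GC3s    ENC   CAI
#> 1 85.430 45.530 85.667 38.730 0.795
#> 2 82.119 44.205 82.333 41.795 0.799
#> 3 84.768 47.020 85.000 42.658 0.810

neutrality_fit(m$GC12, m$GC3, outliers = "none")
#> Neutrality plot regression: GC12 ~ GC3 (ols)
#>   slope 0.0136, intercept 44.4352  (n = 20 used, 0 removed as outliers)
#>   Pearson r = 0.2357 (p = 0.317); Spearman rho = 0.2236 (p = 0.343)
#>   natural selection 98.64% vs mutation pressure 1.36%

pca_rscu(rscu_matrix(seqs))
#> <rscu_pca> 20 observations, 2 components retained
#>   variance explained: PC1 76.89%, PC2 3.66%
```

The near-zero neutrality slope is expected here: the generator draws first
and second codon positions independently of the third, so almost all GC12
variation is decoupled from GC3 and the decomposition attributes ~99% to
"selection". PC1 cleanly separates the two simulated populations (their
GC3 targets are 0.85 vs 0.15), mirroring the species clusters seen in real
RSCU ordinations.

`run_pipeline(run_config(...))` writes every table (composition, RSCU,
classification, PR2, neutrality, correlations, PCA, CAI comparison) as TSV
plus a checksummed manifest, and `write_report()` renders a summary; the
same pipeline is reachable from a shell via `exec/codonusage`
(`analyze`, `simulate`, `rscu`, `enc`, `cai`, `pr2`, `neutrality`, `pca`,
`report`).

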