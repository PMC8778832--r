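test_that("count_codons tallies frame-0 triplets with RNA names", {
  cc <- count_codons("ATGAAACCCGGG")
  expect_s3_class(cc, "codon_counts")
  expect_equal(attr(cc, "total"), 4L)
  expect_equal(unname(cc[c("AUG", "AAA", "CCC", "GGG")]), rep(1L, 4))
  expect_equal(sum(cc), 4L)
  expect_equal(unname(count_codons("AAAAAA")["AAA"]), 2L)
  pooled <- pool_counts(list(count_codons("AAAAAA"), count_codons("AAATTT")))
  expect_equal(unname(pooled["AAA"]), 3L)
  expect_equal(attr(pooled, "total"), 4L)
})

test_that("composition_summary computes positional and synonymous fractions", {
  comp <- composition_summary("AAATTT")  # Lys + Phe, both synonymous
  expect_equal(comp$A, 50)
  expect_equal(comp$U, 50)
  expect_equal(comp$GC3, 0)
  expect_equal(comp$GC12, 0)
  expect_equal(comp$A3s, 50)
  expect_equal(comp$U3s, 50)

  gcc <- composition_summary(strrep("GGGCCC", 5))
  expect_equal(gcc$GC, 100)
  expect_equal(gcc$A, 0)

  # whole-CDS and synonymous third-position percentages each sum to 100
  set.seed(11)
  seqs <- generate_cds_set(usage_spec(n_seq = 5, length_codons = 80, seed = 2))
  for (s in seqs) {
    cp <- composition_summary(s)
    expect_equal(cp$A + cp$C + cp$U + cp$G, 100)
    expect_equal(cp$A3s + cp$C3s + cp$U3s + cp$G3s, 100)
    expect_equal(cp$GC12, (cp$GC1 + cp$GC2) / 2)
  }

  # degenerate input: only Met/Trp codons -> synonymous fields undefined
  deg <- composition_summary("ATGTGGATGTGG")
  expect_true(attr(deg, "degenerate"))
  expect_true(is.na(deg$A3s) && is.na(deg$GC3s))
  expect_false(is.na(deg$GC3))  # all-codon variant still defined
})

test_that("rscu matches definition, brute force, and an external oracle", {
  # 2-fold family, no bias
  cc <- count_codons(strrep("GATGAC", 10))
  prof <- rscu_profile(cc)
  expect_equal(prof$rscu[prof$codon %in% c("GAU", "GAC")], c(1, 1))

  # 4-fold family fully concentrated
  cc4 <- count_codons(strrep("CCT", 8))
  prof4 <- rscu_profile(cc4)
  expect_equal(prof4$rscu[prof4$aa == "P"], c(0, 0, 0, 4))  # CCA CCC CCG CCU order
  expect_equal(prof4$rscu[prof4$codon == "CCU"], 4)

  # random counts: equals brute-force recomputation and seqinr's uco
  set.seed(301)
  for (rep in 1:5) {
    counts_dna <- random_counts_dna()
    cc <- as_codon_counts(counts_dna)
    prof <- rscu_profile(cc)
    oracle <- oracle_rscu(counts_dna)
    got <- setNames(prof$rscu, dna_codon(prof$codon))
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-12)
    # family sums equal degeneracy; family means equal 1
    for (a in unique(prof$aa)) {
      fam <- prof[prof$aa == a, ]
      if (all(is.na(fam$rscu))) next
      expect_equal(sum(fam$rscu), fam$family_size[1])
      expect_equal(mean(fam$rscu), 1)
    }
  }
  seqstr <- paste(rep(names(random_counts_dna()), random_counts_dna()),
                  collapse = "")
  sq <- seqinr::s2c(tolower(seqstr))
  uco_rscu <- seqinr::uco(sq, index = "rscu")
  prof <- rscu_profile(coding_sequence(seqstr))
  got <- setNames(prof$rscu, tolower(dna_codon(prof$codon)))
  common <- intersect(names(got), names(uco_rscu))
  expect_equal(got[common], uco_rscu[common], tolerance = 1e-12)
})

test_that("classify_rscu applies strict thresholds and tie rules", {
  v <- setNames(rep(1, 59), pcv_rscu_profiles()$codon)
  v[c("UUU", "UUC")] <- c(1.6, 0.4)  # boundary over not included
  v[c("GAU", "GAC")] <- c(0.6, 1.4)  # boundary under not included
  cl <- classify_rscu(v)
  expect_false("UUU" %in% cl$over_represented)
  expect_false("GAU" %in% cl$under_represented)
  expect_true("UUC" %in% cl$under_represented)

  # uniform profile: nothing over/under; ties broken lexicographically
  u <- setNames(rep(1, 59), pcv_rscu_profiles()$codon)
  clu <- classify_rscu(u)
  expect_length(clu$over_represented, 0)
  expect_length(clu$under_represented, 0)
  expect_length(clu$preferred, 18)
  expect_equal(clu$preferred[1], "UUC")  # Phe family, alphabetical first

  # reference tie-break: host prefers GAC over GAU
  tie <- u
  ref <- sus_scrofa_reference()
  cl_ref <- classify_rscu(tie, reference = ref)
  expect_true("GAC" %in% cl_ref$preferred)
  expect_false("GAU" %in% cl_ref$preferred)
})

test_that("shared_preferred intersects preferred sets", {
  tab <- pcv_rscu_profiles()
  p3 <- setNames(tab$PCV3, tab$codon)
  host <- setNames(tab$Sus_scrofa, tab$codon)
  expect_setequal(shared_preferred(p3, host),
                  c("AGC", "ACC", "CAC", "AAC", "GAG"))
  expect_length(shared_preferred(host, host), 18)
  a <- setNames(rep(1, 59), tab$codon); a[tab$codon == "UUU"] <- 2
  b <- setNames(rep(1, 59), tab$codon); b[tab$codon == "UUC"] <- 2
  # opposite Phe preference; remaining uniform families tie-break identically
  expect_false("UUU" %in% shared_preferred(b, b))
  expect_length(intersect(shared_preferred(a, a), shared_preferred(b, b)), 17)
})

test_that("enc hits analytic extremes and matches a brute-force recomputation", {
  one_per_family <- pool_counts(simulate_preset("maxbias", seed = 4, n_seq = 3,
                                                length_codons = 300))
  expect_equal(enc(one_per_family)$enc, 20)

  # exactly uniform counts within every family (large): raw value above the
  # cap, reported as 61
  exact_uniform <- as_codon_counts(
    setNames(rep(120L, 64), names(Biostrings::GENETIC_CODE)))
  expect_equal(enc(exact_uniform)$enc, 61)

  # 600-codon synthetic CDS: ENC equals the independent oracle to 1e-9
  set.seed(77)
  spec <- biased_usage(0.6, concentration = 5, n_seq = 1,
                       length_codons = 600, seed = 13)
  s <- generate_cds_set(spec, add_start = FALSE, add_stop = FALSE)[[1]]
  cc <- count_codons(s)
  counts_dna <- setNames(as.integer(cc), dna_codon(names(cc)))
  expect_equal(enc(cc)$enc, oracle_enc(counts_dna), tolerance = 1e-9)

  # scaling counts: p unchanged, F drifts only via n -> ENC nearly invariant
  c10 <- as_codon_counts(counts_dna * 10L)
  c100 <- as_codon_counts(counts_dna * 100L)
  expect_lt(abs(enc(c10)$enc - enc(c100)$enc), 0.5)

  expect_error(enc(count_codons("GCAGCTGCC"), warn_short = FALSE), "class")
  expect_warning(
    enc(count_codons(strrep("AAATTTATTCCTCTTTCTCGTGTTGAAGGTCATCAATAT", 2))),
    "100")
})

test_that("per-family homozygosity matches exhaustive brute force on small families", {
  # all count vectors over a 4-codon family with totals <= 12
  set.seed(5)
  for (rep in 1:50) {
    cnt <- as.vector(stats::rmultinom(1, sample(2:12, 1), rep(0.25, 4)))
    n <- sum(cnt); p <- cnt / n
    f_impl <- (n * sum(p^2) - 1) / (n - 1)
    expect_equal(f_impl, oracle_F(cnt), tolerance = 1e-12)
  }
  # embed a known family in a full counts vector and recover its F via enc()
  counts_dna <- setNames(rep(2L, 64), names(Biostrings::GENETIC_CODE))
  counts_dna[c("GTA", "GTC", "GTG", "GTT")] <- c(5L, 1L, 1L, 1L)
  e <- enc(as_codon_counts(counts_dna), warn_short = FALSE)
  expect_equal(e$f_means[["4"]],
               mean(c(oracle_F(c(5, 1, 1, 1)), rep(oracle_F(rep(2, 4)), 4))),
               tolerance = 1e-12)
})

test_that("expected_enc follows Wright's closed form", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  for (s in c(0.2, 0.8))
    expect_equal(expected_enc(s), expected_enc(1 - s) + (2 * s - 1))
  expect_error(expected_enc(1.2), "0, 1")
})

test_that("cai is the geometric mean of reference weights", {
  ref <- reference_table(c(GAT = 75, GAC = 25, TTT = 50, TTC = 50),
                         units = "count")
  # only optimal codons used -> CAI = 1 (UUU/UUC tie both at w = 1)
  expect_equal(cai(count_codons(strrep("GAT", 10)), ref)$cai, 1)
  # two codons with w = 1 and w = 1/4 used equally -> sqrt(1 * 0.25) = 0.5
  ref2 <- reference_table(c(GAT = 80, GAC = 20), units = "count")
  expect_equal(unname(ref2$w[ref2$codon == "GAC"]), 0.25)
  expect_equal(cai(count_codons(strrep("GATGAC", 6)), ref2)$cai, 0.5)
  # count-scaling invariance (exact)
  cc1 <- count_codons("GATGACGATGAT")
  cc3 <- count_codons(strrep("GATGACGATGAT", 3))
  expect_equal(cai(cc1, ref2)$cai, cai(cc3, ref2)$cai)
  # monotone: recoding to a higher-w codon never decreases CAI
  lower <- cai(count_codons("GACGACGAT"), ref2)$cai
  higher <- cai(count_codons("GATGACGAT"), ref2)$cai
  expect_gt(higher, lower)
  # Met/Trp/stops carry no signal
  expect_equal(cai(count_codons("ATGGATTGGTAA"), ref2)$cai,
               cai(count_codons("GAT"), ref2)$cai)
  expect_error(cai(count_codons("ATGTGG"), ref2), "scorable")
})

test_that("gravy and aroma depend only on the translation", {
  expect_equal(gravy(strrep("ATT", 10)), 4.5)    # poly-Ile
  expect_equal(gravy(strrep("CGT", 10)), -4.5)   # poly-Arg
  expect_equal(gravy(strrep("ATTCGT", 5)), 0)
  expect_equal(aroma(strrep("TTT", 8)), 1)       # poly-Phe
  expect_equal(aroma(strrep("AAA", 8)), 0)
  expect_equal(aroma(paste0("TAT", strrep("AAA", 9))), 0.1)
  expect_error(gravy("ATGTAAAAATAA"), "internal stop")

  # synonymous recoding leaves both fixed
  set.seed(21)
  fams <- codon_families()
  aa_seq <- sample(names(fams), 60, replace = TRUE)
  recode <- function() paste(vapply(aa_seq, function(a)
    dna_codon(sample(fams[[a]], 1)), ""), collapse = "")
  s1 <- recode(); s2 <- recode()
  expect_equal(gravy(s1), gravy(s2))
  expect_equal(aroma(s1), aroma(s2))
})

test_that("codon_metrics assembles the per-sequence table", {
  seqs <- simulate_preset("uniform", seed = 8, n_seq = 6, length_codons = 200)
  ref <- sus_scrofa_reference()
  m <- codon_metrics(seqs, ref = ref)
  expect_equal(nrow(m), 6)
  expect_true(all(c("id", "group", "A", "GC12", "GC3s", "ENC", "CAI",
                    "Gravy", "Aroma") %in% names(m)))
  expect_true(all(m$ENC > 20 & m$ENC <= 61))
  expect_true(all(m$CAI > 0 & m$CAI <= 1))
})
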