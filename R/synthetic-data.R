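# Synthetic coding-sequence generation with controlled codon-usage structure:
# per-family codon probabilities (optionally Dirichlet-tilted toward a target
# GC3), amino-acid composition, and GC12~GC3 neutrality scenarios. Every
# generator runs on a private RNG stream seeded explicitly; the caller's
# random state is never touched.

#' Construct a codon-usage specification
#'
#' A `usage_spec` fixes everything needed to simulate a population of coding
#' sequences: per-amino-acid codon probability vectors, the amino-acid
#' composition, sequence length, number of sequences, a population label and
#' a seed.
#'
#' @param codon_probs named list (one element per amino acid, one-letter
#'   names) of named probability vectors over that family's codons (RNA or
#'   DNA names); each must sum to 1 within 1e-12. Defaults to uniform within
#'   every family.
#' @param aa_freq named probability vector over the 18 degenerate-family
#'   amino acids (default uniform); must sum to 1 within 1e-12. A subset may
#'   be given; omitted amino acids get frequency 0.
#' @param length_codons codons per sequence (excluding start/stop).
#' @param n_seq number of sequences.
#' @param label population label, used as group and id prefix.
#' @param seed integer seed (or `NULL` for the current RNG stream).
#' @return object of class `usage_spec`.
#' @export
usage_spec <- function(codon_probs = NULL, aa_freq = NULL,
                       length_codons = 500L, n_seq = 10L,
                       label = "pop1", seed = NULL) {
  fams <- codon_families()
  if (is.null(codon_probs))
    codon_probs <- lapply(fams, function(cc)
      setNames(rep(1 / length(cc), length(cc)), cc))
  stopifnot(all(names(codon_probs) %in% names(fams)))
  codon_probs <- lapply(names(codon_probs), function(a) {
    p <- codon_probs[[a]]
    names(p) <- rna_codon(toupper(names(p)))
    stopifnot(setequal(names(p), fams[[a]]), all(p >= 0))
    if (abs(sum(p) - 1) > 1e-12)
      stop("codon probabilities for ", a, " do not sum to 1", call. = FALSE)
    p[fams[[a]]]
  }) |> setNames(names(codon_probs))
  if (is.null(aa_freq))
    aa_freq <- setNames(rep(1 / length(codon_probs), length(codon_probs)),
                        names(codon_probs))
  stopifnot(all(names(aa_freq) %in% names(codon_probs)), all(aa_freq >= 0))
  if (abs(sum(aa_freq) - 1) > 1e-12)
    stop("amino-acid frequencies do not sum to 1", call. = FALSE)
  # amino acids left out of the composition get frequency 0
  full <- setNames(numeric(length(codon_probs)), names(codon_probs))
  full[names(aa_freq)] <- aa_freq
  aa_freq <- full
  stopifnot(length_codons >= 1, n_seq >= 1)
  structure(list(codon_probs = codon_probs, aa_freq = aa_freq,
                 length_codons = as.integer(length_codons),
                 n_seq = as.integer(n_seq), label = as.character(label),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "usage_spec")
}

#' @export
print.usage_spec <- function(x, ...) {
  cat(sprintf("<usage_spec> '%s': %d sequences x %d codons, seed %s\n",
              x$label, x$n_seq, x$length_codons,
              if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

# one Dirichlet draw with parameter alpha (gamma construction)
.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Random usage specification tilted toward a target GC3
#'
#' Draws per-family codon probability vectors from a Dirichlet whose mean
#' puts total mass `gc3_target` on the G/C-ending codons of each family
#' (shared equally within the G/C and A/U subsets), so the expected
#' synonymous GC3 of generated sequences equals `gc3_target`. `concentration`
#' scales the Dirichlet parameter: large values give vectors close to the
#' mean (low between-family variability), small values give strongly
#' idiosyncratic families. A family lacking either G/C- or A/U-ending codons
#' would make the tilt infeasible and is left at its uniform mean (none exist
#' under the standard code, but the guard is kept for safety).
#'
#' @param gc3_target target synonymous GC3, strictly between 0 and 1.
#' @param concentration positive Dirichlet concentration multiplier.
#' @param seed integer seed; the same seed gives an identical spec.
#' @inheritParams usage_spec
#' @return a `usage_spec`.
#' @export
biased_usage <- function(gc3_target, concentration = 50, n_seq = 10L,
                         length_codons = 500L, aa_freq = NULL,
                         label = "pop1", seed = NULL) {
  stopifnot(gc3_target > 0, gc3_target < 1, concentration > 0)
  fams <- codon_families()
  probs <- with_seed(seed, {
    lapply(fams, function(cc) {
      third <- substring(cc, 3L, 3L)
      gcc <- third %in% c("G", "C")
      mean_p <- if (!any(gcc) || all(gcc)) {
        message("family ", .CODE[[dna_codon(cc[1])]],
                " cannot be tilted; left uniform")
        rep(1 / length(cc), length(cc))
      } else {
        ifelse(gcc, gc3_target / sum(gcc), (1 - gc3_target) / sum(!gcc))
      }
      setNames(.rdirichlet1(concentration * mean_p), cc)
    })
  })
  usage_spec(codon_probs = probs, aa_freq = aa_freq,
             length_codons = length_codons, n_seq = n_seq,
             label = label, seed = seed)
}

#' Generate a set of coding sequences from a usage specification
#'
#' Amino acids are drawn i.i.d. from the spec's composition vector and each
#' residue's codon from that amino acid's probability vector. By default a
#' start codon (AUG) and a stop (UAA) are attached so the sequences
#' round-trip through [read_fasta()]/[concatenate_orf12()]-style tooling.
#' Output is deterministic given the spec's seed.
#'
#' @param spec a `usage_spec`.
#' @param add_start,add_stop attach ATG / TAA (defaults `TRUE`).
#' @return a `cds_set`; ids are `<label>_<i>`, group is the spec label.
#' @export
generate_cds_set <- function(spec, add_start = TRUE, add_stop = TRUE) {
  stopifnot(inherits(spec, "usage_spec"))
  aas <- names(spec$aa_freq)
  with_seed(if (is.null(spec$seed)) NULL else spec$seed + 1L, {
    total <- spec$n_seq * spec$length_codons
    aa_draw <- sample(aas, total, replace = TRUE, prob = spec$aa_freq)
    codon_draw <- character(total)
    for (a in unique(aa_draw)) {
      idx <- which(aa_draw == a)
      p <- spec$codon_probs[[a]]
      codon_draw[idx] <- sample(names(p), length(idx), replace = TRUE,
                                prob = p)
    }
    codon_draw <- dna_codon(codon_draw)
    out <- vector("list", spec$n_seq)
    for (i in seq_len(spec$n_seq)) {
      block <- codon_draw[((i - 1L) * spec$length_codons + 1L):
                            (i * spec$length_codons)]
      s <- paste0(if (add_start) "ATG" else "",
                  paste(block, collapse = ""),
                  if (add_stop) "TAA" else "")
      out[[i]] <- coding_sequence(s, id = sprintf("%s_%03d", spec$label, i),
                                  group = spec$label)
    }
    structure(out, class = "cds_set")
  })
}

#' Construct a neutrality-plot simulation scenario
#'
#' Fixes the generating linear relationship `GC12 = intercept + slope * GC3 +
#' noise` and the GC3 sampling range for [generate_neutrality_set()].
#'
#' @param slope,intercept generating coefficients (fractions).
#' @param gc3_range length-2 numeric, the uniform sampling range for GC3.
#' @param noise standard deviation of Gaussian noise added to GC12.
#' @param n number of sequences.
#' @param length_codons codons per sequence; targets are matched to within
#'   `1/(2 * length_codons)`.
#' @param seed integer seed.
#' @return object of class `neutrality_scenario`.
#' @export
neutrality_scenario <- function(slope, intercept, gc3_range = c(0.3, 0.7),
                                noise = 0.005, n = 100L,
                                length_codons = 300L, seed = NULL) {
  stopifnot(length(gc3_range) == 2, gc3_range[1] >= 0, gc3_range[2] <= 1,
            gc3_range[1] < gc3_range[2], noise >= 0, n >= 1,
            length_codons >= 50)
  gc12_ends <- intercept + slope * gc3_range
  if (any(gc12_ends < 0 | gc12_ends > 1))
    stop("intercept/slope give GC12 outside [0, 1] over the GC3 range",
         call. = FALSE)
  structure(list(slope = slope, intercept = intercept, gc3_range = gc3_range,
                 noise = noise, n = as.integer(n),
                 length_codons = as.integer(length_codons),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "neutrality_scenario")
}

#' Generate coding sequences realizing a neutrality scenario
#'
#' For each sequence a GC3 value is drawn uniformly over the scenario range
#' and a target GC12 set from the generating line plus noise. The CDS is then
#' assembled from two amino acids chosen for their codon-position GC content
#' — Ala (GCN: positions 1+2 fully G/C, third position free) and Lys (AAR:
#' positions 1+2 fully A/T, third position free) — so the realized GC12
#' equals the Ala fraction and GC3 the G/C-third-position fraction, each
#' matched to the target by rounding to within `1/(2 * length_codons)`. No
#' rejection sampling is needed. Codon order is randomized; no start/stop is
#' attached so measured composition equals the construction exactly.
#'
#' @param scn a `neutrality_scenario`.
#' @return a `cds_set` with group label `"neutrality"`.
#' @export
generate_neutrality_set <- function(scn) {
  stopifnot(inherits(scn, "neutrality_scenario"))
  L <- scn$length_codons
  with_seed(scn$seed, {
    gc3 <- stats::runif(scn$n, scn$gc3_range[1], scn$gc3_range[2])
    gc12 <- scn$intercept + scn$slope * gc3 +
      stats::rnorm(scn$n, 0, scn$noise)
    gc12 <- pmin(pmax(gc12, 0), 1)
    out <- vector("list", scn$n)
    for (i in seq_len(scn$n)) {
      n_ala <- round(gc12[i] * L)
      n_gc3 <- round(gc3[i] * L)
      aa <- sample(c(rep("A", n_ala), rep("K", L - n_ala)))
      third_gc <- logical(L)
      third_gc[sample.int(L, n_gc3)] <- TRUE
      third <- ifelse(aa == "A",
                      ifelse(third_gc,
                             sample(c("C", "G"), L, replace = TRUE),
                             sample(c("A", "T"), L, replace = TRUE)),
                      ifelse(third_gc, "G", "A"))
      codons <- ifelse(aa == "A", paste0("GC", third), paste0("AA", third))
      out[[i]] <- coding_sequence(paste(codons, collapse = ""),
                                  id = sprintf("ntr_%04d", i),
                                  group = "neutrality")
    }
    structure(out, class = "cds_set")
  })
}

#' Preset simulation scenarios
#'
#' Convenience presets exercising characteristic codon-usage structures:
#' \describe{
#'   \item{`"uniform"`}{uniform codon use within every family (ENC near the
#'     61 cap).}
#'   \item{`"maxbias"`}{exactly one codon per family (ENC = 20).}
#'   \item{`"two-pop"`}{two populations with opposed G/C- vs A/U-ending
#'     preferences, separable on PC1 of the RSCU matrix.}
#'   \item{`"neutrality"`}{a GC12 = 0.2 + 0.3 GC3 scenario with mild noise.}
#' }
#'
#' @param preset one of the names above.
#' @param seed integer seed.
#' @param n_seq sequences per population.
#' @param length_codons codons per sequence.
#' @return a `cds_set`.
#' @export
simulate_preset <- function(preset = c("uniform", "maxbias", "two-pop",
                                       "neutrality"),
                            seed = 1L, n_seq = 20L, length_codons = 500L) {
  preset <- match.arg(preset)
  switch(preset,
    uniform = generate_cds_set(
      usage_spec(length_codons = length_codons, n_seq = n_seq,
                 label = "uniform", seed = seed)),
    maxbias = {
      fams <- codon_families()
      probs <- lapply(fams, function(cc)
        setNames(as.numeric(seq_along(cc) == 1L), cc))
      generate_cds_set(usage_spec(codon_probs = probs,
                                  length_codons = length_codons,
                                  n_seq = n_seq, label = "maxbias",
                                  seed = seed))
    },
    `two-pop` = {
      a <- generate_cds_set(biased_usage(0.85, concentration = 200,
                                         n_seq = n_seq,
                                         length_codons = length_codons,
                                         label = "popGC", seed = seed))
      b <- generate_cds_set(biased_usage(0.15, concentration = 200,
                                         n_seq = n_seq,
                                         length_codons = length_codons,
                                         label = "popAU", seed = seed + 1L))
      structure(c(a, b), class = "cds_set")
    },
    neutrality = generate_neutrality_set(
      neutrality_scenario(slope = 0.3, intercept = 0.2, noise = 0.005,
                          n = n_seq, length_codons = length_codons,
                          seed = seed))
  )
}
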