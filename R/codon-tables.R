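# Genetic-code bookkeeping shared by all statistics.
#
# Internal storage is DNA alphabet (A/C/G/T); every user-facing table and codon
# label is emitted in RNA alphabet (AUG...), the convention of codon-usage
# reports. The standard nuclear code is fixed; Leu/Ser/Arg are treated as
# single six-codon families (the CodonW convention), giving 18 degenerate
# families over 59 codons once Met, Trp and the three stops are excluded.

#' @importFrom Biostrings GENETIC_CODE
.CODE <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- as.character(names(gc))
  gc
}

.STOP_DNA <- names(.CODE)[.CODE == "*"]

# the 59 codons belonging to a degenerate synonymous family
.SYN_DNA <- names(.CODE)[!(.CODE %in% "*") & !(names(.CODE) %in% c("ATG", "TGG"))]

# family membership keyed by one-letter amino acid (six-fold families merged)
.FAMILIES <- split(.SYN_DNA, .CODE[.SYN_DNA])

.FAMILY_SIZE <- vapply(.FAMILIES, length, integer(1))

# degeneracy classes used by Wright's ENC estimator
.ENC_CLASSES <- list(
  `2` = names(.FAMILY_SIZE)[.FAMILY_SIZE == 2L],  # 9 families
  `3` = names(.FAMILY_SIZE)[.FAMILY_SIZE == 3L],  # Ile
  `4` = names(.FAMILY_SIZE)[.FAMILY_SIZE == 4L],  # 5 families
  `6` = names(.FAMILY_SIZE)[.FAMILY_SIZE == 6L]   # Leu, Ser, Arg
)

# fixed reporting order for the 59-dimensional RSCU space: amino acids in the
# customary codon-table order (Phe..Gly), codons alphabetical within a family
.AA_ORDER <- c("F", "L", "I", "V", "S", "P", "T", "A", "Y", "H",
               "Q", "N", "K", "D", "E", "C", "R", "G")

.CODON_ORDER_DNA <- unlist(lapply(.AA_ORDER, function(a) sort(.FAMILIES[[a]])),
                           use.names = FALSE)

.ALL_CODONS_DNA <- sort(names(.CODE))

# Kyte-Doolittle hydropathy scale; aromatic residues per the Gravy/Aroma
# outputs of classic codon-usage tools
.KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

.AROMATIC <- c("F", "Y", "W")

#' Convert codon labels between DNA and RNA alphabets
#'
#' All internal computation uses the DNA alphabet; reports use RNA codons.
#'
#' @param x character vector of codons or sequences.
#' @return `x` with T/U interconverted (case preserved for upper case input).
#' @examples
#' rna_codon("ATG")
#' dna_codon("AUG")
#' @export
rna_codon <- function(x) chartr("Tt", "Uu", x)

#' @rdname rna_codon
#' @export
dna_codon <- function(x) chartr("Uu", "Tt", x)

#' Synonymous codon families of the standard genetic code
#'
#' Returns the 18 degenerate synonymous families (Leu, Ser and Arg as single
#' six-codon families) with RNA-alphabet codon labels, in the fixed order used
#' for all 59-dimensional RSCU vectors.
#'
#' @return named list of character vectors, one per amino acid (one-letter).
#' @export
codon_families <- function() {
  fams <- .FAMILIES[.AA_ORDER]
  lapply(fams, function(cc) rna_codon(sort(cc)))
}

# internal: the 59 codons in reporting order, RNA alphabet
.codon_order_rna <- function() rna_codon(.CODON_ORDER_DNA)

# internal: run a block with a temporary RNG state seeded by `seed`;
# the caller's .Random.seed is untouched (no global state leaks)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
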