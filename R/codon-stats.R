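# Per-sequence and pooled codon-level statistics: composition, RSCU and codon
# classification, Wright's ENC and its expected curve, CAI, Gravy, Aroma.

#' Count codon occurrences in a coding sequence
#'
#' Tallies frame-0, non-overlapping triplets. Stop-codon counts are retained
#' in the vector but are excluded from all synonymous statistics downstream.
#'
#' @param seq a `coding_seq` (or nucleotide string).
#' @return an object of class `codon_counts`: named integer vector over all 64
#'   codons (RNA-alphabet names, fixed order), with attributes `total` (number
#'   of codons) and `ids` (source identifiers).
#' @examples
#' count_codons("ATGAAACCCGGG")
#' @export
count_codons <- function(seq) {
  cs <- .as_coding_seq(seq)
  n <- nchar(cs$seq) %/% 3L
  trip <- substring(cs$seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  counts <- setNames(integer(length(.ALL_CODONS_DNA)), .ALL_CODONS_DNA)
  tab <- table(trip)
  counts[names(tab)] <- as.integer(tab)
  names(counts) <- rna_codon(names(counts))
  structure(counts, total = n, ids = cs$id, class = "codon_counts")
}

#' Pool codon counts across sequences
#'
#' @param x a list of `codon_counts`, or a `cds_set` / list of `coding_seq`
#'   (counted first).
#' @return a single pooled `codon_counts`.
#' @export
pool_counts <- function(x) {
  cl <- lapply(x, function(el)
    if (inherits(el, "codon_counts")) el else count_codons(el))
  counts <- Reduce(`+`, lapply(cl, unclass))
  structure(counts,
            total = sum(vapply(cl, attr, 0L, "total")),
            ids = unlist(lapply(cl, attr, "ids")),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("<codon_counts> %d codons from %d source(s)\n",
              attr(x, "total"), length(attr(x, "ids"))))
  print(unclass(x)[unclass(x) > 0])
  invisible(x)
}

# internal: counts restricted to the 59 synonymous-family codons (RNA names)
.syn_counts <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  unclass(counts)[.codon_order_rna()]
}

#' Nucleotide composition summary of a CDS
#'
#' Whole-CDS nucleotide percentages (A%, C%, U%, G%), third-position
#' percentages over synonymous codons only (A3s..G3s, excluding Met, Trp and
#' stops, the CodonW convention), positional GC percentages GC1/GC2/GC3
#' computed over all codons, their synonymous-only counterpart GC3s, and
#' GC12 = (GC1 + GC2) / 2. All values are percentages.
#'
#' If the CDS contains no synonymous codon (e.g. only Met/Trp), the
#' third-position synonymous fields are `NA` and the result carries
#' `degenerate = TRUE`.
#'
#' @param seq a `coding_seq` (or nucleotide string).
#' @return one-row data.frame of class `codon_composition` with columns
#'   `A, C, U, G, A3s, C3s, U3s, G3s, GC, GC1, GC2, GC3, GC12, GC3s`.
#' @examples
#' composition_summary("AAATTT")
#' @export
composition_summary <- function(seq) {
  cs <- .as_coding_seq(seq)
  n <- nchar(cs$seq) %/% 3L
  base <- strsplit(cs$seq, "")[[1]]
  pos <- rep_len(1:3, length(base))
  pct <- function(x) 100 * x
  frac_of <- function(b, set) mean(b %in% set)
  overall <- vapply(c("A", "C", "T", "G"), function(b) frac_of(base, b), 0)
  third <- base[pos == 3L]
  first <- base[pos == 1L]
  second <- base[pos == 2L]
  trip <- substring(cs$seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  syn <- trip %in% .SYN_DNA
  if (any(syn)) {
    t3 <- third[syn]
    syn3 <- vapply(c("A", "C", "T", "G"), function(b) frac_of(t3, b), 0)
    gc3s <- frac_of(t3, c("G", "C"))
  } else {
    syn3 <- rep(NA_real_, 4)
    gc3s <- NA_real_
  }
  gc1 <- frac_of(first, c("G", "C"))
  gc2 <- frac_of(second, c("G", "C"))
  gc3 <- frac_of(third, c("G", "C"))
  out <- data.frame(
    A = pct(overall[["A"]]), C = pct(overall[["C"]]),
    U = pct(overall[["T"]]), G = pct(overall[["G"]]),
    A3s = pct(syn3[[1]]), C3s = pct(syn3[[2]]),
    U3s = pct(syn3[[3]]), G3s = pct(syn3[[4]]),
    GC = pct(frac_of(base, c("G", "C"))),
    GC1 = pct(gc1), GC2 = pct(gc2), GC3 = pct(gc3),
    GC12 = pct((gc1 + gc2) / 2), GC3s = pct(gc3s))
  attr(out, "degenerate") <- !any(syn)
  class(out) <- c("codon_composition", "data.frame")
  out
}

#' Relative synonymous codon usage profile
#'
#' RSCU(c) = observed count of codon c divided by the count expected under
#' uniform use of its synonymous family, i.e. `count(c) * n / N` for a family
#' of `n` codons with family total `N`. RSCU 1 means no bias; values sum to
#' the family degeneracy within each observed family. Families with no
#' observed codon get `NA` RSCU and are flagged.
#'
#' @param counts a `codon_counts` (or a `coding_seq`/string, counted first).
#' @return data.frame of class `rscu_profile` with columns `codon` (RNA),
#'   `aa`, `family_size`, `count`, `rscu`, in the fixed 59-codon order;
#'   attribute `missing_families` names unobserved families.
#' @export
rscu_profile <- function(counts) {
  if (!inherits(counts, "codon_counts")) counts <- count_codons(counts)
  cnt <- .syn_counts(counts)
  aa <- unname(.CODE[.CODON_ORDER_DNA])
  rscu <- rep(NA_real_, length(cnt))
  missing <- character()
  for (a in names(.FAMILIES)) {
    idx <- which(aa == a)
    N <- sum(cnt[idx])
    if (N == 0) { missing <- c(missing, a); next }
    rscu[idx] <- cnt[idx] * length(idx) / N
  }
  out <- data.frame(codon = names(cnt), aa = aa,
                    family_size = unname(.FAMILY_SIZE[aa]),
                    count = unname(cnt), rscu = rscu,
                    stringsAsFactors = FALSE)
  attr(out, "missing_families") <- missing
  class(out) <- c("rscu_profile", "data.frame")
  out
}

#' Classify codons of an RSCU profile
#'
#' Per synonymous family the preferred codon is the RSCU argmax;
#' over-represented codons have RSCU strictly above `over` (default 1.6) and
#' under-represented strictly below `under` (default 0.6). Ties for preferred
#' are broken toward the codon with the higher reference RSCU when a
#' `ref_usage` table is supplied, otherwise toward the alphabetically first
#' codon.
#'
#' @param profile an `rscu_profile` (or anything [rscu_profile()] accepts), or
#'   a named numeric vector of RSCU values over the 59 codons.
#' @param reference optional `ref_usage` used only for tie-breaking.
#' @param over,under strict thresholds for over-/under-representation.
#' @return list of class `rscu_classification` with character-vector elements
#'   `preferred`, `over_represented`, `under_represented` (RNA codons).
#' @export
classify_rscu <- function(profile, reference = NULL, over = 1.6, under = 0.6) {
  rscu <- .as_rscu_vector(profile)
  aa <- unname(.CODE[.CODON_ORDER_DNA])
  ref_rscu <- if (!is.null(reference)) {
    stopifnot(inherits(reference, "ref_usage"))
    setNames(reference$rscu, reference$codon)
  }
  preferred <- character()
  for (a in .AA_ORDER) {
    idx <- which(aa == a)
    vals <- rscu[idx]
    if (all(is.na(vals))) next
    m <- max(vals, na.rm = TRUE)
    cand <- names(vals)[!is.na(vals) & vals == m]
    if (length(cand) > 1L && !is.null(ref_rscu))
      cand <- cand[order(-ref_rscu[cand], cand)]
    else cand <- sort(cand)
    preferred <- c(preferred, cand[1L])
  }
  ok <- !is.na(rscu)
  structure(list(preferred = preferred,
                 over_represented = names(rscu)[ok & rscu > over],
                 under_represented = names(rscu)[ok & rscu < under]),
            class = "rscu_classification")
}

#' @export
print.rscu_classification <- function(x, ...) {
  cat("<rscu_classification>\n",
      " preferred (", length(x$preferred), "): ",
      paste(x$preferred, collapse = " "), "\n",
      " over-represented (", length(x$over_represented), "): ",
      paste(x$over_represented, collapse = " "), "\n",
      " under-represented (", length(x$under_represented), "): ",
      paste(x$under_represented, collapse = " "), "\n", sep = "")
  invisible(x)
}

# accept rscu_profile, named numeric vector, codon_counts or sequence
.as_rscu_vector <- function(x) {
  if (inherits(x, "rscu_profile")) return(setNames(x$rscu, x$codon))
  if (is.numeric(x) && !is.null(names(x))) {
    v <- setNames(rep(NA_real_, 59L), .codon_order_rna())
    nm <- rna_codon(toupper(names(x)))  # normalize alphabet
    keep <- nm %in% names(v)
    v[nm[keep]] <- x[keep]
    return(v)
  }
  p <- rscu_profile(x)
  setNames(p$rscu, p$codon)
}

#' Preferred codons shared between two usage profiles
#'
#' The intersection of the per-family preferred codons of two RSCU profiles,
#' e.g. a virus and its host — the classic indicator of host-adapted usage.
#'
#' @param a,b `rscu_profile`s, `rscu_classification`s, or RSCU vectors.
#' @param reference_a,reference_b optional `ref_usage` tie-breakers passed to
#'   [classify_rscu()].
#' @return character vector of shared preferred codons (RNA).
#' @export
shared_preferred <- function(a, b, reference_a = NULL, reference_b = NULL) {
  pa <- if (inherits(a, "rscu_classification")) a$preferred
        else classify_rscu(a, reference = reference_a)$preferred
  pb <- if (inherits(b, "rscu_classification")) b$preferred
        else classify_rscu(b, reference = reference_b)$preferred
  intersect(pa, pb)
}

#' Effective number of codons (Wright's ENC)
#'
#' Wright's estimator of how far codon usage departs from uniform synonymous
#' use, ranging from 20 (one codon per amino acid) to 61 (uniform; capped).
#' For each amino-acid family with at least 2 observed codons, the codon
#' homozygosity is `F = (n * sum(p^2) - 1) / (n - 1)` with `n` the family
#' total and `p` the within-family proportions. Class means over the 2-, 3-,
#' 4- and 6-fold degeneracy classes give
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. A missing 3-fold mean (no usable
#' Ile counts) is replaced by the average of the 2- and 4-fold means; any
#' other empty class is an error.
#'
#' @param counts a `codon_counts` (or sequence).
#' @param warn_short warn when fewer than 100 codons are scored.
#' @return object of class `enc_result`: list with `enc`, `f_means` (named by
#'   degeneracy class), `gc3s` (fraction, the ENC-plot abscissa) and
#'   `n_codons`.
#' @export
enc <- function(counts, warn_short = TRUE) {
  if (!inherits(counts, "codon_counts")) counts <- count_codons(counts)
  cnt <- .syn_counts(counts)
  if (warn_short && sum(cnt) < 100)
    warning("fewer than 100 synonymous codons; ENC is noisy", call. = FALSE)
  aa <- unname(.CODE[.CODON_ORDER_DNA])
  fam_F <- setNames(rep(NA_real_, length(.FAMILIES)), names(.FAMILIES))
  for (a in names(.FAMILIES)) {
    idx <- which(aa == a)
    n <- sum(cnt[idx])
    if (n < 2) next
    p <- cnt[idx] / n
    fam_F[a] <- (n * sum(p^2) - 1) / (n - 1)
  }
  f_means <- vapply(.ENC_CLASSES, function(fams)
    mean(fam_F[fams], na.rm = TRUE), 0)
  f_means[is.nan(f_means)] <- NA_real_
  if (is.na(f_means[["3"]]) && !is.na(f_means[["2"]]) && !is.na(f_means[["4"]]))
    f_means[["3"]] <- mean(c(f_means[["2"]], f_means[["4"]]))
  if (anyNA(f_means))
    stop("ENC undefined: no usable families in degeneracy class(es) ",
         paste(names(f_means)[is.na(f_means)], collapse = ", "), call. = FALSE)
  raw <- 2 + 9 / f_means[["2"]] + 1 / f_means[["3"]] +
    5 / f_means[["4"]] + 3 / f_means[["6"]]
  third <- substring(names(cnt), 3L, 3L)
  gc3s <- if (sum(cnt) > 0) sum(cnt[third %in% c("G", "C")]) / sum(cnt)
          else NA_real_
  structure(list(enc = min(raw, 61), f_means = f_means, gc3s = gc3s,
                 n_codons = sum(cnt)),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("<enc_result> ENC = %.3f (GC3s = %.3f, %d synonymous codons)\n",
              x$enc, x$gc3s, x$n_codons))
  invisible(x)
}

#' Expected ENC under mutation pressure alone
#'
#' Wright's expected curve `ENC(s) = 2 + s + 29 / (s^2 + (1 - s)^2)` where `s`
#' is GC3s. Sequences on or near this curve are compatible with codon usage
#' shaped by compositional (mutational) pressure only.
#'
#' @param s GC3s fraction(s) in `[0, 1]`.
#' @return expected ENC value(s).
#' @examples
#' expected_enc(0.5)  # 60.5
#' @export
expected_enc <- function(s) {
  if (any(s < 0 | s > 1, na.rm = TRUE))
    stop("s must lie in [0, 1]", call. = FALSE)
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Codon adaptation index
#'
#' Sharp-Li CAI: the geometric mean of relative-adaptiveness weights w of the
#' codons used, `CAI = exp(sum(count * log(w)) / sum(count))`, scored over
#' degenerate-family codons only (Met, Trp and stops excluded). CAI is 1 when
#' every used codon is its family's reference-optimal codon.
#'
#' @param counts a `codon_counts` (or sequence).
#' @param ref a `ref_usage` reference table (see [reference_table()]).
#' @return object of class `cai_result`: list with `cai` and `n_codons`.
#' @export
cai <- function(counts, ref) {
  if (!inherits(counts, "codon_counts")) counts <- count_codons(counts)
  stopifnot(inherits(ref, "ref_usage"))
  cnt <- .syn_counts(counts)
  w <- setNames(ref$w, ref$codon)[names(cnt)]
  n <- sum(cnt)
  if (n == 0) stop("no scorable (synonymous-family) codons", call. = FALSE)
  structure(list(cai = exp(sum(cnt * log(w)) / n), n_codons = n),
            class = "cai_result")
}

#' @export
print.cai_result <- function(x, ...) {
  cat(sprintf("<cai_result> CAI = %.4f over %d codons\n", x$cai, x$n_codons))
  invisible(x)
}

#' Translate a coding sequence
#'
#' Standard-code translation. A terminal stop codon is dropped; an internal
#' stop is an error.
#'
#' @param seq a `coding_seq` (or string).
#' @return one-letter amino-acid string.
#' @export
translate_cds <- function(seq) {
  cs <- .as_coding_seq(seq)
  n <- nchar(cs$seq) %/% 3L
  trip <- substring(cs$seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(.CODE[trip])
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*"))
    stop("internal stop codon in '", cs$id, "'", call. = FALSE)
  if (!length(aa)) stop("empty translation for '", cs$id, "'", call. = FALSE)
  paste(aa, collapse = "")
}

#' Mean hydropathy (Gravy) of the encoded protein
#'
#' Mean Kyte-Doolittle hydropathy over the translated residues; a proxy for
#' selection acting on protein physicochemistry.
#'
#' @inheritParams translate_cds
#' @return numeric Gravy value.
#' @export
gravy <- function(seq) {
  aa <- strsplit(translate_cds(seq), "")[[1]]
  mean(.KYTE_DOOLITTLE[aa])
}

#' Aromaticity (Aroma) of the encoded protein
#'
#' Fraction of residues that are aromatic (Phe, Tyr, Trp).
#'
#' @inheritParams translate_cds
#' @return numeric fraction in `[0, 1]`.
#' @export
aroma <- function(seq) {
  aa <- strsplit(translate_cds(seq), "")[[1]]
  mean(aa %in% .AROMATIC)
}

#' Per-sequence codon-usage metrics table
#'
#' Computes, for each sequence, the composition summary plus ENC, CAI (if a
#' reference is supplied), Gravy and Aroma — the per-sequence table feeding
#' the PR2, neutrality, correlation and group-comparison analyses.
#'
#' @param seqs a `cds_set` or list of `coding_seq`.
#' @param ref optional `ref_usage` for CAI.
#' @return data.frame with one row per sequence: `id`, `group`, composition
#'   columns (see [composition_summary()]), `ENC`, `CAI`, `Gravy`, `Aroma`.
#' @export
codon_metrics <- function(seqs, ref = NULL) {
  rows <- lapply(seqs, function(s) {
    s <- .as_coding_seq(s)
    comp <- composition_summary(s)
    cc <- count_codons(s)
    # ENC can be undefined (a whole degeneracy class absent); record NA then
    e <- tryCatch(suppressWarnings(enc(cc))$enc, error = function(e) NA_real_)
    data.frame(id = s$id, group = s$group, as.data.frame(comp),
               ENC = e,
               CAI = if (is.null(ref)) NA_real_ else cai(cc, ref)$cai,
               Gravy = gravy(s), Aroma = aroma(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
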