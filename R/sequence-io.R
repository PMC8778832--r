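# Reading, validating, assembling and deduplicating coding sequences, and
# reading host reference codon-usage tables.

#' Construct a coding sequence
#'
#' A `coding_seq` is an in-frame nucleotide CDS with an identifier and a group
#' label (typically the virus species). The sequence is upper-cased, U is
#' normalized to T, and the invariants — length a positive multiple of 3,
#' alphabet restricted to A/C/G/T — are enforced.
#'
#' @param seq nucleotide string (DNA or RNA alphabet).
#' @param id free-text identifier.
#' @param group free-text group label, e.g. a species name.
#' @return an object of class `coding_seq`.
#' @examples
#' coding_sequence("ATGAAAUAA", id = "demo")
#' @export
coding_sequence <- function(seq, id = "seq", group = NA_character_) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- dna_codon(toupper(seq))
  bad <- gsub("[ACGT]", "", s)
  if (nchar(bad) > 0L)
    stop("sequence '", id, "' contains non-ACGT/U characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","), call. = FALSE)
  if (nchar(s) == 0L || nchar(s) %% 3L != 0L)
    stop("sequence '", id, "' length ", nchar(s),
         " is not a positive multiple of 3", call. = FALSE)
  structure(list(id = as.character(id), group = as.character(group), seq = s),
            class = "coding_seq")
}

#' @export
print.coding_seq <- function(x, ...) {
  cat(sprintf("<coding_seq> %s [%s], %d nt (%d codons)\n",
              x$id, x$group, nchar(x$seq), nchar(x$seq) %/% 3L))
  invisible(x)
}

# coerce one element of a user-supplied collection
.as_coding_seq <- function(x, id = "seq") {
  if (inherits(x, "coding_seq")) x else coding_sequence(x, id = id)
}

#' Read coding sequences from a FASTA file
#'
#' One `coding_seq` per record, in file order. Record ids are taken from the
#' header up to the first whitespace; U is normalized to T. In strict mode
#' (default) a record violating the CDS invariants aborts the read with an
#' error naming the record; in lenient mode offending records are skipped with
#' a warning.
#'
#' @param path FASTA file, plain or gzipped.
#' @param group group label attached to every record (default `NA`).
#' @param strict logical; reject (`TRUE`) or skip-and-warn (`FALSE`) invalid
#'   records.
#' @return list of `coding_seq` objects, class `cds_set`.
#' @export
read_fasta <- function(path, group = NA_character_, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(recs))
  out <- vector("list", length(recs))
  keep <- logical(length(recs))
  for (i in seq_along(recs)) {
    res <- tryCatch(coding_sequence(as.character(recs[[i]]), id = ids[i],
                                    group = group),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop(conditionMessage(res), call. = FALSE)
      warning("skipping record: ", conditionMessage(res), call. = FALSE)
    } else {
      out[[i]] <- res
      keep[i] <- TRUE
    }
  }
  structure(out[keep], class = "cds_set")
}

#' Write coding sequences to a FASTA file
#'
#' @param seqs a `cds_set` or list of `coding_seq`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "seq"))
  names(ss) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @export
print.cds_set <- function(x, ...) {
  grp <- table(vapply(x, `[[`, "", "group"), useNA = "ifany")
  cat(sprintf("<cds_set> %d coding sequences (%s)\n", length(x),
              paste(sprintf("%s: %d", names(grp), grp), collapse = ", ")))
  invisible(x)
}

#' Concatenate ORF1 and ORF2 into an ORF12 analysis unit
#'
#' Removes the stop codon of ORF1 and the start codon of ORF2, then joins them
#' in ORF1-ORF2 order, the unit used for whole-virus codon-usage analysis. By
#' default ORF1 must end in a stop (TAA/TAG/TGA) and ORF2 must start with ATG;
#' `allow_partial_orf1` relaxes the ORF1 stop check for species whose ORF1
#' 5'/3' boundaries are incompletely annotated (then only the final codon is
#' still trimmed if it is a stop).
#'
#' @param orf1,orf2 `coding_seq` objects (or nucleotide strings).
#' @param allow_partial_orf1 logical override for a non-stop-terminated ORF1.
#' @param id,group identifier and group for the result; defaults derive from
#'   `orf1`.
#' @return a `coding_seq` of length `nchar(orf1) + nchar(orf2) - 6` (or minus
#'   3 when a partial ORF1 does not end in a stop).
#' @export
concatenate_orf12 <- function(orf1, orf2, allow_partial_orf1 = FALSE,
                              id = NULL, group = NULL) {
  orf1 <- .as_coding_seq(orf1, "orf1")
  orf2 <- .as_coding_seq(orf2, "orf2")
  last1 <- substring(orf1$seq, nchar(orf1$seq) - 2L)
  if (!(last1 %in% .STOP_DNA) && !allow_partial_orf1)
    stop("ORF1 '", orf1$id, "' does not end in a stop codon (", rna_codon(last1),
         "); use allow_partial_orf1 = TRUE for truncated ORF1 annotations",
         call. = FALSE)
  first2 <- substring(orf2$seq, 1L, 3L)
  if (first2 != "ATG")
    stop("ORF2 '", orf2$id, "' does not start with ATG", call. = FALSE)
  body1 <- if (last1 %in% .STOP_DNA)
    substring(orf1$seq, 1L, nchar(orf1$seq) - 3L) else orf1$seq
  coding_sequence(paste0(body1, substring(orf2$seq, 4L)),
                  id = if (is.null(id)) paste0(orf1$id, "_ORF12") else id,
                  group = if (is.null(group)) orf1$group else group)
}

#' Remove duplicate coding sequences
#'
#' Keeps the first occurrence of each distinct sequence string (case- and
#' alphabet-insensitive, i.e. 100% genetic identity), preserving input order.
#' The ids of removed records are reported via `message()` and attached as
#' attribute `removed`.
#'
#' @param seqs a `cds_set` or list of `coding_seq`.
#' @return the deduplicated `cds_set`, with attribute `removed` (character
#'   vector of dropped ids).
#' @export
deduplicate <- function(seqs) {
  key <- vapply(seqs, `[[`, "", "seq")
  dup <- duplicated(key)
  removed <- vapply(seqs[dup], `[[`, "", "id")
  if (length(removed))
    message("deduplicate: removed ", length(removed), " duplicate sequence(s): ",
            paste(removed, collapse = ", "))
  structure(seqs[!dup], class = "cds_set", removed = removed)
}

#' Build a host reference codon-usage table
#'
#' Normalizes a per-codon value vector (raw counts, frequencies per thousand,
#' or already-computed RSCU) to per-family RSCU and the relative-adaptiveness
#' weights w used by CAI: within each synonymous family, w(c) =
#' RSCU(c) / max RSCU, so the family-optimal codon has w = 1. Codons with zero
#' observed usage receive `zero_w` (default 0.01) so the CAI geometric mean
#' stays defined. Stop codons, Met and Trp are dropped.
#'
#' @param values named numeric vector: names are codons (DNA or RNA alphabet),
#'   values nonnegative.
#' @param units one of `"count"`, `"per-thousand"`, `"rscu"`. Counts and
#'   per-thousand frequencies are equivalent up to scale and are converted to
#'   RSCU; `"rscu"` values are taken as-is.
#' @param zero_w weight substituted for zero-usage codons, in (0, 1).
#' @return data.frame of class `ref_usage` with columns `codon` (RNA), `aa`,
#'   `value`, `rscu`, `w`, ordered as in all RSCU reports.
#' @examples
#' reference_table(c(GAT = 75, GAC = 25), units = "count")
#' @export
reference_table <- function(values, units = c("count", "per-thousand", "rscu"),
                            zero_w = 0.01) {
  units <- match.arg(units)
  stopifnot(is.numeric(values), !is.null(names(values)),
            zero_w > 0, zero_w < 1)
  cod <- dna_codon(toupper(names(values)))
  if (anyDuplicated(cod))
    stop("duplicate codon entries: ",
         paste(rna_codon(unique(cod[duplicated(cod)])), collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(cod, .ALL_CODONS_DNA)
  if (length(unknown))
    stop("unknown codon(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (any(values < 0)) stop("negative usage values", call. = FALSE)
  v <- setNames(rep(NA_real_, length(.CODON_ORDER_DNA)), .CODON_ORDER_DNA)
  keep <- cod %in% .CODON_ORDER_DNA
  v[cod[keep]] <- values[keep]
  supplied <- !is.na(v)
  v[!supplied] <- 0  # codons absent from the table: unobserved
  rscu <- v
  w <- v
  missing_families <- character()
  for (a in names(.FAMILIES)) {
    idx <- .FAMILIES[[a]]
    if (!any(supplied[idx])) {
      # family entirely absent: imputed at the zero-usage weight, flagged
      missing_families <- c(missing_families, a)
      rscu[idx] <- NA_real_
      w[idx] <- zero_w
      next
    }
    if (units != "rscu") {
      tot <- sum(v[idx])
      if (tot == 0) stop("all-zero synonymous family: ", a, call. = FALSE)
      rscu[idx] <- v[idx] * length(idx) / tot
    }
    m <- max(rscu[idx])
    if (m == 0) stop("all-zero synonymous family: ", a, call. = FALSE)
    w[idx] <- rscu[idx] / m
  }
  w[!is.na(w) & w == 0] <- zero_w
  out <- data.frame(codon = rna_codon(.CODON_ORDER_DNA),
                    aa = unname(.CODE[.CODON_ORDER_DNA]),
                    value = unname(v), rscu = unname(rscu), w = unname(w),
                    stringsAsFactors = FALSE)
  attr(out, "missing_families") <- missing_families
  class(out) <- c("ref_usage", "data.frame")
  out
}

#' Read a host reference codon-usage table from a text file
#'
#' Expects two whitespace- or tab-separated columns, codon then value, with
#' optional comment lines starting `#`. See [reference_table()] for the
#' normalization applied.
#'
#' @inheritParams reference_table
#' @param path path to the table.
#' @return a `ref_usage` data.frame.
#' @export
read_reference_table <- function(path, units = c("count", "per-thousand", "rscu"),
                                 zero_w = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("codon", "value"),
                           colClasses = c("character", "numeric"))
  reference_table(setNames(tab$value, tab$codon), units = units,
                  zero_w = zero_w)
}

#' @export
print.ref_usage <- function(x, ...) {
  cat("<ref_usage> host codon-usage reference, 59 synonymous codons\n")
  print.data.frame(utils::head(x, 6), row.names = FALSE)
  cat("  ...\n")
  invisible(x)
}
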