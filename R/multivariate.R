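# Principal component analysis of 59-dimensional RSCU vectors.

#' Assemble an RSCU matrix across sequences
#'
#' Rows are sequences, columns the 59 degenerate-family codons in the fixed
#' reporting order (amino acids Phe..Gly, codons alphabetical within family).
#' Families absent from a sequence have undefined RSCU; they are imputed with
#' the family-neutral value 1 and flagged in the logical attribute `imputed`.
#'
#' @param seqs a `cds_set` / list of `coding_seq`, or a list of
#'   `rscu_profile`s.
#' @return numeric matrix (rownames = ids) with attributes `group` (character
#'   vector per row) and `imputed` (logical matrix).
#' @export
rscu_matrix <- function(seqs) {
  profs <- lapply(seqs, function(s)
    if (inherits(s, "rscu_profile")) s else rscu_profile(count_codons(s)))
  ids <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (inherits(s, "coding_seq")) s$id else paste0("seq", i)
  }, "")
  groups <- vapply(seqs, function(s)
    if (inherits(s, "coding_seq")) s$group else NA_character_, "")
  m <- do.call(rbind, lapply(profs, function(p) p$rscu))
  colnames(m) <- profs[[1]]$codon
  rownames(m) <- make.unique(ids)
  imputed <- is.na(m)
  m[imputed] <- 1
  attr(m, "group") <- groups
  attr(m, "imputed") <- imputed
  m
}

#' Principal component analysis of RSCU vectors
#'
#' Columns are mean-centered (no variance scaling by default — RSCU values
#' share a common scale) and the covariance eigenstructure extracted. The sign
#' of each component is fixed deterministically: the largest-magnitude loading
#' of every PC is made positive, so scores are reproducible across runs and
#' platforms.
#'
#' @param m matrix from [rscu_matrix()] (or any numeric matrix, rows =
#'   observations).
#' @param k number of components to keep (default 2, the usual plot axes).
#' @param scale. logical, unit-variance scaling (default `FALSE`).
#' @return object of class `rscu_pca`: list with `scores` (n x k), `loadings`
#'   (p x k), `var_explained` (fraction per retained PC), `sdev` (all PCs),
#'   `center`, `group`.
#' @export
pca_rscu <- function(m, k = 2, scale. = FALSE) {
  stopifnot(is.matrix(m) || is.data.frame(m))
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need at least 3 rows", call. = FALSE)
  k <- as.integer(k)
  stopifnot(k >= 1, k <= min(nrow(m) - 1L, ncol(m)))
  if (all(apply(m, 2, stats::sd) == 0))
    stop("all rows identical: total variance is zero", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 var_explained = ve[seq_len(k)], sdev = pc$sdev,
                 center = pc$center,
                 group = attr(m, "group")),
            class = "rscu_pca")
}

#' @export
print.rscu_pca <- function(x, ...) {
  cat("<rscu_pca> ", nrow(x$scores), " observations, ", ncol(x$scores),
      " components retained\n", sep = "")
  cat("  variance explained:",
      paste0(sprintf("PC%d %.2f%%", seq_along(x$var_explained),
                     100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.rscu_pca <- function(x, ...) {
  grp <- x$group
  col <- if (!is.null(grp) && !all(is.na(grp)))
    as.integer(factor(grp)) else 1L
  plot(x$scores[, 1], x$scores[, 2],
       xlab = sprintf("PC1 (%.2f%%)", 100 * x$var_explained[1]),
       ylab = sprintf("PC2 (%.2f%%)", 100 * x$var_explained[2]),
       col = col, pch = 19, main = "PCA of RSCU vectors", ...)
  if (!is.null(grp) && !all(is.na(grp)))
    graphics::legend("topright", legend = levels(factor(grp)),
                     col = seq_along(levels(factor(grp))), pch = 19, bty = "n")
  invisible(x)
}
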