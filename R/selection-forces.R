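# Mutation-vs-selection diagnostics across a sequence set: PR2 coordinates,
# neutrality regression with the contribution split, outlier screening,
# Spearman correlation matrix, CAI group comparison.

#' Parity rule 2 coordinates
#'
#' AT bias `A3/(A3 + U3)` and GC bias `G3/(G3 + C3)` computed from the
#' synonymous third-position frequencies. Under strand-symmetric mutation with
#' no selection both equal 0.5 (A3 = U3 and G3 = C3), the PR2-plot center.
#' A zero denominator yields `NA` with `undefined = TRUE` — never a silent 0.
#'
#' @param comp a `codon_composition` (from [composition_summary()]), or a
#'   `coding_seq`/string which is summarized first.
#' @return one-row data.frame of class `pr2_point`: `at_bias`, `gc_bias`,
#'   `undefined`.
#' @export
pr2_coordinates <- function(comp) {
  if (!inherits(comp, "codon_composition")) comp <- composition_summary(comp)
  au <- comp$A3s + comp$U3s
  gc <- comp$G3s + comp$C3s
  at_bias <- if (is.na(au) || au == 0) NA_real_ else comp$A3s / au
  gc_bias <- if (is.na(gc) || gc == 0) NA_real_ else comp$G3s / gc
  out <- data.frame(at_bias = at_bias, gc_bias = gc_bias,
                    undefined = is.na(at_bias) || is.na(gc_bias))
  class(out) <- c("pr2_point", "data.frame")
  out
}

#' PR2 coordinates for a set of sequences
#'
#' @param seqs a `cds_set` or list of `coding_seq`.
#' @return data.frame with columns `id`, `group`, `at_bias`, `gc_bias`,
#'   `undefined`.
#' @export
pr2_points <- function(seqs) {
  rows <- lapply(seqs, function(s) {
    s <- .as_coding_seq(s)
    cbind(data.frame(id = s$id, group = s$group, stringsAsFactors = FALSE),
          as.data.frame(pr2_coordinates(s)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen paired GC12/GC3 values for outliers
#'
#' Default rule: Tukey fences at 1.5 IQR applied to each margin; a point is
#' removed if it lies outside either fence. `"sd3"` removes points more than 3
#' standard deviations from either marginal mean; `"none"` removes nothing.
#' Fewer than 8 points triggers a warning and no removal.
#'
#' @param gc12,gc3 numeric vectors of equal length (fractions or percentages).
#' @param method `"tukey"`, `"sd3"` or `"none"`.
#' @return list with integer indices `keep` and `removed`.
#' @export
detect_outliers <- function(gc12, gc3, method = c("tukey", "sd3", "none")) {
  method <- match.arg(method)
  stopifnot(length(gc12) == length(gc3))
  n <- length(gc12)
  if (method == "none") return(list(keep = seq_len(n), removed = integer()))
  if (n < 8) {
    warning("fewer than 8 points; outlier screening skipped", call. = FALSE)
    return(list(keep = seq_len(n), removed = integer()))
  }
  inside <- function(x) {
    if (method == "tukey") {
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr
    } else {
      s <- stats::sd(x)
      if (s == 0) rep(TRUE, length(x)) else abs(x - mean(x)) <= 3 * s
    }
  }
  keep <- which(inside(gc12) & inside(gc3))
  list(keep = keep, removed = setdiff(seq_len(n), keep))
}

#' Split a neutrality-plot slope into selection and mutation contributions
#'
#' On the neutrality plot (GC12 regressed on GC3), slope 1 means directional
#' mutation pressure fully explains the first/second-position composition and
#' slope 0 means natural selection decouples them entirely. The slope
#' magnitude is therefore read as the mutation-pressure share:
#' `mutation% = min(|slope|, 1) * 100`, `selection% = 100 - mutation%`.
#'
#' @param slope finite regression slope.
#' @return named numeric vector `c(selection = , mutation = )`, in percent,
#'   summing to 100 exactly.
#' @examples
#' selection_contribution(-0.243)  # selection 75.7
#' @export
selection_contribution <- function(slope) {
  if (!is.finite(slope)) stop("slope must be finite", call. = FALSE)
  mut <- min(abs(slope), 1) * 100
  c(selection = 100 - mut, mutation = mut)
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Fits ordinary least squares of GC12 (mean GC at codon positions 1 and 2)
#' on GC3 across a sequence set, after optional outlier screening, and splits
#' the slope into natural-selection and mutation-pressure contributions via
#' [selection_contribution()]. Both Pearson and Spearman correlations of the
#' retained points are reported.
#'
#' @param gc12,gc3 numeric vectors (same units, fractions or percentages), or
#'   leave `gc3` missing and pass a data.frame with `GC12` and `GC3` columns
#'   (e.g. from [codon_metrics()]) as `gc12`.
#' @param outliers outlier rule for [detect_outliers()].
#' @param method `"ols"` (default) or `"rma"` (reduced major axis, slope
#'   `sign(r) * sd(y)/sd(x)` through the means).
#' @return object of class `neutrality_fit` with components `slope`,
#'   `intercept`, `pearson` (list `r`, `p`), `spearman` (list `rho`, `p`),
#'   `contribution` (selection/mutation %), `n_used`, `n_removed`, `removed`
#'   (indices), `model` (the `lm` fit for OLS), `data` (retained points).
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' fit <- neutrality_fit(gc12 = c(40, 42, 44, 46), gc3 = c(40, 45, 50, 55),
#'                       outliers = "none")
#' coef(fit)
#' @export
neutrality_fit <- function(gc12, gc3, outliers = c("tukey", "sd3", "none"),
                           method = c("ols", "rma")) {
  if (missing(gc3) && is.data.frame(gc12)) {
    gc3 <- gc12$GC3
    gc12 <- gc12$GC12
  }
  outliers <- match.arg(outliers)
  method <- match.arg(method)
  stopifnot(is.numeric(gc12), is.numeric(gc3), length(gc12) == length(gc3))
  ok <- stats::complete.cases(gc12, gc3)
  gc12 <- gc12[ok]; gc3 <- gc3[ok]
  scr <- detect_outliers(gc12, gc3, method = outliers)
  x <- gc3[scr$keep]; y <- gc12[scr$keep]
  if (length(x) < 3) stop("fewer than 3 points after outlier removal",
                          call. = FALSE)
  if (stats::sd(x) == 0) stop("GC3 is constant; regression undefined",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (method == "rma") {
    r0 <- stats::cor(x, y)
    slope <- sign(r0) * stats::sd(y) / stats::sd(x)
    intercept <- mean(y) - slope * mean(x)
  }
  # correlations are NA (not a warning) when GC12 is constant
  if (stats::sd(y) == 0) {
    pe <- list(estimate = NA_real_, p.value = NA_real_)
    sp <- list(estimate = NA_real_, p.value = NA_real_)
  } else {
    pe <- stats::cor.test(x, y, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
  }
  structure(list(slope = slope, intercept = intercept,
                 pearson = list(r = unname(pe$estimate), p = pe$p.value),
                 spearman = list(rho = unname(sp$estimate), p = sp$p.value),
                 contribution = selection_contribution(slope),
                 n_used = length(x), n_removed = length(scr$removed),
                 removed = scr$removed, outlier_method = outliers,
                 fit_method = method, model = fit,
                 data = data.frame(gc3 = x, gc12 = y)),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, digits = 4, ...) {
  cat("Neutrality plot regression: GC12 ~ GC3 (", x$fit_method, ")\n", sep = "")
  cat(sprintf("  slope %.*f, intercept %.*f  (n = %d used, %d removed as outliers)\n",
              digits, x$slope, digits, x$intercept, x$n_used, x$n_removed))
  cat(sprintf("  Pearson r = %.*f (p = %.3g); Spearman rho = %.*f (p = %.3g)\n",
              digits, x$pearson$r, x$pearson$p,
              digits, x$spearman$rho, x$spearman$p))
  cat(sprintf("  natural selection %.2f%% vs mutation pressure %.2f%%\n",
              x$contribution[["selection"]], x$contribution[["mutation"]]))
  invisible(x)
}

#' @export
summary.neutrality_fit <- function(object, ...) {
  print(object)
  cat("\nOLS details:\n")
  print(summary(object$model))
  invisible(object)
}

#' @export
coef.neutrality_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.neutrality_fit <- function(object, gc3 = NULL, ...) {
  if (is.null(gc3)) gc3 <- object$data$gc3
  object$intercept + object$slope * gc3
}

#' @export
residuals.neutrality_fit <- function(object, ...) {
  object$data$gc12 - predict(object)
}

#' @export
plot.neutrality_fit <- function(x, ...) {
  plot(x$data$gc3, x$data$gc12, xlab = "GC3", ylab = "GC12",
       main = "Neutrality plot", ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::abline(0, 1, col = "grey60")
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "GC12 = %.3f + %.3f GC3\nselection %.1f%%",
    x$intercept, x$slope, x$contribution[["selection"]]))
  invisible(x)
}

#' Spearman correlation matrix of codon-usage metrics
#'
#' Spearman rank correlations (average ranks for ties, two-sided p) between
#' the third-position/ENC block (rows: A3s, C3s, U3s, G3s, GC3, ENC) and the
#' overall-composition/protein block (columns: A, C, U, G, GC, Gravy, Aroma),
#' the classic mutation-vs-selection correlation screen. Stars mark p < 0.05
#' (`*`) and p < 0.01 (`**`). A constant column yields `NA` entries.
#'
#' @param metrics data.frame from [codon_metrics()] (needs those columns).
#' @param rows,cols optional character vectors overriding the variable sets.
#' @return object of class `cub_cor`: list with matrices `rho`, `p`, `stars`
#'   and scalar `n`.
#' @export
spearman_matrix <- function(metrics,
                            rows = c("A3s", "C3s", "U3s", "G3s", "GC3", "ENC"),
                            cols = c("A", "C", "U", "G", "GC", "Gravy", "Aroma")) {
  stopifnot(is.data.frame(metrics), all(c(rows, cols) %in% names(metrics)))
  if (nrow(metrics) < 5) stop("need at least 5 sequences", call. = FALSE)
  rho <- p <- matrix(NA_real_, length(rows), length(cols),
                     dimnames = list(rows, cols))
  for (i in rows) for (j in cols) {
    x <- metrics[[i]]; y <- metrics[[j]]
    if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0)
      next  # undefined, left NA
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  stars <- ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  structure(list(rho = rho, p = p, stars = stars, n = nrow(metrics)),
            class = "cub_cor")
}

#' @export
print.cub_cor <- function(x, digits = 2, ...) {
  cat("<cub_cor> Spearman correlations (n = ", x$n, ")\n", sep = "")
  shown <- matrix(paste0(formatC(x$rho, digits = digits, format = "f"),
                         ifelse(x$stars == "", "", " "), x$stars),
                  nrow(x$rho), dimnames = dimnames(x$rho))
  shown[is.na(x$rho)] <- "NA"
  print(shown, quote = FALSE)
  cat("* p < 0.05; ** p < 0.01\n")
  invisible(x)
}

#' Pairwise Mann-Whitney comparison of CAI values across groups
#'
#' All pairwise two-sided Mann-Whitney (Wilcoxon rank-sum) tests on CAI
#' values, unadjusted by default, plus a compact letter display: groups
#' sharing a letter are not significantly different at `alpha`. Letters are
#' assigned by insert-and-absorb over the pairwise significance graph, with
#' groups ordered by decreasing mean.
#'
#' @param cai numeric vector of CAI values.
#' @param group group label per value (coerced to factor); every group needs
#'   at least 3 values.
#' @param alpha significance level for the letter display.
#' @param adjust p-value adjustment passed to [stats::p.adjust()] (default
#'   `"none"`; `"BH"` available).
#' @return object of class `cai_comparison`: list with `p` (symmetric matrix
#'   of pairwise p-values), `letters` (named character vector), `means`,
#'   `alpha`, `adjust`.
#' @export
cai_group_comparison <- function(cai, group, alpha = 0.05, adjust = "none") {
  group <- factor(group)
  stopifnot(length(cai) == length(group))
  sizes <- table(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 3))
    stop("every group needs at least 3 values; too small: ",
         paste(names(sizes)[sizes < 3], collapse = ", "), call. = FALSE)
  lev <- levels(group)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  praw <- vapply(pairs, function(pr) {
    suppressWarnings(stats::wilcox.test(cai[group == pr[1]],
                                        cai[group == pr[2]],
                                        alternative = "two.sided"))$p.value
  }, 0)
  padj <- stats::p.adjust(praw, method = adjust)
  p <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  diag(p) <- 1
  for (k in seq_along(pairs)) {
    p[pairs[[k]][1], pairs[[k]][2]] <- padj[k]
    p[pairs[[k]][2], pairs[[k]][1]] <- padj[k]
  }
  means <- tapply(cai, group, mean)
  p_cld <- p
  p_cld[is.na(p_cld)] <- 1  # untestable pair: no evidence of difference
  letters <- .compact_letters(p_cld, order(-means), alpha)
  structure(list(p = p, letters = letters, means = means, alpha = alpha,
                 adjust = adjust),
            class = "cai_comparison")
}

# insert-and-absorb compact letter display: `p` symmetric matrix, `ord`
# processing order (indices into rownames), shared letter <=> not significant
.compact_letters <- function(p, ord, alpha) {
  lev <- rownames(p)[ord]
  groups <- list(lev[1])  # letter groups, each a set of compatible levels
  for (g in lev[-1]) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (all(p[g, groups[[k]]] >= alpha)) {
        groups[[k]] <- c(groups[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) {
      # open a new letter containing g and every level compatible with it
      newset <- g
      for (h in setdiff(lev, g))
        if (all(p[h, newset] >= alpha)) newset <- c(newset, h)
      groups <- c(groups, list(newset))
    }
  }
  # absorb letter groups fully contained in another
  keep <- rep(TRUE, length(groups))
  for (k in seq_along(groups)) for (m in seq_along(groups))
    if (k != m && keep[k] && keep[m] && all(groups[[k]] %in% groups[[m]]))
      keep[k] <- FALSE
  groups <- groups[keep]
  out <- setNames(rep("", nrow(p)), rownames(p))
  for (k in seq_along(groups))
    for (g in groups[[k]]) out[g] <- paste0(out[g], letters[k])
  out
}

#' @export
print.cai_comparison <- function(x, ...) {
  cat("<cai_comparison> pairwise Mann-Whitney (", x$adjust,
      " adjustment), alpha = ", x$alpha, "\n", sep = "")
  df <- data.frame(group = names(x$means),
                   mean_cai = round(as.numeric(x$means), 4),
                   letter = x$letters[names(x$means)])
  print(df, row.names = FALSE)
  invisible(x)
}
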