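# Standard diagnostic plots (base graphics, headless-safe: nothing is drawn
# unless the user calls these).

#' ENC versus GC3s plot with Wright's expected curve
#'
#' @param metrics data.frame from [codon_metrics()] (`ENC`, `GC3s`, `group`).
#' @param ... passed to [plot()].
#' @return the input, invisibly.
#' @export
plot_enc_gc3 <- function(metrics, ...) {
  grp <- factor(metrics$group)
  plot(metrics$GC3s / 100, metrics$ENC, xlim = c(0, 1), ylim = c(20, 62),
       xlab = "GC3s", ylab = "ENC", col = as.integer(grp), pch = 19,
       main = "ENC plot", ...)
  s <- seq(0.01, 0.99, by = 0.01)
  graphics::lines(s, expected_enc(s))
  graphics::legend("bottomright", legend = levels(grp),
                   col = seq_along(levels(grp)), pch = 19, bty = "n")
  invisible(metrics)
}

#' Parity rule 2 plot
#'
#' @param points data.frame from [pr2_points()].
#' @param ... passed to [plot()].
#' @return the input, invisibly.
#' @export
plot_pr2 <- function(points, ...) {
  grp <- factor(points$group)
  plot(points$gc_bias, points$at_bias, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "G3/(G3+C3)", ylab = "A3/(A3+U3)", col = as.integer(grp),
       pch = 19, main = "PR2 plot", ...)
  graphics::abline(h = 0.5, v = 0.5, lty = 3)
  graphics::legend("topright", legend = levels(grp),
                   col = seq_along(levels(grp)), pch = 19, bty = "n")
  invisible(points)
}

#' CAI by group with compact-letter annotations
#'
#' @param cai numeric CAI values.
#' @param group group labels.
#' @param comparison optional `cai_comparison` (computed if omitted).
#' @param ... passed to [graphics::boxplot()].
#' @return the comparison object, invisibly.
#' @export
plot_cai_groups <- function(cai, group, comparison = NULL, ...) {
  if (is.null(comparison)) comparison <- cai_group_comparison(cai, group)
  grp <- factor(group)
  graphics::boxplot(cai ~ grp, xlab = "group", ylab = "CAI",
                    main = "Codon adaptation index", ...)
  ymax <- tapply(cai, grp, max)
  graphics::text(seq_along(levels(grp)), ymax,
                 comparison$letters[levels(grp)], pos = 3, xpd = NA)
  invisible(comparison)
}
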