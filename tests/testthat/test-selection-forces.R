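test_that("pr2_coordinates hit the center iff A3=U3 and G3=C3", {
  # AAA/TTT balance A3/U3; GGG/CCC balance G3/C3
  p <- pr2_coordinates("AAATTTGGGCCC")
  expect_equal(p$at_bias, 0.5)
  expect_equal(p$gc_bias, 0.5)
  expect_false(p$undefined)

  # A3 = 30, U3 = 10 -> at_bias 0.75 (Lys AAA x3, Phe UUU x1)
  p2 <- pr2_coordinates(paste0(strrep("AAA", 3), "TTTGGGCCC"))
  expect_equal(p2$at_bias, 0.75)

  # no G3/C3 at synonymous third positions -> flagged undefined, never 0
  p3 <- pr2_coordinates("AAATTT")
  expect_true(is.na(p3$gc_bias))
  expect_true(p3$undefined)

  # ratio invariance: scaling counts x10 leaves coordinates unchanged
  s <- "AAATTTGGGCCCGATCCT"
  expect_equal(pr2_coordinates(s)[, 1:2],
               pr2_coordinates(strrep(s, 10))[, 1:2])

  pts <- pr2_points(simulate_preset("uniform", seed = 2, n_seq = 4,
                                    length_codons = 100))
  expect_equal(nrow(pts), 4)
  expect_true(all(pts$at_bias >= 0 & pts$at_bias <= 1))
})

test_that("detect_outliers applies marginal Tukey fences", {
  # identical values: nothing removed
  same <- rep(0.5, 20)
  expect_length(detect_outliers(same, same)$removed, 0)

  # 99 points near 0.5 plus one extreme at 0.99: the extreme is fenced out
  set.seed(14)
  gc3 <- c(runif(99, 0.45, 0.55), 0.99)
  gc12 <- c(runif(99, 0.45, 0.55), 0.5)
  out <- detect_outliers(gc12, gc3)
  expect_equal(out$removed, 100L)

  # removal on either margin suffices
  out2 <- detect_outliers(c(runif(99, 0.45, 0.55), 0.99),
                          c(runif(99, 0.45, 0.55), 0.5))
  expect_equal(out2$removed, 100L)

  expect_equal(detect_outliers(gc12, gc3, method = "none")$keep, 1:100)
  expect_warning(detect_outliers(runif(5), runif(5)), "8 points")
})

test_that("selection_contribution splits the slope, summing to 100 exactly", {
  expect_equal(unname(selection_contribution(-0.243)["selection"]), 75.7)
  expect_equal(unname(selection_contribution(0)["selection"]), 100)
  expect_equal(unname(selection_contribution(1)["selection"]), 0)
  expect_equal(unname(selection_contribution(2.5)["mutation"]), 100)  # clipped
  for (sl in seq(-1.5, 1.5, by = 0.125))
    expect_identical(sum(selection_contribution(sl)), 100)
  expect_error(selection_contribution(NaN), "finite")
})

test_that("neutrality_fit recovers exact lines and reports contributions", {
  x <- seq(30, 70, length.out = 12)
  diag_fit <- neutrality_fit(x, x, outliers = "none")
  expect_equal(unname(coef(diag_fit)["slope"]), 1)
  expect_equal(diag_fit$contribution[["mutation"]], 100)

  flat <- neutrality_fit(rep(45, 12), x, outliers = "none")
  expect_equal(unname(coef(flat)["slope"]), 0)
  expect_equal(flat$contribution[["selection"]], 100)

  expect_error(neutrality_fit(x, rep(50, 12), outliers = "none"), "constant")
  expect_error(neutrality_fit(1:2, 1:2, outliers = "none"), "3 points")

  # methods on the fitted object
  fit <- neutrality_fit(0.5 * x + 3 + c(rep(0, 11), 0.4), x, outliers = "none")
  expect_equal(predict(fit, gc3 = 50), unname(coef(fit)[1] + coef(fit)[2] * 50))
  expect_length(residuals(fit), fit$n_used)
  expect_output(print(fit), "selection")
})

test_that("neutrality_fit recovers a generating slope from simulation", {
  scn <- neutrality_scenario(slope = 0.3, intercept = 0.2, noise = 0.005,
                             n = 500, length_codons = 300, seed = 99)
  m <- codon_metrics(generate_neutrality_set(scn))
  fit <- neutrality_fit(m$GC12, m$GC3)
  expect_lt(abs(fit$slope - 0.3), 0.05)

  # over seeded replicates the estimate stays within 3 SE of the truth
  hits <- vapply(1:20, function(i) {
    scn <- neutrality_scenario(slope = 0.3, intercept = 0.2, noise = 0.005,
                               n = 60, length_codons = 200, seed = 1000 + i)
    m <- codon_metrics(generate_neutrality_set(scn))
    f <- neutrality_fit(m$GC12, m$GC3, outliers = "none")
    se <- summary(f$model)$coefficients[2, 2]
    abs(f$slope - 0.3) <= 3 * se
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("spearman_matrix matches the rank formula and is rank-invariant", {
  set.seed(33)
  n <- 24
  base <- data.frame(
    A3s = runif(n), C3s = runif(n), U3s = runif(n), G3s = runif(n),
    GC3 = runif(n), ENC = runif(n, 40, 61),
    A = runif(n), C = runif(n), U = runif(n), G = runif(n), GC = runif(n),
    Gravy = rnorm(n), Aroma = runif(n))
  cm <- spearman_matrix(base)
  expect_equal(dim(cm$rho), c(6, 7))
  expect_true(all(abs(cm$rho) <= 1, na.rm = TRUE))

  # brute force on 6 hand-written untied pairs
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 5)
  df <- base[1:6, ]
  df$A3s <- x; df$A <- y
  cm6 <- spearman_matrix(df)
  expect_equal(cm6$rho["A3s", "A"], oracle_spearman(x, y), tolerance = 1e-12)

  # self-correlation and antithetic columns
  df2 <- base; df2$A <- df2$A3s; df2$C <- -df2$A3s
  cm2 <- spearman_matrix(df2)
  expect_equal(cm2$rho["A3s", "A"], 1)
  expect_equal(cm2$rho["A3s", "C"], -1)

  # invariance under strictly monotone transforms of either variable
  df3 <- base
  df3$A <- exp(df3$A); df3$GC3 <- df3$GC3^3
  cm3 <- spearman_matrix(df3)
  expect_equal(cm3$rho["GC3", "A"], cm$rho["GC3", "A"], tolerance = 1e-12)

  # constant column flagged as NA, and stars match the p thresholds
  df4 <- base; df4$G <- 1
  cm4 <- spearman_matrix(df4)
  expect_true(all(is.na(cm4$rho[, "G"])))
  expect_true(all(cm4$stars[!is.na(cm4$p) & cm4$p < 0.01] == "**"))

  expect_error(spearman_matrix(base[1:4, ]), "5")
})

test_that("cai_group_comparison runs Mann-Whitney tests with letter display", {
  # two identical groups share a letter
  g <- rep(c("a", "b"), each = 5)
  v <- rep(c(0.7, 0.71, 0.72, 0.73, 0.74), 2)
  cmp <- cai_group_comparison(v, g)
  expect_equal(unname(cmp$letters["a"]), unname(cmp$letters["b"]))

  # complete separation at n = 5 vs 5: exact two-sided p = 2 / choose(10, 5)
  cmp2 <- cai_group_comparison(c(1:5, 101:105), rep(c("lo", "hi"), each = 5))
  expect_equal(cmp2$p["lo", "hi"], 2 / choose(10, 5), tolerance = 1e-12)
  expect_false(cmp2$letters["lo"] == cmp2$letters["hi"])

  # a far-shifted third group gets its own letter
  set.seed(6)
  v3 <- c(rnorm(8, 0.70, 0.002), rnorm(8, 0.701, 0.002), rnorm(8, 0.9, 0.002))
  g3 <- rep(c("p1", "p2", "far"), each = 8)
  cmp3 <- cai_group_comparison(v3, g3)
  expect_false(cmp3$letters["far"] %in% cmp3$letters[c("p1", "p2")])

  expect_error(cai_group_comparison(1:5, rep("a", 5)), "2 groups")
  expect_error(cai_group_comparison(c(1, 2, 3, 4), c("a", "a", "a", "b")),
               "at least 3")
})
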