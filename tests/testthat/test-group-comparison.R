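test_that("Kruskal-Wallis matches the rank formula and degenerates to p = 1", {
  same <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # perfectly separated groups: H = 12/(N(N+1)) * sum n_j (Rbar_j - (N+1)/2)^2
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$statistic, 7.2, tolerance = 1e-10)
  expect_equal(res$p_value, 1 - pchisq(7.2, 2), tolerance = 1e-10)

  # chi-square approximation tracks the permutation distribution at
  # moderate N for mid-range p-values
  set.seed(31)
  x <- rnorm(18); g <- rep(1:3, each = 6)
  obs <- kruskal_wallis(x, g)
  perm <- replicate(4000, kruskal_wallis(x, sample(g))$statistic)
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p_value - p_perm), 0.05)
})

test_that("Dunn z-statistics match a hand evaluation with ties", {
  x <- c(1, 2, 2, 5, 6, 7, 8, 9, 10)
  g <- rep(c("Ctrl", "LC", "HCC"), each = 3)
  res <- dunn_posthoc(x, g, adjust_method = "none")

  # independent evaluation of the pooled-rank formula
  r <- rank(x); n <- 9
  ties <- table(x)
  v0 <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  rb <- tapply(r, g, mean)
  z_exp <- function(a, b) (rb[[a]] - rb[[b]]) / sqrt(v0 * (1 / 3 + 1 / 3))
  for (i in seq_len(nrow(res))) {
    expect_equal(res$z[i], z_exp(res$group1[i], res$group2[i]),
                 tolerance = 1e-10)
  }
  # sign of z matches the mean-rank ordering
  expect_true(all(sign(res$z) ==
                    sign(mapply(function(a, b) rb[[a]] - rb[[b]],
                                res$group1, res$group2))))

  ident <- dunn_posthoc(list(c(1, 2, 3), c(1, 2, 3)), adjust_method = "none")
  expect_equal(ident$z, 0)
  expect_equal(ident$p_value, 1)

  # adjusted p never drops below raw p for any supported method
  set.seed(4)
  xx <- rnorm(30); gg <- rep(1:3, 10)
  for (m in c("BH", "bonferroni", "holm")) {
    rr <- dunn_posthoc(xx, gg, adjust_method = m)
    expect_true(all(rr$p_adjusted >= rr$p_value - 1e-12))
  }
})

test_that("screening flags planted shifts and stays order-invariant", {
  ds <- generate_cohort(recovery_spec(21))
  scr <- screen_features(ds)
  expect_equal(nrow(scr), sum(vapply(ds$layers, function(l) nrow(l$values),
                                     numeric(1))))
  # a constant feature is never significant
  ds2 <- ds
  ds2$layers$metabolite$values["met_010", ] <- 5
  scr2 <- screen_features(ds2)
  row <- scr2[scr2$feature_id == "met_010", ]
  expect_false(row$significant)
  expect_true(is.na(row$enriched_group))

  # planted LC+HCC shifts give significance with the right enrichment call
  met1 <- scr[scr$feature_id == "met_001", ]
  expect_true(met1$significant)
  expect_true(met1$enriched_group %in% c("LC", "HCC"))

  # permuting samples and features leaves results unchanged
  ds3 <- ds
  set.seed(1)
  perm <- sample(ncol(ds$layers$bacteria$values))
  ds3$layers <- lapply(ds$layers, function(l) {
    l$values <- l$values[sample(nrow(l$values)), perm, drop = FALSE]
    l
  })
  ds3$metadata <- ds$metadata[perm, ]
  ds3 <- multiomics_dataset(ds3$layers, ds3$metadata, truth = ds3$truth)
  scr3 <- screen_features(ds3)
  j <- dplyr::select(dplyr::arrange(scr, layer, feature_id), -dunn)
  j3 <- dplyr::select(dplyr::arrange(scr3, layer, feature_id), -dunn)
  expect_equal(j, j3)
})

test_that("planted single-cohort shifts are recovered with high probability", {
  hits <- vapply(1:40, function(s) {
    spec <- cohort_spec(
      layers = list(layer_spec("metabolite", 8, mean = 10, sd = 2,
                               shifts = tibble::tibble(feature = 1L, Ctrl = 0,
                                                       LC = 4, HCC = 0))),
      seed = 4000 + s)
    scr <- screen_features(generate_cohort(spec))
    row <- scr[scr$feature_id == "met_001", ]
    isTRUE(row$significant) && identical(row$enriched_group, "LC")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("summary t-test reproduces printed clinical comparisons", {
  # equal summaries give t = 0, p = 1
  eq <- t_test_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)

  expect_equal(round(t_test_from_summary(56.7, 9.8, 17, 65.2, 11.4, 18)$p_value, 3),
               0.024)
  expect_equal(round(t_test_from_summary(30.9, 3.5, 17, 43.3, 17.1, 10)$p_value, 3),
               0.007)

  # degenerate zero-variance equal-mean case
  expect_equal(t_test_from_summary(3, 0, 5, 3, 0, 5)$p_value, 1)

  tab <- summary_cohort_tests()
  expect_true(all(c("parameter", "comparison", "p_value") %in% names(tab)))
  expect_gt(nrow(tab), 10)
})

test_that("2x2 chi-square honours the continuity-correction flag", {
  prop <- matrix(c(10, 20, 5, 10), 2)  # proportional rows
  expect_equal(chi2_2x2(prop, correct = FALSE)$statistic, 0, tolerance = 1e-10)
  expect_equal(chi2_2x2(prop, correct = FALSE)$p_value, 1, tolerance = 1e-10)

  expect_equal(round(chi2_2x2(matrix(c(7, 12, 10, 6), 2),
                              correct = TRUE)$p_value, 3), 0.241)
  expect_equal(round(chi2_2x2(matrix(c(12, 6, 6, 4), 2),
                              correct = FALSE)$p_value, 3), 0.724)

  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("Mann-Whitney exact branch matches enumeration, approximate agrees", {
  ident <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_value, 1)

  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)

  # exact and normal-approximation branches agree closely at n = 8
  set.seed(12)
  diffs <- replicate(40, {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    abs(mann_whitney(x, y, exact = TRUE)$p_value -
          mann_whitney(x, y, exact = FALSE)$p_value)
  })
  expect_lt(max(diffs), 0.06)
  expect_lt(mean(diffs), 0.02)
})

test_that("two-group Kruskal-Wallis ranks cases like Mann-Whitney", {
  set.seed(8)
  agree <- replicate(50, {
    x <- rnorm(10); y <- rnorm(8, runif(1, 0, 1.5))
    kw <- kruskal_wallis(list(x, y))$p_value
    mw <- mann_whitney(x, y, exact = FALSE)$p_value
    (kw < 0.05) == (mw < 0.05)
  })
  expect_gte(mean(agree), 0.94)
})
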