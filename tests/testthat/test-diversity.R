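test_that("alpha indices match hand-evaluated fixtures", {
  # single species, uniform, and mixed vectors
  expect_equal(shannon(c(7, 0, 0)), 0)
  expect_equal(shannon(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon(c(2, 1, 1)), 1.039721, tolerance = 1e-6)

  expect_equal(simpson(c(9, 0)), 0)
  expect_equal(simpson(c(5, 5)), 0.5)
  expect_equal(simpson(c(2, 1, 1)), 0.625)
  expect_equal(simpson(c(2, 1, 1), variant = "concentration"), 0.375)

  expect_equal(chao1(c(5, 5, 5)), 3)
  expect_equal(chao1(c(1, 1, 2, 5)), 4.5)
  expect_equal(chao1(c(1, 1, 1)), 6)
  expect_equal(chao1(c(1, 1, 2, 5), bias_corrected = FALSE), 4 + 4 / 2)

  expect_equal(ace(rep(20, 4)), 4)         # no rare species
  expect_equal(ace(c(1, 1, 2, 3, 12)), 6.786667, tolerance = 1e-6)

  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(chao1(c(1.5, 2)), "integer")
})

test_that("alpha estimators agree with vegan on random count vectors", {
  set.seed(42)
  for (i in 1:25) {
    x <- rpois(60, lambda = sample(c(0.5, 2, 8), 1))
    if (sum(x) == 0) next
    ref <- vegan::estimateR(matrix(x, nrow = 1))
    expect_equal(chao1(x), unname(ref["S.chao1", 1]), tolerance = 1e-8)
    if (is.finite(ref["S.ACE", 1]) && sum(x == 1) < sum(x > 0 & x <= 10)) {
      expect_equal(ace(x), unname(ref["S.ACE", 1]), tolerance = 1e-8)
    }
    expect_equal(shannon(x), unname(vegan::diversity(x, "shannon")),
                 tolerance = 1e-10)
    expect_equal(simpson(x), unname(vegan::diversity(x, "simpson")),
                 tolerance = 1e-10)
  }
})

test_that("alpha identities and degenerate ACE handling hold", {
  set.seed(1)
  for (i in 1:200) {
    x <- rpois(40, lambda = runif(1, 0.2, 5))
    if (sum(x) == 0) next
    s_obs <- sum(x > 0)
    expect_gte(chao1(x), s_obs)
    expect_gte(shannon(x), 0)
    expect_lte(shannon(x), log(max(s_obs, 1)) + 1e-12)
    expect_gte(simpson(x), 0)
    expect_lt(simpson(x), 1)
    # scale invariance of the proportions-based indices
    expect_equal(shannon(x * 3), shannon(x))
    expect_equal(simpson(x * 3), simpson(x))
  }
  # all rare species singletons: coverage zero, falls back to chao1
  expect_warning(v <- ace(c(1, 1, 1, 50)), "Chao1")
  expect_equal(v, chao1(c(1, 1, 1, 50)))
  # adding a singleton never decreases ACE (enumerated small vectors)
  set.seed(2)
  for (i in 1:50) {
    x <- rpois(20, 2); if (sum(x) == 0 || !any(x > 0 & x <= 10)) next
    expect_gte(suppressWarnings(ace(c(x, 1))),
               suppressWarnings(ace(x)) - 1e-8)
  }
})

test_that("Bray-Curtis matches the direct formula and its range", {
  t_id <- feature_table(matrix(c(1, 2, 1, 2), 2,
                               dimnames = list(c("a", "b"), c("s1", "s2"))),
                        "bacteria", "counts")
  expect_equal(unname(bray_curtis(t_id)["s1", "s2"]), 0)

  t_disj <- feature_table(matrix(c(3, 0, 0, 4), 2,
                                 dimnames = list(c("a", "b"), c("s1", "s2"))),
                          "bacteria", "counts")
  expect_equal(unname(bray_curtis(t_disj)["s1", "s2"]), 1)

  t_mix <- feature_table(matrix(c(1, 2, 2, 1), 2,
                                dimnames = list(c("a", "b"), c("s1", "s2"))),
                         "bacteria", "counts")
  expect_equal(unname(bray_curtis(t_mix)["s1", "s2"]), 1 / 3, tolerance = 1e-9)

  ds <- generate_cohort(recovery_spec(5))
  d <- bray_curtis(ds$layers$bacteria)
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA embeds Euclidean distances exactly and orders eigenvalues", {
  # collinear points: one meaningful axis, line recovered up to reflection
  x <- c(0, 1, 2, 5)
  d <- as.matrix(dist(x)); dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- pcoa_ord(d, n_axes = 3)
  expect_equal(sum(res$eigenvalues > 1e-8), 1)
  got <- res$coordinates$Axis1
  expect_equal(abs(diff(got)), abs(diff(x)), tolerance = 1e-8)

  # random Euclidean configuration: pairwise distances reproduce d
  set.seed(3)
  pts <- matrix(rnorm(8 * 3), 8)
  d2 <- as.matrix(dist(pts))
  dimnames(d2) <- list(paste0("s", 1:8), paste0("s", 1:8))
  res2 <- pcoa_ord(d2, n_axes = 7)
  emb <- as.matrix(res2$coordinates[, -1])
  expect_lt(max(abs(as.matrix(dist(emb)) - d2)), 1e-8)
  expect_true(all(diff(res2$eigenvalues) <= 1e-8))
  expect_lte(sum(res2$explained_fraction), 1 + 1e-12)
})

test_that("PERMANOVA is calibrated under the null and powered under separation", {
  set.seed(10)
  labels <- rep(c("Ctrl", "LC", "HCC"), times = c(17, 18, 10))
  # null: iid data, p roughly uniform -> mean near 0.5 across replicates
  ps <- vapply(1:15, function(i) {
    m <- matrix(rpois(45 * 20, 20), nrow = 20,
                dimnames = list(paste0("f", 1:20), paste0("s", 1:45)))
    ft <- feature_table(m, "bacteria", "counts")
    beta_permanova(bray_curtis(ft), labels, n_perm = 199, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)

  # planted strong separation: p hits the permutation floor
  m <- matrix(rpois(45 * 20, 20), nrow = 20,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:45)))
  m[1:10, labels == "HCC"] <- m[1:10, labels == "HCC"] + 200
  ft <- feature_table(m, "bacteria", "counts")
  res <- beta_permanova(bray_curtis(ft), labels, n_perm = 999, seed = 1)
  expect_equal(res$p_value, 1 / (1 + 999))
  expect_gt(res$pseudo_F, 1)

  expect_error(beta_permanova(bray_curtis(ft), rep("Ctrl", 45)), ">= 2 groups")
})

test_that("Venn overlap counts match direct set arithmetic", {
  md <- tibble::tibble(sample_id = paste0("s", 1:6),
                       cohort = rep(c("Ctrl", "LC", "HCC"), each = 2))
  # identical presence everywhere
  m <- matrix(5, nrow = 4, ncol = 6,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
  ov <- overlap_counts(feature_table(m, "bacteria", "counts"), md)
  expect_equal(ov$shared_all, 4)
  expect_equal(sum(ov$regions$n[ov$regions$region %in%
                                  c("Ctrl", "LC", "HCC")]), 0)

  # disjoint presence
  m2 <- matrix(0, nrow = 6, ncol = 6,
               dimnames = list(paste0("f", 1:6), paste0("s", 1:6)))
  m2[1:2, 1:2] <- 3; m2[3:4, 3:4] <- 3; m2[5:6, 5:6] <- 3
  ov2 <- overlap_counts(feature_table(m2, "bacteria", "counts"), md)
  expect_equal(ov2$shared_all, 0)
  expect_equal(ov2$regions$n[ov2$regions$region == "Ctrl"], 2L)
  expect_equal(ov2$union_all, 6)

  # random presence: compare every region against brute-force set arithmetic
  set.seed(9)
  m3 <- matrix(rbinom(50 * 6, 1, 0.4) * rpois(50 * 6, 3), nrow = 50,
               dimnames = list(paste0("f", 1:50), paste0("s", 1:6)))
  m3[1, ] <- 1  # keep at least one feature present everywhere
  ov3 <- overlap_counts(feature_table(m3, "bacteria", "counts"), md)
  pres <- lapply(c("Ctrl", "LC", "HCC"), function(g) {
    rownames(m3)[rowSums(m3[, md$cohort == g, drop = FALSE] >= 1) >= 1]
  })
  names(pres) <- c("Ctrl", "LC", "HCC")
  in_set <- function(f, g) f %in% pres[[g]]
  all_f <- rownames(m3)
  expect_equal(ov3$shared_all,
               sum(in_set(all_f, "Ctrl") & in_set(all_f, "LC") &
                     in_set(all_f, "HCC")))
  only_lc <- sum(in_set(all_f, "LC") & !in_set(all_f, "Ctrl") &
                   !in_set(all_f, "HCC"))
  expect_equal(ov3$regions$n[ov3$regions$region == "LC"], only_lc)
  pairw <- ov3$pairwise[ov3$pairwise$cohort_a == "Ctrl" &
                          ov3$pairwise$cohort_b == "LC", ]
  expect_equal(pairw$shared, sum(in_set(all_f, "Ctrl") & in_set(all_f, "LC")))
  expect_equal(pairw$union_size, length(union(pres$Ctrl, pres$LC)))
  # inclusion-exclusion: the 7 region counts sum to the union size
  expect_equal(sum(ov3$regions$n), ov3$union_all)
})
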