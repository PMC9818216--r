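test_that("Pearson r and p match hand-evaluated cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_p(x, 2 * x + 1)$p_value, 0)

  res <- pearson_with_p(x, c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-10)
  t_exp <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(res$p_value, 2 * pt(-t_exp, 2), tolerance = 1e-10)
  expect_equal(res$n, 4)

  # exactly orthogonal input: r = 0, p = 1
  y <- c(1, -1, -1, 1)
  expect_equal(pearson_with_p(x, y)$r, 0)
  expect_equal(pearson_with_p(x, y)$p_value, 1)

  expect_warning(out <- pearson_with_p(x, rep(2, 4)), "constant")
  expect_true(is.na(out$r))
  expect_error(pearson_with_p(1:2, 1:2), "n >= 3")

  # cross-check against cor.test on random data
  set.seed(6)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    ct <- cor.test(a, b)
    got <- pearson_with_p(a, b)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
  }
})

test_that("candidate set equals the significant screen rows", {
  ds <- generate_cohort(recovery_spec(17))
  scr <- screen_features(ds)
  cand <- candidate_set(scr)
  sig <- scr[scr$significant, c("layer", "feature_id")]
  expect_setequal(paste(cand$layer, cand$feature_id),
                  paste(sig$layer, sig$feature_id))

  none <- scr; none$significant <- FALSE
  expect_equal(nrow(candidate_set(none)), 0)
  expect_equal(nrow(build_network(ds, candidate_set(none))), 0)
})

test_that("edge construction respects thresholds, subsets and canonical order", {
  ds <- generate_cohort(recovery_spec(19))
  cand <- candidate_set(screen_features(ds))
  edges <- build_network(ds, cand, subset = "ALL")
  expect_true(all(edges$p_value < 0.05))
  expect_true(all(abs(edges$r) <= 1))
  expect_equal(unique(edges$n), 45)
  # each unordered pair at most once
  key <- paste(edges$layer_a, edges$feature_a, edges$layer_b, edges$feature_b)
  expect_false(any(duplicated(key)))
  expect_true(all(paste(edges$layer_a, edges$feature_a) <
                    paste(edges$layer_b, edges$feature_b)))

  sub <- build_network(ds, cand, subset = "LC_HCC")
  expect_equal(unique(sub$n), 28)

  expect_equal(nrow(build_network(ds, cand, r_min = 1.0)), 0)

  # constant candidate columns are dropped with a warning
  ds2 <- ds
  ds2$layers$metabolite$values["met_002", ] <- 7
  cand2 <- dplyr::bind_rows(cand,
                            tibble::tibble(layer = "metabolite",
                                           feature_id = "met_002"))
  expect_warning(build_network(ds2, cand2), "constant")
})

test_that("null features connect at about the nominal edge rate", {
  ds <- generate_cohort(null_spec(23, n_features = 60))
  cand <- tibble::tibble(layer = "metabolite",
                         feature_id = sprintf("met_%03d", 1:60))
  edges <- build_network(ds, cand, alpha_edge = 0.05)
  rate <- nrow(edges) / choose(60, 2)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("planted star edges are recovered at defaults", {
  found <- vapply(1:20, function(s) {
    ds <- generate_cohort(recovery_spec(300 + s))
    cand <- tibble::tibble(
      layer = c("bacteria", "virus", "metabolite", "cytokine"),
      feature_id = c("bact_001", "vir_001", "met_001", "cyt_001"))
    edges <- build_network(ds, cand)
    key <- paste(edges$feature_a, edges$feature_b)
    all(c("bact_001 vir_001", "bact_001 met_001", "bact_001 cyt_001") %in%
          key | c("vir_001 bact_001", "met_001 bact_001",
                  "cyt_001 bact_001") %in% key)
  }, logical(1))
  expect_gte(mean(found), 0.95)
})

test_that("star extraction matches a brute-force recount and is monotone", {
  edges <- random_edges(12, 0.3, seed = 1)
  stars <- extract_stars(edges, min_layers = 3)
  # brute force: for every node, collect incident edges and count layers
  nodes <- unique(c(paste(edges$layer_a, edges$feature_a, sep = "|"),
                    paste(edges$layer_b, edges$feature_b, sep = "|")))
  brute <- Filter(Negate(is.null), lapply(nodes, function(nd) {
    parts <- strsplit(nd, "|", fixed = TRUE)[[1]]
    inc <- edges[(edges$feature_a == parts[2] & edges$layer_a == parts[1]) |
                   (edges$feature_b == parts[2] & edges$layer_b == parts[1]), ]
    if (nrow(inc) == 0) return(NULL)
    nb <- ifelse(inc$feature_a == parts[2], inc$layer_b, inc$layer_a)
    if (length(unique(c(parts[1], nb))) >= 3) parts[2] else NULL
  }))
  expect_setequal(stars$center, unlist(brute))

  # a center whose neighbors span only two layers fails min_layers = 4
  e2 <- tibble::tibble(
    feature_a = c("b1", "b1"), layer_a = c("bacteria", "bacteria"),
    feature_b = c("v1", "v2"), layer_b = c("virus", "virus"),
    r = c(0.9, 0.8), p_value = c(0.001, 0.002), n = 45L, subset = "ALL")
  expect_equal(nrow(extract_stars(e2, min_layers = 4)), 0)
  expect_equal(nrow(extract_stars(e2, min_layers = 2)), 3)

  # center-inclusive coverage: bacteria center + 3 other layers qualifies
  e3 <- tibble::tibble(
    feature_a = rep("b1", 3), layer_a = rep("bacteria", 3),
    feature_b = c("v1", "m1", "c1"),
    layer_b = c("virus", "metabolite", "cytokine"),
    r = 0.9, p_value = 0.001, n = 45L, subset = "ALL")
  s3 <- extract_stars(e3, min_layers = 4)
  expect_equal(s3$center, "b1")
  expect_equal(s3$coverage, 4L)
  # exclusive reading: neighbors alone span only 3 layers
  expect_equal(nrow(extract_stars(e3, min_layers = 4,
                                  include_center = FALSE)), 0)

  # removing an edge never adds a retained star
  set.seed(2)
  for (i in 1:10) {
    e <- random_edges(15, 0.25, seed = 100 + i)
    full <- extract_stars(e, min_layers = 3)$center
    drop1 <- extract_stars(e[-sample(nrow(e), 1), ], min_layers = 3)$center
    expect_true(all(drop1 %in% full))
  }

  # invariance to edge insertion order
  e <- random_edges(15, 0.3, seed = 77)
  s_a <- extract_stars(e, min_layers = 3)
  s_b <- extract_stars(e[sample(nrow(e)), ], min_layers = 3)
  expect_equal(s_a$center, s_b$center)
  expect_equal(s_a$coverage, s_b$coverage)
})

test_that("membership across subsets marks every analysis a center appears in", {
  mk <- function(centers, layers, subset) {
    tibble::tibble(center = centers, center_layer = layers,
                   n_neighbors = 3L, coverage = 4L, layers = "x",
                   subset = subset, neighbors = list(tibble::tibble()))
  }
  mem <- star_membership(list(
    ALL = mk(c("A", "B"), c("bacteria", "virus"), "ALL"),
    CTRL_LC = mk("A", "bacteria", "CTRL_LC"),
    LC_HCC = mk("C", "cytokine", "LC_HCC")
  ))
  expect_equal(nrow(mem), 3)
  a <- mem[mem$center == "A", ]
  expect_true(a$ALL && a$CTRL_LC && !a$CTRL_HCC && !a$LC_HCC)
  c_ <- mem[mem$center == "C", ]
  expect_true(!c_$ALL && c_$LC_HCC)
  expect_error(star_membership(list(BAD = mk("A", "bacteria", "BAD"))),
               "unknown subset")
})
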