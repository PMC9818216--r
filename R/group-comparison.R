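#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' (`stats::kruskal.test` under the hood). The degenerate case where every
#' observation is identical (tie correction zero) is defined as H = 0,
#' p = 1.
#'
#' @param x Numeric vector of observations, or a list of per-group vectors
#'   (in which case `g` is ignored).
#' @param g Group labels, same length as `x`.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(x, g = NULL) {
  xg <- as_groups(x, g)
  if (length(unique(xg$x)) == 1) {
    return(tibble::tibble(statistic = 0, df = nlevels(xg$g) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(xg$x, xg$g)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = min(max(kt$p.value, .Machine$double.xmin), 1))
}

as_groups <- function(x, g) {
  if (is.list(x)) {
    g <- rep(seq_along(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  if (is.null(g)) stop("group labels required", call. = FALSE)
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tabulate(g) == 0)) stop("empty group", call. = FALSE)
  list(x = x, g = droplevels(g))
}

#' Dunn's post hoc pairwise rank comparisons
#'
#' Follows a Kruskal-Wallis test: on the pooled ranking, for groups j and k
#' \deqn{z_{jk} = (\bar R_j - \bar R_k) /
#'   \sqrt{[N(N+1)/12 - \sum(t^3 - t)/(12(N-1))] (1/n_j + 1/n_k)}}
#' with t running over tie-group sizes. Two-sided normal p-values are
#' adjusted across the pairs; the adjustment defaults to Benjamini-Hochberg
#' (the motivating analysis reports "adjusted p" without naming the method).
#'
#' @param x,g As in [kruskal_wallis()].
#' @param adjust_method One of `"BH"`, `"bonferroni"`, `"holm"`, `"none"`.
#' @return Tibble with one row per pair: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(x, g = NULL,
                         adjust_method = c("BH", "bonferroni", "holm", "none")) {
  adjust_method <- match.arg(adjust_method)
  xg <- as_groups(x, g)
  x <- xg$x; g <- xg$g
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tabulate(g)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(levels(g), 2)
  z <- apply(pairs, 2, function(p) {
    j <- match(p[1], levels(g)); k <- match(p[2], levels(g))
    denom <- sqrt(v0 * (1 / ns[j] + 1 / ns[k]))
    if (denom == 0) return(0)
    (rbar[[p[1]]] - rbar[[p[2]]]) / denom
  })
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ], z = z,
    p_value = p, p_adjusted = stats::p.adjust(p, method = adjust_method)
  )
}

#' Screen every feature of every layer for cohort differences
#'
#' For each feature: a Kruskal-Wallis test across the cohorts in `subset`,
#' followed by Dunn's post hoc pairs. A feature is `significant` when its KW
#' p-value is below `alpha` and at least one Dunn-adjusted pair is too; the
#' `enriched_group` of a significant feature is the cohort with the maximal
#' group mean (medians by flag) on the analyzed scale. Count layers are
#' converted to relative abundance before testing (the scale the abundance
#' heatmaps compare); set `transform_counts = FALSE` to test raw counts.
#'
#' @param dataset A `multiomics_dataset`.
#' @param alpha Significance level (default 0.05).
#' @param adjust_method Dunn adjustment, see [dunn_posthoc()].
#' @param subset Subject subset: `"ALL"` (default) or one of `"CTRL_LC"`,
#'   `"CTRL_HCC"`, `"LC_HCC"` for two-cohort screening.
#' @param center `"mean"` (default) or `"median"` for the enrichment call.
#' @param transform_counts Convert count layers to relative abundance first.
#' @return Tibble with one row per feature: `layer`, `feature_id`,
#'   `kw_stat`, `kw_p`, `significant`, `enriched_group`, and a `dunn`
#'   list-column of per-pair results.
#' @export
screen_features <- function(dataset, alpha = 0.05,
                            adjust_method = c("BH", "bonferroni", "holm", "none"),
                            subset = "ALL", center = c("mean", "median"),
                            transform_counts = TRUE) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  adjust_method <- match.arg(adjust_method)
  center <- match.arg(center)
  cohorts <- subset_cohorts(subset)
  keep <- dataset$metadata$cohort %in% cohorts
  md <- dataset$metadata[keep, , drop = FALSE]
  g <- droplevels(md$cohort)
  cfun <- if (center == "mean") mean else stats::median

  purrr::map_dfr(dataset$layers, function(layer) {
    if (layer$semantics == "counts" && transform_counts) {
      layer <- to_relative_abundance(layer)
    }
    v <- layer$values[, md$sample_id, drop = FALSE]
    purrr::map_dfr(seq_len(nrow(v)), function(i) {
      x <- v[i, ]
      kw <- kruskal_wallis(x, g)
      dunn <- dunn_posthoc(x, g, adjust_method = adjust_method)
      sig <- kw$p_value < alpha && any(dunn$p_adjusted < alpha)
      enriched <- if (sig) {
        centers <- tapply(x, g, cfun)
        names(centers)[which.max(centers)]
      } else {
        NA_character_
      }
      tibble::tibble(
        layer = layer$layer_id, feature_id = rownames(v)[i],
        kw_stat = kw$statistic, kw_p = kw$p_value,
        significant = sig, enriched_group = enriched,
        dunn = list(dunn)
      )
    })
  })
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sided Student t-test computed from printed
#' mean / SD / n per group — the form needed to recompute a clinical
#' characteristics table without subject-level data. When both SDs are zero
#' and the means are equal, t is taken as 0 with p = 1.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group a (`n_a >= 2`,
#'   `sd_a >= 0`).
#' @param mean_b,sd_b,n_b Summary statistics of group b.
#' @return One-row tibble: `t`, `df`, `p_value`.
#' @examples
#' t_test_from_summary(56.7, 9.8, 17, 65.2, 11.4, 18)  # p = 0.024
#' @export
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  if (se == 0) {
    t <- if (mean_a == mean_b) 0 else sign(mean_a - mean_b) * Inf
  } else {
    t <- (mean_a - mean_b) / se
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  tibble::tibble(t = t, df = df, p_value = max(p, .Machine$double.xmin))
}

#' Chi-square test for a 2x2 table
#'
#' Wraps `stats::chisq.test` with df = 1. Yates continuity correction is on
#' by default; disable with `correct = FALSE`. (Published clinical tables
#' are not always consistent about the correction — both variants are
#' exposed.)
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @param correct Apply the continuity correction (default TRUE).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi2_2x2 <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("2x2 table has a zero margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic), df = 1L,
                 p_value = unname(ct$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. With at most `exact_max` observations per side
#' (default 8) the p-value comes from full enumeration of all group
#' assignments of the pooled values (tie-aware): the two-sided p is the
#' probability of a U at least as far from its null mean as observed.
#' Larger samples use the continuity-corrected normal approximation with
#' tie-corrected variance.
#'
#' @param x,y Nonempty numeric vectors.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   `NULL` (default) decides by sample size.
#' @param exact_max Per-side size ceiling for the automatic exact branch.
#' @return One-row tibble: `statistic` (U for the first sample), `p_value`,
#'   `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
mann_whitney <- function(x, y, exact = NULL, exact_max = 8) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  use_exact <- if (is.null(exact)) n1 <= exact_max && n2 <= exact_max else exact
  if (use_exact) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u1 - mu) - 1e-9)
  } else {
    ties <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      # continuity-corrected normal approximation
      z <- max(abs(u1 - mu) - 0.5, 0) / sqrt(sigma2)
      p <- min(2 * stats::pnorm(-z), 1)
    }
  }
  tibble::tibble(statistic = u1, p_value = p, exact = use_exact)
}

#' Recompute a clinical characteristics table from summary statistics
#'
#' Applies [t_test_from_summary()] to every pairwise comparison available in
#' a summary table of per-cohort mean / SD / n. The packaged fixture
#' (`system.file("extdata", "table1_summary.tsv", package = "omicstar")`)
#' transcribes the normally-distributed clinical parameters of the
#' motivating study's cohort-characteristics table.
#'
#' @param summary_tbl Tibble with columns `parameter`, then
#'   `<cohort>_mean`, `<cohort>_sd`, `<cohort>_n` for cohorts `ctrl`, `lc`,
#'   `hcc` (NA where a cohort was not measured). Default: packaged fixture.
#' @return Tibble: `parameter`, `comparison`, `t`, `df`, `p_value`.
#' @export
summary_cohort_tests <- function(summary_tbl = NULL) {
  if (is.null(summary_tbl)) {
    summary_tbl <- readr::read_tsv(
      system.file("extdata", "table1_summary.tsv", package = "omicstar"),
      show_col_types = FALSE, progress = FALSE
    )
  }
  pairs <- list(c("ctrl", "lc"), c("ctrl", "hcc"), c("lc", "hcc"))
  purrr::map_dfr(seq_len(nrow(summary_tbl)), function(i) {
    row <- summary_tbl[i, ]
    purrr::map_dfr(pairs, function(p) {
      a <- paste0(p[1], c("_mean", "_sd", "_n"))
      b <- paste0(p[2], c("_mean", "_sd", "_n"))
      if (anyNA(c(row[[a[1]]], row[[b[1]]]))) return(NULL)
      res <- t_test_from_summary(row[[a[1]]], row[[a[2]]], row[[a[3]]],
                                 row[[b[1]]], row[[b[2]]], row[[b[3]]])
      tibble::tibble(parameter = row$parameter,
                     comparison = paste(toupper(p[1]), toupper(p[2]), sep = "-"),
                     t = res$t, df = res$df, p_value = res$p_value)
    })
  })
}
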