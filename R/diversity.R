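#' Alpha-diversity indices
#'
#' Within-sample diversity of a count vector. `shannon()` is
#' \eqn{H = -\sum_{p_i>0} p_i \ln p_i} in natural-log units; `simpson()`
#' defaults to the Gini-Simpson complement \eqn{1 - \sum p_i^2} (the
#' `concentration` variant returns \eqn{\sum p_i^2}); `chao1()` is the
#' bias-corrected richness estimator
#' \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))} (classic form
#' \eqn{S_{obs} + F_1^2/(2F_2)} by flag); `ace()` is the abundance-based
#' coverage estimator with rare/abundant cut at `rare_threshold` reads.
#'
#' ACE degenerate cases: when every rare species is a singleton the sample
#' coverage is zero and the estimator is undefined — `ace()` falls back to
#' `chao1()` with a warning; with at most one rare read it returns observed
#' richness.
#'
#' @param counts Nonnegative count vector (integers for `chao1`/`ace`).
#' @param variant For `simpson()`: `"gini_simpson"` (default) or
#'   `"concentration"`.
#' @param bias_corrected Use the bias-corrected Chao1 form (default TRUE).
#' @param rare_threshold ACE rare/abundant boundary (default 10 reads).
#' @return A single numeric value.
#' @examples
#' shannon(c(5, 5, 5, 5))   # log(4)
#' simpson(c(2, 1, 1))      # 0.625
#' chao1(c(1, 1, 2, 5))     # 4.5
#' @export
shannon <- function(counts) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' @rdname shannon
#' @export
simpson <- function(counts, variant = c("gini_simpson", "concentration")) {
  variant <- match.arg(variant)
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  d <- sum(p^2)
  if (variant == "gini_simpson") 1 - d else d
}

#' @rdname shannon
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  check_counts(counts, integer = TRUE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    # classic form undefined at F2 = 0; use the bias-corrected term there
    s_obs + f1 * (f1 - 1) / 2
  }
}

#' @rdname shannon
#' @export
ace <- function(counts, rare_threshold = 10) {
  check_counts(counts, integer = TRUE)
  s_obs <- sum(counts > 0)
  rare <- counts[counts > 0 & counts <= rare_threshold]
  s_abund <- sum(counts > rare_threshold)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  if (s_rare == 0) return(s_obs)
  if (n_rare <= 1) return(s_obs)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("ACE undefined (all rare species are singletons); using Chao1",
            call. = FALSE)
    return(chao1(counts))
  }
  f <- tabulate(rare, nbins = rare_threshold)
  i <- seq_len(rare_threshold)
  gamma2 <- max(s_rare * sum(i * (i - 1) * f) /
                  (c_ace * n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

check_counts <- function(counts, integer = FALSE) {
  if (!is.numeric(counts) || any(counts < 0)) {
    stop("counts must be a nonnegative numeric vector", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all-zero count vector", call. = FALSE)
  if (integer && any(abs(counts - round(counts)) > 1e-8)) {
    stop("estimator requires integer counts", call. = FALSE)
  }
  invisible(counts)
}

#' Per-sample alpha diversity of a count layer
#'
#' @param table A `feature_table` with `counts` semantics.
#' @param metadata Optional metadata tibble; when given, the sample's cohort
#'   is joined in.
#' @return A tibble with one row per sample: `sample_id`, `observed`,
#'   `shannon`, `simpson`, `chao1`, `ace` (plus `cohort` when metadata is
#'   supplied).
#' @export
alpha_diversity <- function(table, metadata = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (table$semantics != "counts") {
    stop("alpha_diversity() expects a counts table", call. = FALSE)
  }
  v <- table$values
  out <- tibble::tibble(
    sample_id = colnames(v),
    observed = apply(v, 2, function(x) sum(x > 0)),
    shannon = apply(v, 2, shannon),
    simpson = apply(v, 2, simpson),
    chao1 = apply(v, 2, chao1),
    ace = apply(v, 2, function(x) suppressWarnings(ace(x)))
  )
  if (!is.null(metadata)) {
    out <- dplyr::left_join(out,
                            dplyr::select(validate_metadata(metadata),
                                          "sample_id", "cohort"),
                            by = "sample_id")
  }
  out
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to a common depth.
#' Off by default everywhere in the pipeline: the motivating workflow does
#' not rarefy, and depth normalisation is left to the caller.
#'
#' @param table A counts `feature_table`.
#' @param depth Target depth; defaults to the minimum sample total.
#' @param seed Integer seed.
#' @return A rarefied counts `feature_table`.
#' @export
rarefy_counts <- function(table, depth = NULL, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), table$semantics == "counts")
  v <- table$values
  if (is.null(depth)) depth <- min(colSums(v))
  if (any(colSums(v) < depth)) stop("sample shallower than target depth",
                                    call. = FALSE)
  with_preserved_seed(seed, {
    out <- apply(v, 2, function(x) {
      picked <- sample(rep.int(seq_along(x), x), depth)
      tabulate(picked, nbins = length(x))
    })
    dimnames(out) <- dimnames(v)
    feature_table(out, table$layer_id, "counts", table$units)
  })
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} over feature
#' vectors of two samples (computed via \pkg{vegan}). Bray-Curtis is not a
#' metric (the triangle inequality may fail); entries lie in \[0, 1\].
#'
#' @param table A `feature_table` (counts or relative abundance).
#' @return A `distance_matrix`: symmetric matrix with zero diagonal and
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  if (ncol(v) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(colSums(v) == 0)) {
    stop("all-zero sample column: Bray-Curtis undefined", call. = FALSE)
  }
  m <- as.matrix(vegan::vegdist(t(v), method = "bray"))
  structure(m, class = c("distance_matrix", class(m)))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower-centers \eqn{-d^2/2} and eigendecomposes it; coordinates are
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Negative eigenvalues — routine for Bray-Curtis input — are kept in
#' `eigenvalues` but excluded from coordinates and from the explained
#' fractions.
#'
#' @param d A `distance_matrix` (or square symmetric matrix / `dist`).
#' @param n_axes Number of axes to return (capped at the number of positive
#'   eigenvalues).
#' @return An object of class `pcoa_result` with `coordinates` (tibble:
#'   `sample_id`, `Axis1`, ...), `eigenvalues`, and `explained_fraction`.
#' @export
pcoa_ord <- function(d, n_axes = 2) {
  m <- as.matrix(d)
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  ids <- rownames(m)
  n <- nrow(m)
  # negative eigenvalues are routine for non-Euclidean input; cmdscale warns
  cmd <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1,
                                          eig = TRUE))
  eig <- cmd$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  k <- min(n_axes, length(pos))
  coords <- cmd$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(
    coordinates = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                   tibble::as_tibble(coords)),
    eigenvalues = eig,
    explained_fraction = eig[pos] / sum(eig[pos]),
    n_axes = k
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d axes (%.1f%%, %.1f%% explained)\n",
              nrow(x$coordinates), x$n_axes,
              100 * x$explained_fraction[1],
              if (x$n_axes > 1) 100 * x$explained_fraction[2] else NA))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' @rdname tidy
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_positive_eig = sum(x$eigenvalues > 0),
    n_negative_eig = sum(x$eigenvalues < 0),
    explained_axis1 = x$explained_fraction[1],
    explained_axis2 = if (length(x$explained_fraction) > 1) {
      x$explained_fraction[2]
    } else {
      NA_real_
    }
  )
}

#' PERMANOVA test of group separation on a distance matrix
#'
#' Permutational multivariate analysis of variance (via
#' \pkg{vegan}'s `adonis2`) with permutation p-value
#' \eqn{p = (1 + \#\{F^{perm} \ge F\}) / (1 + n_{perm})}. Used here as the
#' significance test for beta-diversity ordination spacing.
#'
#' @param d A `distance_matrix`.
#' @param labels Group label per sample (in `d`'s sample order), or a
#'   metadata tibble with `sample_id` and `cohort`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A one-row tibble: `pseudo_F`, `r_squared`, `df`, `p_value`,
#'   `n_perm`.
#' @export
beta_permanova <- function(d, labels, n_perm = 999, seed = 1L) {
  m <- as.matrix(d)
  if (is.data.frame(labels)) {
    labels <- labels$cohort[match(rownames(m), labels$sample_id)]
  }
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  df <- data.frame(group = labels)
  fit <- with_preserved_seed(seed, {
    vegan::adonis2(stats::as.dist(m) ~ group, data = df,
                   permutations = n_perm)
  })
  tibble::tibble(
    pseudo_F = fit$F[1], r_squared = fit$R2[1], df = fit$Df[1],
    p_value = fit$`Pr(>F)`[1], n_perm = n_perm
  )
}

#' Venn overlap of features present per cohort
#'
#' A feature counts as "present" in a cohort when at least `min_count` reads
#' are observed in at least `min_prevalence` of the cohort's samples. Counts
#' are reported for every Venn region plus the pairwise "shared X of Y"
#' summaries.
#'
#' @param table A counts `feature_table`.
#' @param metadata Metadata tibble (`sample_id`, `cohort`).
#' @param min_count Presence threshold per sample (default 1 read).
#' @param min_prevalence Minimum number of qualifying samples (default 1).
#' @return A list of class `overlap_counts`: `regions` (tibble `region`,
#'   `n`), `pairwise` (tibble `cohort_a`, `cohort_b`, `shared`, `union_size`),
#'   `shared_all`, `union_all`, and `presence` (logical matrix).
#' @export
overlap_counts <- function(table, metadata, min_count = 1, min_prevalence = 1) {
  stopifnot(inherits(table, "feature_table"))
  metadata <- validate_metadata(metadata)
  coh <- metadata$cohort[match(colnames(table$values), metadata$sample_id)]
  if (anyNA(coh)) stop("samples missing from metadata", call. = FALSE)
  groups <- levels(droplevels(coh))
  presence <- vapply(groups, function(g) {
    rowSums(table$values[, coh == g, drop = FALSE] >= min_count) >=
      min_prevalence
  }, logical(nrow(table$values)))
  sets <- apply(presence, 1, function(row) paste(groups[row], collapse = "&"))
  combos <- unlist(lapply(seq_along(groups), function(k) {
    utils::combn(groups, k, paste, collapse = "&")
  }))
  regions <- tibble::tibble(
    region = combos,
    n = vapply(combos, function(r) sum(sets == r), integer(1),
               USE.NAMES = FALSE)
  )
  pairs <- utils::combn(groups, 2)
  pairwise <- tibble::tibble(
    cohort_a = pairs[1, ], cohort_b = pairs[2, ],
    shared = apply(pairs, 2, function(p) sum(presence[, p[1]] & presence[, p[2]])),
    union_size = apply(pairs, 2, function(p) sum(presence[, p[1]] | presence[, p[2]]))
  )
  structure(list(
    regions = regions, pairwise = pairwise,
    shared_all = sum(rowSums(presence) == length(groups)),
    union_all = sum(rowSums(presence) > 0),
    presence = presence
  ), class = "overlap_counts")
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat(sprintf("<overlap_counts> shared by all: %d of %d\n",
              x$shared_all, x$union_all))
  print(x$regions)
  invisible(x)
}
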