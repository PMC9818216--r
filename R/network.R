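#' Pearson correlation with a t-based p-value
#'
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n - 2 degrees of freedom,
#' two-sided. A constant vector makes the correlation undefined: the result
#' is reported as missing (NA, not zero) with a warning.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined", call. = FALSE)
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) {
    0
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t), n - 2)
  }
  tibble::tibble(r = r, p_value = p, n = n)
}

#' Candidate features for the joint correlation analysis
#'
#' The candidate list is exactly the set of features called significant by
#' [screen_features()] on the relevant subject subset, deduplicated and
#' layer-tagged — the markers with cohort differences in any of the four
#' omics layers.
#'
#' @param screen Tibble returned by [screen_features()].
#' @return Tibble: `layer`, `feature_id` of significant features.
#' @export
candidate_set <- function(screen) {
  dplyr::distinct(
    dplyr::select(dplyr::filter(screen, .data$significant),
                  "layer", "feature_id")
  )
}

#' Build the joint Pearson correlation network
#'
#' Correlates every pair of candidate features — across all four layers — on
#' the samples of a subject subset, keeping edges with `p < alpha_edge` and
#' `|r| >= r_min`. Count layers enter on the relative-abundance scale;
#' concentrations on their measurement scale (optionally
#' `log10(x + pseudocount)` for abundance layers). P-values are unadjusted
#' by default (`adjust = "BH"` for the conservative variant). Constant
#' candidate columns are dropped with a warning.
#'
#' @param dataset A `multiomics_dataset`.
#' @param candidates Tibble with `layer`, `feature_id` (see
#'   [candidate_set()]).
#' @param subset One of `"ALL"`, `"CTRL_LC"`, `"CTRL_HCC"`, `"LC_HCC"`.
#' @param alpha_edge Edge p-value threshold (default 0.05).
#' @param r_min Minimum |r| (default 0).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param log_abundance Log10-transform abundance layers before correlating.
#' @param pseudocount Pseudocount for the log transform (default 1e-6, on
#'   the relative-abundance scale).
#' @return Edge tibble: `feature_a`, `layer_a`, `feature_b`, `layer_b`,
#'   `r`, `p_value`, `n`, `subset`, each unordered pair at most once.
#' @export
build_network <- function(dataset, candidates, subset = "ALL",
                          alpha_edge = 0.05, r_min = 0,
                          adjust = c("none", "BH"),
                          log_abundance = FALSE, pseudocount = 1e-6) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  adjust <- match.arg(adjust)
  subset <- match.arg(subset, SUBSET_IDS)
  candidates <- dplyr::distinct(tibble::as_tibble(candidates)[, c("layer", "feature_id")])
  if (nrow(candidates) == 0) {
    return(empty_edges(subset))
  }
  keep <- dataset$metadata$cohort %in% subset_cohorts(subset)
  ids <- dataset$metadata$sample_id[keep]
  if (length(ids) < 4) stop("subset has fewer than 4 samples", call. = FALSE)

  mats <- lapply(split(candidates, candidates$layer), function(cand) {
    layer <- dataset$layers[[cand$layer[1]]]
    if (is.null(layer)) stop("candidate layer absent: ", cand$layer[1],
                             call. = FALSE)
    if (layer$semantics == "counts") {
      layer <- to_relative_abundance(layer)
      if (log_abundance) layer$values <- log10(layer$values + pseudocount)
    }
    miss <- setdiff(cand$feature_id, rownames(layer$values))
    if (length(miss) > 0) stop("candidate feature absent: ", miss[1],
                               call. = FALSE)
    m <- t(layer$values[cand$feature_id, ids, drop = FALSE])
    colnames(m) <- paste(cand$layer[1], cand$feature_id, sep = "\r")
    m
  })
  x <- do.call(cbind, mats)
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant candidate column(s)", sum(const)),
            call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) return(empty_edges(subset))

  n <- nrow(x)
  r <- stats::cor(x)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0

  idx <- which(upper.tri(r), arr.ind = TRUE)
  key_a <- colnames(x)[idx[, 1]]
  key_b <- colnames(x)[idx[, 2]]
  split_key <- function(k, i) vapply(strsplit(k, "\r", fixed = TRUE), `[[`,
                                     character(1), i)
  edges <- tibble::tibble(
    feature_a = split_key(key_a, 2), layer_a = split_key(key_a, 1),
    feature_b = split_key(key_b, 2), layer_b = split_key(key_b, 1),
    r = r[idx], p_value = p[idx], n = n, subset = subset
  )
  if (adjust == "BH") edges$p_value <- stats::p.adjust(edges$p_value, "BH")
  # canonical undirected ordering: (layer, feature) of a sorts before b
  swap <- paste(edges$layer_a, edges$feature_a) >
    paste(edges$layer_b, edges$feature_b)
  if (any(swap)) {
    tmp <- edges[swap, c("feature_a", "layer_a")]
    edges[swap, c("feature_a", "layer_a")] <-
      edges[swap, c("feature_b", "layer_b")]
    edges[swap, c("feature_b", "layer_b")] <- tmp
  }
  dplyr::arrange(
    dplyr::filter(edges, .data$p_value < alpha_edge, abs(.data$r) >= r_min),
    .data$layer_a, .data$feature_a, .data$layer_b, .data$feature_b
  )
}

empty_edges <- function(subset) {
  tibble::tibble(
    feature_a = character(), layer_a = character(),
    feature_b = character(), layer_b = character(),
    r = numeric(), p_value = numeric(), n = integer(),
    subset = if (length(subset)) character() else character()
  )
}

#' Extract star (ego) subnetworks spanning multiple omics layers
#'
#' A "network centered on X" is the star of X: the center plus every feature
#' directly connected to it by a retained correlation edge. Stars are kept
#' when their layer coverage — the set of layers of the center and its
#' neighbors — has at least `min_layers` members. The center's own layer
#' counts toward coverage by default (`include_center = FALSE` for the
#' stricter reading where neighbors alone must span the remaining layers).
#'
#' @param edges Edge tibble from [build_network()].
#' @param min_layers Minimum layer coverage (default 4, i.e. all layers).
#' @param include_center Count the center's layer toward coverage.
#' @return Tibble with one row per retained star: `center`, `center_layer`,
#'   `n_neighbors`, `coverage` (number of layers), `layers` (comma-joined),
#'   `subset`, and a `neighbors` list-column of the incident edges.
#' @export
extract_stars <- function(edges, min_layers = 4, include_center = TRUE) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0) {
    return(tibble::tibble(center = character(), center_layer = character(),
                          n_neighbors = integer(), coverage = integer(),
                          layers = character(), subset = character(),
                          neighbors = list()))
  }
  nodes <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(center = edges$feature_a, center_layer = edges$layer_a),
    tibble::tibble(center = edges$feature_b, center_layer = edges$layer_b)
  ))
  stars <- purrr::map_dfr(seq_len(nrow(nodes)), function(i) {
    f <- nodes$center[i]; l <- nodes$center_layer[i]
    inc <- edges[(edges$feature_a == f & edges$layer_a == l) |
                   (edges$feature_b == f & edges$layer_b == l), ]
    nb_layers <- ifelse(inc$feature_a == f & inc$layer_a == l,
                        inc$layer_b, inc$layer_a)
    cov <- unique(if (include_center) c(l, nb_layers) else nb_layers)
    tibble::tibble(
      center = f, center_layer = l, n_neighbors = nrow(inc),
      coverage = length(cov),
      layers = paste(sort(cov), collapse = ","),
      subset = inc$subset[1],
      neighbors = list(inc)
    )
  })
  out <- dplyr::filter(stars, .data$coverage >= min_layers)
  dplyr::arrange(out, .data$center_layer, .data$center)
}

#' Star-center membership across the four subject-subset analyses
#'
#' @param stars_by_subset Named list of [extract_stars()] results, names
#'   among `ALL`, `CTRL_LC`, `CTRL_HCC`, `LC_HCC` (missing subsets count as
#'   all-FALSE).
#' @return Membership tibble: `center`, `center_layer`, and logical columns
#'   `ALL`, `CTRL_LC`, `CTRL_HCC`, `LC_HCC`.
#' @export
star_membership <- function(stars_by_subset) {
  stopifnot(is.list(stars_by_subset))
  bad <- setdiff(names(stars_by_subset), SUBSET_IDS)
  if (length(bad) > 0) stop("unknown subset id: ", bad[1], call. = FALSE)
  centers <- dplyr::distinct(dplyr::bind_rows(
    lapply(stars_by_subset, function(s) s[, c("center", "center_layer")])
  ))
  if (nrow(centers) == 0) {
    return(tibble::tibble(center = character(), center_layer = character(),
                          ALL = logical(), CTRL_LC = logical(),
                          CTRL_HCC = logical(), LC_HCC = logical()))
  }
  for (s in SUBSET_IDS) {
    tbl <- stars_by_subset[[s]]
    centers[[s]] <- if (is.null(tbl) || nrow(tbl) == 0) {
      FALSE
    } else {
      paste(centers$center, centers$center_layer) %in%
        paste(tbl$center, tbl$center_layer)
    }
  }
  dplyr::arrange(centers, .data$center_layer, .data$center)
}
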