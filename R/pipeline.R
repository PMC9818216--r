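#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default.
#' Thresholds live in (0, 1); the single seed drives every stochastic stage
#' through a documented splitting scheme (`stage seed = seed + fixed
#' offset`), so stages can be rerun in isolation reproducibly.
#'
#' @param alpha_screen Feature-screening level (default 0.05).
#' @param alpha_edge Correlation-edge p threshold (default 0.05).
#' @param r_min Minimum |r| for an edge (default 0).
#' @param dunn_adjust Dunn adjustment method (default `"BH"`).
#' @param min_mean_rel_abund Prevalence filter threshold (default 1e-4).
#' @param min_layers Star layer-coverage requirement (default 4).
#' @param include_center Center's layer counts toward coverage (default
#'   TRUE).
#' @param edge_adjust `"none"` or `"BH"` for edge p-values.
#' @param n_perm PERMANOVA permutations (default 999).
#' @param run_diversity Compute alpha/beta diversity for count layers.
#' @param seed Integer master seed.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha_screen = 0.05, alpha_edge = 0.05,
                            r_min = 0, dunn_adjust = "BH",
                            min_mean_rel_abund = 1e-4, min_layers = 4,
                            include_center = TRUE, edge_adjust = "none",
                            n_perm = 999, run_diversity = TRUE, seed = 1L) {
  cfg <- list(
    alpha_screen = alpha_screen, alpha_edge = alpha_edge, r_min = r_min,
    dunn_adjust = dunn_adjust, min_mean_rel_abund = min_mean_rel_abund,
    min_layers = min_layers, include_center = include_center,
    edge_adjust = edge_adjust, n_perm = n_perm,
    run_diversity = run_diversity, seed = as.integer(seed)
  )
  for (th in c("alpha_screen", "alpha_edge")) {
    if (cfg[[th]] <= 0 || cfg[[th]] > 1) {
      stop(th, " must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) stop("unknown config key(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1)),
             sep = "=", collapse = ";")
  # small stable polynomial hash over the serialized config; stamps output
  # directories so reruns with different parameters never collide
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full multi-omics signature pipeline
#'
#' Stages: (1) optional alpha/beta diversity per count layer; (2) relative
#' abundance + prevalence filter on count layers; (3) per-subset feature
#' screening (all subjects plus the three cohort pairs); (4) joint Pearson
#' correlation network and star extraction per subset; (5) star-center
#' membership and signature classification. All tabular outputs are written
#' as TSV, structured outputs as JSON, into a parameter-stamped directory
#' `<out_dir>/run-<confighash>` so reruns with changed thresholds never
#' overwrite earlier results. A manifest records parameters, seed, and
#' per-stage feature counts.
#'
#' @param dataset A `multiomics_dataset` (e.g. from [generate_cohort()] or
#'   [read_multiomics()]).
#' @param out_dir Output root; created if needed. `NULL` skips writing.
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list: `diversity`, `screens`, `candidates`,
#'   `edges`, `stars`, `membership`, `signatures`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(dataset, out_dir = NULL, config = pipeline_config()) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  t0 <- proc.time()[["elapsed"]]
  counts_log <- list()

  diversity <- NULL
  if (isTRUE(config$run_diversity)) {
    count_layers <- Filter(function(l) l$semantics == "counts", dataset$layers)
    diversity <- lapply(count_layers, function(l) {
      d <- bray_curtis(l)
      list(
        alpha = alpha_diversity(l, dataset$metadata),
        pcoa = pcoa_ord(d),
        permanova = beta_permanova(d, dataset$metadata,
                                   n_perm = config$n_perm,
                                   seed = config$seed + 101L)
      )
    })
  }

  # screening operates on filtered relative abundances for count layers
  screened_ds <- dataset
  screened_ds$layers <- lapply(dataset$layers, function(l) {
    if (l$semantics != "counts") return(l)
    ra <- to_relative_abundance(l)
    out <- prevalence_filter(ra, config$min_mean_rel_abund)
    counts_log[[paste0("filter_", l$layer_id)]] <<-
      c(features_in = nrow(l$values), features_out = nrow(out$values))
    out
  })

  screens <- lapply(stats::setNames(SUBSET_IDS, SUBSET_IDS), function(s) {
    screen_features(screened_ds, alpha = config$alpha_screen,
                    adjust_method = config$dunn_adjust, subset = s,
                    transform_counts = FALSE)
  })
  candidates <- lapply(screens, candidate_set)

  edges <- lapply(stats::setNames(SUBSET_IDS, SUBSET_IDS), function(s) {
    if (nrow(candidates[[s]]) == 0) return(empty_edges(s))
    build_network(screened_ds, candidates[[s]], subset = s,
                  alpha_edge = config$alpha_edge, r_min = config$r_min,
                  adjust = config$edge_adjust)
  })
  stars <- lapply(edges, extract_stars, min_layers = config$min_layers,
                  include_center = config$include_center)
  membership <- star_membership(stars)

  signatures <- if (nrow(membership) > 0) {
    mem <- add_cohort_means(membership, screened_ds)
    classify_signatures(mem)
  } else {
    classify_signatures(membership)
  }

  for (s in SUBSET_IDS) {
    counts_log[[paste0("candidates_", s)]] <- nrow(candidates[[s]])
    counts_log[[paste0("edges_", s)]] <- nrow(edges[[s]])
    counts_log[[paste0("stars_", s)]] <- nrow(stars[[s]])
  }
  manifest <- list(
    package = "omicstar",
    version = as.character(utils::packageVersion("omicstar")),
    config = unclass(config), config_hash = config_hash(config),
    n_samples = nrow(dataset$metadata),
    cohort_sizes = as.list(table(dataset$metadata$cohort)),
    stage_counts = counts_log,
    elapsed_seconds = proc.time()[["elapsed"]] - t0
  )

  result <- list(diversity = diversity, screens = screens,
                 candidates = candidates, edges = edges, stars = stars,
                 membership = membership, signatures = signatures,
                 manifest = manifest, out_dir = NULL)
  if (!is.null(out_dir)) {
    result$out_dir <- write_pipeline_outputs(result, dataset, out_dir, config)
  }
  invisible(result)
}

# cohort means of each star center on the analyzed scale, for rule 4
add_cohort_means <- function(membership, dataset) {
  md <- dataset$metadata
  means <- purrr::pmap_dfr(membership[, c("center", "center_layer")],
                           function(center, center_layer) {
    layer <- dataset$layers[[center_layer]]
    x <- layer$values[center, md$sample_id]
    m <- tapply(x, md$cohort, mean)
    tibble::tibble(ctrl_mean = m[["Ctrl"]], lc_mean = m[["LC"]],
                   hcc_mean = m[["HCC"]])
  })
  dplyr::bind_cols(membership, means)
}

write_pipeline_outputs <- function(result, dataset, out_dir, config) {
  run_dir <- file.path(out_dir, paste0("run-", config_hash(config)))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$diversity)) {
    for (nm in names(result$diversity)) {
      readr::write_tsv(result$diversity[[nm]]$alpha,
                       file.path(run_dir, paste0("alpha_", nm, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(tidy(result$diversity[[nm]]$pcoa),
                       file.path(run_dir, paste0("pcoa_", nm, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(result$diversity[[nm]]$permanova,
                       file.path(run_dir, paste0("permanova_", nm, ".tsv")),
                       progress = FALSE)
    }
  }
  for (s in SUBSET_IDS) {
    scr <- dplyr::select(result$screens[[s]], -"dunn")
    readr::write_tsv(scr, file.path(run_dir, paste0("screen_", s, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(result$edges[[s]],
                     file.path(run_dir, paste0("edges_", s, ".tsv")),
                     progress = FALSE)
    stars_flat <- dplyr::select(result$stars[[s]], -"neighbors")
    readr::write_tsv(stars_flat,
                     file.path(run_dir, paste0("stars_", s, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(result$membership, file.path(run_dir, "membership.tsv"),
                   progress = FALSE)
  readr::write_tsv(signature_report(result$signatures),
                   file.path(run_dir, "signatures.tsv"), progress = FALSE)
  manifest <- result$manifest
  manifest$elapsed_seconds <- NULL  # keep reruns byte-identical
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_dir
}
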