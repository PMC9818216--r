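#' Specify a synthetic omics layer
#'
#' Count layers (bacteria, virus) are drawn per sample from a
#' Dirichlet-multinomial: base concentrations set the mean composition and
#' overdispersion, the sequencing depth defaults to 70,000 (the order of
#' magnitude of cleaned amplicon reads per subject in the motivating study).
#' Concentration layers (metabolite, cytokine) are truncated normal,
#' truncated at zero because several real plasma analytes have means near
#' zero with large standard deviations.
#'
#' Cohort effects are planted via `shifts`: for count layers the effect
#' multiplies the feature's base concentration in that cohort (1 = no
#' effect); for concentration layers it is added to the feature's mean in
#' measurement units (0 = no effect).
#'
#' @param layer_id One of `"bacteria"`, `"virus"`, `"metabolite"`,
#'   `"cytokine"`.
#' @param n_features Number of features to simulate.
#' @param depth Sequencing depth per sample (count layers).
#' @param base_conc Dirichlet base concentrations, length `n_features`
#'   (count layers). Default is a geometric ladder `5 * 0.9^i` normalised to
#'   total 50, giving realistically skewed compositions with strong
#'   overdispersion.
#' @param mean,sd Feature means and SDs (concentration layers), recycled to
#'   `n_features`. Parameterise these from printed cohort "mean +/- SD"
#'   tables to emulate a given panel.
#' @param shifts Tibble with columns `feature` (integer index or feature id),
#'   and one column per cohort (`Ctrl`, `LC`, `HCC`) holding the effect.
#' @param prefix Feature-id prefix (default derived from `layer_id`).
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(layer_id, n_features, depth = 70000,
                       base_conc = NULL, mean = 10, sd = 2,
                       shifts = NULL, prefix = NULL) {
  layer_id <- match.arg(layer_id, OMICS_LAYERS)
  stopifnot(n_features >= 1)
  model <- if (layer_id %in% c("bacteria", "virus")) "counts" else "concentration"
  if (model == "counts" && is.null(base_conc)) {
    base_conc <- 5 * 0.9^seq_len(n_features)
    base_conc <- base_conc / sum(base_conc) * 50
  }
  if (is.null(prefix)) {
    prefix <- c(bacteria = "bact", virus = "vir",
                metabolite = "met", cytokine = "cyt")[[layer_id]]
  }
  structure(list(
    layer_id = layer_id, n_features = as.integer(n_features), model = model,
    depth = depth, base_conc = base_conc,
    mean = rep_len(mean, n_features), sd = rep_len(sd, n_features),
    shifts = shifts, prefix = prefix
  ), class = "layer_spec")
}

#' Specify a planted cross-layer star
#'
#' A per-sample latent Gaussian factor couples the center feature (loading
#' fixed at +1) to its neighbors with signed loadings in \[-1, 1\]. The factor
#' acts on the log scale for count layers (multiplying the Dirichlet base
#' concentration by `exp(loading * z)`) and linearly, in SD units, for
#' concentration layers — a simple, sign-controllable way to induce
#' cross-layer Pearson correlation.
#'
#' @param center Length-2 character vector `c(feature_id, layer_id)`.
#' @param neighbors Tibble with columns `feature`, `layer`, `loading`.
#' @param latent_sd SD of the latent factor (default 1).
#' @return A `planted_star_spec` list.
#' @export
planted_star <- function(center, neighbors, latent_sd = 1) {
  stopifnot(length(center) == 2, latent_sd > 0)
  neighbors <- tibble::as_tibble(neighbors)
  stopifnot(all(c("feature", "layer", "loading") %in% names(neighbors)))
  if (any(abs(neighbors$loading) > 1)) {
    stop("star loadings must lie in [-1, 1]", call. = FALSE)
  }
  bad <- setdiff(neighbors$layer, OMICS_LAYERS)
  if (length(bad) > 0) stop("unknown layer id: ", bad[1], call. = FALSE)
  structure(list(center_feature = center[[1]], center_layer = center[[2]],
                 neighbors = neighbors, latent_sd = latent_sd),
            class = "planted_star_spec")
}

#' Specify a synthetic three-cohort study
#'
#' Defaults mirror the motivating study design: cohorts Ctrl/LC/HCC of sizes
#' 17/18/10.
#'
#' @param group_sizes Named integer vector over exactly
#'   `c("Ctrl", "LC", "HCC")`, each at least 3.
#' @param layers List of [layer_spec()] objects.
#' @param stars List of [planted_star()] objects.
#' @param seed Integer seed; fully determines the generated dataset.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(group_sizes = c(Ctrl = 17, LC = 18, HCC = 10),
                        layers = list(), stars = list(), seed = 1L) {
  if (!setequal(names(group_sizes), COHORT_LEVELS)) {
    stop("group_sizes must be named exactly Ctrl, LC, HCC", call. = FALSE)
  }
  group_sizes <- group_sizes[COHORT_LEVELS]
  if (any(group_sizes < 3)) stop("each cohort needs >= 3 subjects", call. = FALSE)
  stopifnot(all(vapply(layers, inherits, logical(1), "layer_spec")),
            all(vapply(stars, inherits, logical(1), "planted_star_spec")))
  structure(list(group_sizes = group_sizes, layers = layers, stars = stars,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Generate a seeded synthetic multi-omics cohort
#'
#' Draws one feature table per layer with identical sample ids across layers,
#' cohort metadata, planted group shifts, and planted cross-layer star
#' correlation structure. The spec's seed fully determines the output; the
#' generator restores the caller's RNG state on exit. The returned dataset
#' carries a truth record (planted stars, shifted features, the truncation
#' fraction of each concentration layer) retrievable with [planted_truth()].
#'
#' @param spec A [cohort_spec()].
#' @return A `multiomics_dataset` with attached truth record.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- sum(spec$group_sizes)
  cohort <- factor(rep(COHORT_LEVELS, times = spec$group_sizes),
                   levels = COHORT_LEVELS)
  samp <- sprintf("S%03d", seq_len(n))
  metadata <- tibble::tibble(sample_id = samp, cohort = cohort)

  with_preserved_seed(spec$seed, {
    # one latent factor per planted star, shared across layers
    latents <- lapply(spec$stars, function(st) stats::rnorm(n, 0, st$latent_sd))

    shifted <- list()
    trunc_frac <- list()
    layers <- lapply(spec$layers, function(ls) {
      fid <- sprintf("%s_%03d", ls$prefix, seq_len(ls$n_features))
      # per-feature latent loading for this layer (0 when not in any star)
      load_mat <- matrix(0, nrow = ls$n_features, ncol = length(spec$stars),
                         dimnames = list(fid, NULL))
      for (k in seq_along(spec$stars)) {
        st <- spec$stars[[k]]
        if (st$center_layer == ls$layer_id && st$center_feature %in% fid) {
          load_mat[st$center_feature, k] <- 1
        }
        nb <- st$neighbors[st$neighbors$layer == ls$layer_id, ]
        if (nrow(nb) > 0) {
          miss <- setdiff(nb$feature, fid)
          if (length(miss) > 0) {
            stop("star neighbor not in layer: ", miss[1], call. = FALSE)
          }
          load_mat[nb$feature, k] <- nb$loading
        }
      }
      # cohort effect per feature (multiplicative for counts, additive else)
      eff <- matrix(if (ls$model == "counts") 1 else 0,
                    nrow = ls$n_features, ncol = 3,
                    dimnames = list(fid, COHORT_LEVELS))
      if (!is.null(ls$shifts)) {
        sh <- tibble::as_tibble(ls$shifts)
        idx <- if (is.numeric(sh$feature)) sh$feature else match(sh$feature, fid)
        if (anyNA(idx)) stop("shift refers to unknown feature", call. = FALSE)
        for (g in intersect(COHORT_LEVELS, names(sh))) eff[idx, g] <- sh[[g]]
        shifted[[ls$layer_id]] <<- tibble::tibble(
          layer = ls$layer_id, feature_id = fid[idx],
          Ctrl = eff[idx, "Ctrl"], LC = eff[idx, "LC"], HCC = eff[idx, "HCC"]
        )
      }
      lat_term <- if (length(latents) > 0) {
        load_mat %*% do.call(rbind, lapply(latents, rbind))  # features x n
      } else {
        matrix(0, ls$n_features, n)
      }
      if (ls$model == "counts") {
        vals <- matrix(0, nrow = ls$n_features, ncol = n,
                       dimnames = list(fid, samp))
        for (j in seq_len(n)) {
          a <- ls$base_conc * eff[, as.character(cohort[j])] *
            exp(lat_term[, j])
          g <- stats::rgamma(ls$n_features, shape = a, rate = 1)
          if (sum(g) == 0) g <- rep(1, ls$n_features)
          vals[, j] <- stats::rmultinom(1, size = ls$depth, prob = g / sum(g))
        }
        feature_table(vals, ls$layer_id, "counts")
      } else {
        mu <- outer(ls$mean, rep(1, n)) + eff[, as.character(cohort)] +
          ls$sd * lat_term
        raw <- mu + ls$sd * matrix(stats::rnorm(ls$n_features * n),
                                   ls$n_features, n)
        trunc_frac[[ls$layer_id]] <<- mean(raw < 0)
        vals <- pmax(raw, 0)
        dimnames(vals) <- list(fid, samp)
        feature_table(vals, ls$layer_id, "concentration")
      }
    })
    names(layers) <- vapply(spec$layers, function(l) l$layer_id, character(1))

    truth <- list(
      seed = spec$seed,
      stars = lapply(spec$stars, function(st) {
        list(center_feature = st$center_feature, center_layer = st$center_layer,
             latent_sd = st$latent_sd,
             neighbors = st$neighbors)
      }),
      shifted_features = if (length(shifted) > 0) {
        dplyr::bind_rows(shifted)
      } else {
        tibble::tibble(layer = character(), feature_id = character())
      },
      truncation_fraction = trunc_frac
    )
    multiomics_dataset(layers, metadata, truth = truth)
  })
}

#' Retrieve the generator's ground-truth record
#'
#' @param dataset A `multiomics_dataset` produced by [generate_cohort()] (or
#'   read back from disk alongside its `truth.json`).
#' @return List with elements `stars`, `shifted_features`, and
#'   `truncation_fraction`.
#' @export
planted_truth <- function(dataset) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  if (is.null(dataset$truth)) {
    stop("dataset carries no truth record (not produced by generate_cohort)",
         call. = FALSE)
  }
  dataset$truth
}
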