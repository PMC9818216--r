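# Shared synthetic fixtures, built in code at test time.

# Small feature table with fixed values
toy_table <- function(layer = "bacteria", semantics = "counts") {
  m <- matrix(c(5, 0, 3,
                1, 4, 2,
                0, 0, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("fA", "fB", "fC"), c("s1", "s2", "s3")))
  feature_table(m, layer, semantics)
}

# Study-sized cohort spec with one planted four-layer star and 2-SD group
# shifts on the star members. Effects are sized against each feature's own
# variability: star members on count layers carry a latent log-scale factor
# of SD ~1, so a 2-SD multiplicative shift is exp(2) ~ 8x; concentration
# members have total SD = sd * sqrt(1 + loading^2), so the additive shift is
# twice that. Shift directions follow the loading signs so the cohort-shift
# and latent-factor contributions to the planted correlations reinforce.
recovery_spec <- function(seed) {
  cohort_spec(
    layers = list(
      layer_spec("bacteria", 12,
                 shifts = tibble::tibble(feature = 1L, Ctrl = 1, LC = 8, HCC = 8)),
      layer_spec("virus", 12,
                 shifts = tibble::tibble(feature = 1L, Ctrl = 1, LC = 8, HCC = 8)),
      layer_spec("metabolite", 10, mean = 10, sd = 2,
                 shifts = tibble::tibble(feature = 1L, Ctrl = 0, LC = 5, HCC = 5)),
      layer_spec("cytokine", 10, mean = 50, sd = 10,
                 shifts = tibble::tibble(feature = 1L, Ctrl = 0, LC = -26, HCC = -26))
    ),
    stars = list(planted_star(
      c("bact_001", "bacteria"),
      tibble::tibble(feature = c("vir_001", "met_001", "cyt_001"),
                     layer = c("virus", "metabolite", "cytokine"),
                     loading = c(0.8, 0.8, -0.8)),
      latent_sd = 1
    )),
    seed = seed
  )
}

# Null spec: no shifts, no stars, one concentration layer of many features
null_spec <- function(seed, n_features = 1000) {
  cohort_spec(
    layers = list(layer_spec("metabolite", n_features, mean = 10, sd = 2)),
    seed = seed
  )
}

# Random edge tibble over nodes with random layer tags (graph fixtures for
# the star-extraction oracle)
random_edges <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  layers <- sample(c("bacteria", "virus", "metabolite", "cytokine"),
                   n_nodes, replace = TRUE)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- utils::combn(n_nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  pairs <- pairs[, keep, drop = FALSE]
  tibble::tibble(
    feature_a = ids[pairs[1, ]], layer_a = layers[pairs[1, ]],
    feature_b = ids[pairs[2, ]], layer_b = layers[pairs[2, ]],
    r = stats::runif(ncol(pairs), -1, 1),
    p_value = stats::runif(ncol(pairs), 0, 0.05),
    n = 45L, subset = "ALL"
  )
}
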