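#' Omics layer identifiers and cohort labels
#'
#' The pipeline integrates four omics layers measured on the same subjects:
#' gut bacterial genus abundances, gut viral species abundances, plasma
#' aqueous-phase metabolite concentrations, and plasma cytokine/chemokine
#' concentrations. Subjects belong to one of three cohorts: healthy controls
#' (`Ctrl`), liver cirrhosis (`LC`), and hepatocellular carcinoma (`HCC`).
#'
#' @name omicstar-vocab
#' @keywords internal
NULL

OMICS_LAYERS <- c("bacteria", "virus", "metabolite", "cytokine")
VALUE_SEMANTICS <- c("counts", "relative_abundance", "concentration")
COHORT_LEVELS <- c("Ctrl", "LC", "HCC")
SUBSET_IDS <- c("ALL", "CTRL_LC", "CTRL_HCC", "LC_HCC")

#' Cohorts entering each subject subset
#' @keywords internal
subset_cohorts <- function(subset) {
  subset <- match.arg(subset, SUBSET_IDS)
  switch(subset,
    ALL = COHORT_LEVELS,
    CTRL_LC = c("Ctrl", "LC"),
    CTRL_HCC = c("Ctrl", "HCC"),
    LC_HCC = c("LC", "HCC")
  )
}

#' Construct a feature table for one omics layer
#'
#' A feature table holds a features x samples matrix for a single omics layer
#' together with its layer tag and value semantics. Count layers (16S genus
#' or virome species tables) hold nonnegative integers; concentration layers
#' hold nonnegative reals. Relative-abundance tables must have columns summing
#' to one.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Feature ids are free text;
#'   only tabs and newlines are forbidden (virome species names legitimately
#'   contain spaces, dots and colons).
#' @param layer_id One of `"bacteria"`, `"virus"`, `"metabolite"`,
#'   `"cytokine"`.
#' @param semantics One of `"counts"`, `"relative_abundance"`,
#'   `"concentration"`.
#' @param units Free-text measurement units (e.g. `"pg/mL"`), or `NA`.
#' @return An object of class `feature_table`.
#' @examples
#' m <- matrix(c(2, 2, 1, 3), nrow = 2,
#'             dimnames = list(c("gA", "gB"), c("s1", "s2")))
#' ft <- feature_table(m, "bacteria", "counts")
#' to_relative_abundance(ft)
#' @export
feature_table <- function(values, layer_id, semantics, units = NA_character_) {
  layer_id <- match.arg(layer_id, OMICS_LAYERS)
  semantics <- match.arg(semantics, VALUE_SEMANTICS)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry feature ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  validate_ids(rownames(values), "feature")
  validate_ids(colnames(values), "sample")
  if (anyNA(values)) stop("feature table contains missing values", call. = FALSE)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative value at feature '%s', sample '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]),
         call. = FALSE)
  }
  if (semantics == "counts") {
    if (any(abs(values - round(values)) > 1e-8)) {
      stop("semantics = 'counts' requires integer values", call. = FALSE)
    }
    storage.mode(values) <- "double"
    values <- round(values)
  }
  if (semantics == "relative_abundance") {
    cs <- colSums(values)
    bad <- which(abs(cs - 1) > 1e-6)
    if (length(bad) > 0) {
      stop(sprintf("relative-abundance column '%s' sums to %.8f, not 1",
                   colnames(values)[bad[1]], cs[bad[1]]), call. = FALSE)
    }
  }
  structure(
    list(values = values, layer_id = layer_id, semantics = semantics,
         units = units),
    class = "feature_table"
  )
}

validate_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate %s id: '%s'", what, ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  if (any(grepl("[\t\n\r]", ids))) {
    stop(sprintf("%s ids must not contain tabs or newlines", what), call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> layer '%s' (%s%s): %d features x %d samples\n",
              x$layer_id, x$semantics,
              if (is.na(x$units)) "" else paste0(", ", x$units),
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature and sample ids of a feature table
#' @param table A `feature_table`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(table) rownames(table$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(table) colnames(table$values)

#' Tidy a feature table into long format
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return A tibble with columns `layer`, `feature_id`, `sample_id`, `value`.
#' @export
tidy.feature_table <- function(x, ...) {
  tibble::tibble(
    layer = x$layer_id,
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' One-row summary of a feature table
#' @param x A `feature_table`.
#' @param ... Unused.
#' @export
glance.feature_table <- function(x, ...) {
  tibble::tibble(
    layer = x$layer_id, semantics = x$semantics,
    n_features = nrow(x$values), n_samples = ncol(x$values),
    total = sum(x$values)
  )
}

#' Convert a count table to relative abundances
#'
#' Divides each sample column by its total so that columns sum to one; the
#' table's semantics becomes `relative_abundance`. This is the scale on which
#' abundance screening and the prevalence filter operate.
#'
#' @param table A `feature_table` with `counts` semantics.
#' @return A `feature_table` with `relative_abundance` semantics.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$semantics != "counts") {
    stop("to_relative_abundance() expects counts semantics", call. = FALSE)
  }
  cs <- colSums(table$values)
  zero <- which(cs == 0)
  if (length(zero) > 0) {
    stop(sprintf("sample '%s' has zero total count", colnames(table$values)[zero[1]]),
         call. = FALSE)
  }
  feature_table(sweep(table$values, 2, cs, "/"), table$layer_id,
                "relative_abundance", table$units)
}

#' Filter features by mean relative abundance
#'
#' Retains features whose mean relative abundance exceeds a threshold
#' (strictly; default 1e-4, i.e. 0.01%). The default averages across all
#' samples; with `metadata` and `scope = "any_cohort"` a feature is kept when
#' its within-cohort mean exceeds the threshold in at least one cohort.
#'
#' @param table A `feature_table` with `relative_abundance` semantics.
#' @param min_mean_rel_abund Strict threshold on the mean (default `1e-4`).
#' @param metadata Optional sample metadata tibble (needed for
#'   `scope = "any_cohort"`).
#' @param scope `"all"` (mean over all samples) or `"any_cohort"`.
#' @return A filtered `feature_table`.
#' @export
prevalence_filter <- function(table, min_mean_rel_abund = 1e-4,
                              metadata = NULL,
                              scope = c("all", "any_cohort")) {
  stopifnot(inherits(table, "feature_table"))
  scope <- match.arg(scope)
  if (table$semantics != "relative_abundance") {
    stop("prevalence_filter() expects relative_abundance semantics", call. = FALSE)
  }
  if (scope == "all") {
    keep <- rowMeans(table$values) > min_mean_rel_abund
  } else {
    if (is.null(metadata)) stop("metadata required for scope = 'any_cohort'",
                                call. = FALSE)
    coh <- metadata$cohort[match(colnames(table$values), metadata$sample_id)]
    keep <- rep(FALSE, nrow(table$values))
    for (g in unique(coh)) {
      keep <- keep | rowMeans(table$values[, coh == g, drop = FALSE]) >
        min_mean_rel_abund
    }
  }
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  out
}

#' Assemble aligned omics layers and cohort metadata
#'
#' Layers are aligned on their shared samples: if sample sets differ, the
#' intersection is taken (in the metadata's order) and the dropped ids are
#' reported in a warning.
#'
#' @param layers Named list of `feature_table`s, names = layer ids.
#' @param metadata Tibble with columns `sample_id` and `cohort`
#'   (values among `Ctrl`, `LC`, `HCC`), plus optional covariates.
#' @param truth Optional generator truth record (see [generate_cohort()]).
#' @return An object of class `multiomics_dataset`.
#' @export
multiomics_dataset <- function(layers, metadata, truth = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    names(layers) <- vapply(layers, function(l) l$layer_id, character(1))
  }
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "feature_table")) {
      stop(sprintf("layer '%s' is not a feature_table", nm), call. = FALSE)
    }
    if (layers[[nm]]$layer_id != nm) {
      stop(sprintf("layer name '%s' does not match its layer_id '%s'",
                   nm, layers[[nm]]$layer_id), call. = FALSE)
    }
  }
  metadata <- validate_metadata(metadata)
  shared <- Reduce(intersect, lapply(layers, sample_ids))
  shared <- metadata$sample_id[metadata$sample_id %in% shared]
  if (length(shared) < 1) stop("layers share no samples", call. = FALSE)
  all_ids <- unique(c(unlist(lapply(layers, sample_ids)), metadata$sample_id))
  dropped <- setdiff(all_ids, shared)
  if (length(dropped) > 0) {
    warning(sprintf("dropping %d sample(s) absent from some layer: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  layers <- lapply(layers, function(l) {
    l$values <- l$values[, shared, drop = FALSE]
    l
  })
  metadata <- metadata[match(shared, metadata$sample_id), , drop = FALSE]
  structure(list(layers = layers, metadata = metadata, truth = truth),
            class = "multiomics_dataset")
}

validate_metadata <- function(metadata) {
  metadata <- tibble::as_tibble(metadata)
  if (!all(c("sample_id", "cohort") %in% names(metadata))) {
    stop("metadata needs columns 'sample_id' and 'cohort'", call. = FALSE)
  }
  validate_ids(metadata$sample_id, "sample")
  bad <- setdiff(unique(as.character(metadata$cohort)), COHORT_LEVELS)
  if (length(bad) > 0) {
    stop(sprintf("unknown cohort label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  metadata$cohort <- factor(as.character(metadata$cohort), levels = COHORT_LEVELS)
  metadata
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("<multiomics_dataset> %d layer(s), %d samples (%s)\n",
              length(x$layers), nrow(x$metadata),
              paste(sprintf("%s=%d", levels(x$metadata$cohort),
                            tabulate(x$metadata$cohort, 3)), collapse = ", ")))
  for (l in x$layers) print(l)
  invisible(x)
}

#' Generic tidiers (broom-style)
#'
#' `tidy()` returns an observation-level tibble, `glance()` a one-row summary.
#' Methods exist for [feature_table()] and [pcoa_ord()] results.
#' @param x Object to tidy.
#' @param ... Method-specific arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
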