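#' Read a feature table from TSV
#'
#' The expected dialect is tab-separated UTF-8 with '.' as the decimal mark:
#' header row holds sample ids, the first column holds feature ids, and the
#' body is numeric. Duplicate ids, negative entries, non-numeric cells and
#' ragged rows are rejected with the offending row/column named.
#'
#' @param path Path to a TSV file.
#' @param layer_id,semantics,units Passed to [feature_table()].
#' @return A validated `feature_table`. Counts are coerced to integers only
#'   when `semantics = "counts"`.
#' @export
read_feature_table <- function(path, layer_id, semantics, units = NA_character_) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("file has no data rows: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  sample_names <- header[-1]
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1]
    stop(sprintf("ragged row %d: %d fields, expected %d", bad + 1L,
                 widths[bad], n_col), call. = FALSE)
  }
  feat <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L,
                 dimnames = list(feat, sample_names))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    bad <- which(is.na(v) & !body[[i]][-1] %in% c("NA", ""))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   feat[i], sample_names[bad[1]], body[[i]][-1][bad[1]]),
           call. = FALSE)
    }
    vals[i, ] <- v
  }
  feature_table(vals, layer_id, semantics, units)
}

#' Write a feature table to TSV
#'
#' Values are written with full double precision so that a write/read
#' round-trip preserves them to at least 12 significant digits.
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  body <- apply(v, 1, function(row) paste(format_num(row), collapse = "\t"))
  lines <- c(paste(c("feature_id", colnames(v)), collapse = "\t"),
             paste(rownames(v), body, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) sprintf("%.0f", v)
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Read or write sample metadata
#'
#' Metadata TSV has a `sample_id` column, a `cohort` column restricted to
#' `Ctrl`/`LC`/`HCC`, and optional covariate columns (age, sex, BMI, ...).
#'
#' @param path TSV path.
#' @return A validated metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata Metadata tibble.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(validate_metadata(metadata), path, progress = FALSE)
  invisible(path)
}

#' Read a multi-omics dataset from a directory
#'
#' Expects `<layer>.tsv` per layer, `metadata.tsv`, and optionally
#' `truth.json` (the synthetic generator's ground-truth record). Layers are
#' aligned on shared samples via [multiomics_dataset()].
#'
#' @param dir Directory written by [write_multiomics()].
#' @param semantics Named character vector mapping layer id to value
#'   semantics; defaults to counts for bacteria/virus and concentration for
#'   metabolite/cytokine.
#' @return A `multiomics_dataset`.
#' @export
read_multiomics <- function(dir, semantics = default_semantics()) {
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  layer_files <- intersect(OMICS_LAYERS,
                           sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$")))
  layers <- lapply(layer_files, function(l) {
    read_feature_table(file.path(dir, paste0(l, ".tsv")), l, semantics[[l]])
  })
  names(layers) <- layer_files
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    # keep the nested star/neighbor structure as written
    jsonlite::read_json(truth_path, simplifyVector = FALSE)
  }
  multiomics_dataset(layers, md, truth = truth)
}

default_semantics <- function() {
  c(bacteria = "counts", virus = "counts",
    metabolite = "concentration", cytokine = "concentration")
}

#' @rdname read_multiomics
#' @param dataset A `multiomics_dataset`.
#' @export
write_multiomics <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in dataset$layers) {
    write_feature_table(l, file.path(dir, paste0(l$layer_id, ".tsv")))
  }
  write_sample_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(dataset$truth)) {
    jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}
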