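SIGNATURE_LABELS <- c("Common", "CommonAllOnly", "LCSpecific", "HCCSpecific",
                      "Unclassified")

# printed-report rendering of each label
PRINTED_LABELS <- c(Common = "Common", CommonAllOnly = "Common *",
                    LCSpecific = "LC specific", HCCSpecific = "HCC specific",
                    Unclassified = "-")

#' Classify star centers into signature categories
#'
#' Applies the decision rules that turn a center's star membership across
#' the four subject-subset analyses into a signature label, in order:
#'
#' 1. member in both Ctrl-LC and Ctrl-HCC (with or without ALL) ->
#'    `Common`;
#' 2. Ctrl-LC only -> `LCSpecific`;
#' 3. Ctrl-HCC only -> `HCCSpecific`;
#' 4. ALL only: `CommonAllOnly` when the control cohort's mean of the
#'    center is strictly the extreme (minimum or maximum) of the three
#'    cohort means, with LC and HCC on the same side — the weaker evidence
#'    class where the all-subject analysis alone supports a shared
#'    direction of change in both diseases; otherwise `Unclassified`;
#' 5. otherwise `Unclassified`.
#'
#' Severity association is an orthogonal flag: it is simply membership in
#' the LC-HCC analysis, so a center can be, say, both `Common` and
#' severity-associated.
#'
#' `CommonAllOnly` is kept distinct from `Common` rather than merged, so the
#' weaker evidence class stays visible in reports (rendered "Common *").
#'
#' @param membership Tibble with columns `center`, logical `ALL`,
#'   `CTRL_LC`, `CTRL_HCC`, `LC_HCC` (see [star_membership()]), and — when
#'   rule 4 is reachable, i.e. some row has ALL membership only — numeric
#'   columns `ctrl_mean`, `lc_mean`, `hcc_mean`.
#' @return The membership tibble with added columns `label` (factor over
#'   `Common`, `CommonAllOnly`, `LCSpecific`, `HCCSpecific`,
#'   `Unclassified`), `printed_label`, and logical `severity`.
#' @export
classify_signatures <- function(membership) {
  m <- tibble::as_tibble(membership)
  need <- c("center", "ALL", "CTRL_LC", "CTRL_HCC", "LC_HCC")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) stop("membership lacks column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  label <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    label[i] <- classify_one(
      all = m$ALL[i], ctrl_lc = m$CTRL_LC[i], ctrl_hcc = m$CTRL_HCC[i],
      ctrl_mean = m$ctrl_mean[i] %||% NA_real_,
      lc_mean = m$lc_mean[i] %||% NA_real_,
      hcc_mean = m$hcc_mean[i] %||% NA_real_
    )
  }
  m$label <- factor(label, levels = SIGNATURE_LABELS)
  m$printed_label <- unname(PRINTED_LABELS[label])
  m$severity <- m$LC_HCC
  m
}

classify_one <- function(all, ctrl_lc, ctrl_hcc,
                         ctrl_mean = NA, lc_mean = NA, hcc_mean = NA) {
  if (ctrl_lc && ctrl_hcc) return("Common")
  if (ctrl_lc) return("LCSpecific")
  if (ctrl_hcc) return("HCCSpecific")
  if (all) {
    if (anyNA(c(ctrl_mean, lc_mean, hcc_mean))) {
      stop("cohort means required to resolve an ALL-only membership",
           call. = FALSE)
    }
    below <- ctrl_mean < lc_mean && ctrl_mean < hcc_mean
    above <- ctrl_mean > lc_mean && ctrl_mean > hcc_mean
    if (below || above) return("CommonAllOnly")
  }
  "Unclassified"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a transcribed star-membership table
#'
#' The packaged fixture
#' (`system.file("extdata", "table4_membership.tsv", package = "omicstar")`)
#' transcribes the motivating study's published summary of biomarker
#' networks: 39 centers with their membership in the all-subject, Ctrl-LC,
#' Ctrl-HCC, and LC-HCC analyses, the published signature label, and — for
#' the centers whose classification needs them — the published cohort means.
#'
#' @param path TSV path; default the packaged fixture.
#' @return Membership tibble suitable for [classify_signatures()], with the
#'   published `published_label` and `published_severity` columns alongside.
#' @export
read_membership <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table4_membership.tsv",
                        package = "omicstar")
  }
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("ALL", "CTRL_LC", "CTRL_HCC", "LC_HCC")) {
    m[[col]] <- as.logical(m[[col]])
  }
  m
}

#' Signature report in the published table's shape
#'
#' Runs [classify_signatures()] and renders the printed-style columns
#' (Yes/- membership flags, "Common *" for the all-subjects-only common
#' class).
#'
#' @param membership Membership tibble (see [classify_signatures()]).
#' @return Tibble: `center`, `center_layer` (if present), `all_subjects`,
#'   `ctrl_lc`, `ctrl_hcc`, `signature`, `severity`.
#' @export
signature_report <- function(membership) {
  cls <- classify_signatures(membership)
  yn <- function(x) ifelse(x, "Yes", "-")
  out <- tibble::tibble(
    center = cls$center,
    all_subjects = yn(cls$ALL), ctrl_lc = yn(cls$CTRL_LC),
    ctrl_hcc = yn(cls$CTRL_HCC),
    signature = cls$printed_label,
    severity = yn(cls$severity)
  )
  if ("center_layer" %in% names(cls)) {
    out <- dplyr::bind_cols(out[, 1, drop = FALSE],
                            tibble::tibble(center_layer = cls$center_layer),
                            out[, -1])
  }
  out
}
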