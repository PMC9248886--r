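#' Construct an omics block
#'
#' An omics block is one measured molecular layer (an "ome"): a feature-by-
#' sample abundance matrix together with the calendar window during which each
#' sample was collected. It is the unit every downstream step (preprocessing,
#' correlation networks, contribution models) consumes.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique row and column names. Missing measurements are `NA`.
#' @param ome_label Single string naming the ome (e.g. `"chemical"`,
#'   `"metabolome"`, `"cytokine"`).
#' @param sample_windows Optional data frame with columns `sample_id`,
#'   `start_date`, `end_date` (ISO-8601 dates), one row per sample of
#'   `values`. Collection windows drive the temporal alignment of blocks.
#' @param feature_annotations Optional named character vector mapping feature
#'   ids to a class label (chemical class, kingdom, ...).
#'
#' @return An object of class `omics_block`: a list with elements `ome`,
#'   `values`, `sample_windows`, `feature_annotations`.
#' @export
omics_block <- function(values, ome_label, sample_windows = NULL,
                        feature_annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature ids as rownames and sample ids as colnames")
  }
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f) > 0) {
    stop("duplicated feature ids: ", paste(dup_f, collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    stop("duplicated sample ids: ", paste(dup_s, collapse = ", "))
  }
  if (!is.character(ome_label) || length(ome_label) != 1L || is.na(ome_label)) {
    stop("`ome_label` must be a single string")
  }
  if (!is.null(sample_windows)) {
    sample_windows <- validate_sample_windows(sample_windows, colnames(values))
  }
  if (!is.null(feature_annotations)) {
    if (is.null(names(feature_annotations))) {
      stop("`feature_annotations` must be named by feature id")
    }
    unknown <- setdiff(names(feature_annotations), rownames(values))
    if (length(unknown) > 0) {
      stop("feature_annotations name unknown features: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(ome = ome_label, values = values, sample_windows = sample_windows,
         feature_annotations = feature_annotations),
    class = "omics_block"
  )
}

validate_sample_windows <- function(sample_windows, sample_ids) {
  req <- c("sample_id", "start_date", "end_date")
  if (!is.data.frame(sample_windows) || !all(req %in% names(sample_windows))) {
    stop("`sample_windows` must be a data frame with columns ",
         paste(req, collapse = ", "))
  }
  sw <- sample_windows[, req]
  sw$sample_id <- as.character(sw$sample_id)
  sw$start_date <- parse_iso_date(sw$start_date, "start_date")
  sw$end_date <- parse_iso_date(sw$end_date, "end_date")
  missing <- setdiff(sample_ids, sw$sample_id)
  if (length(missing) > 0) {
    stop("sample_windows missing samples: ", paste(missing, collapse = ", "))
  }
  sw <- sw[match(sample_ids, sw$sample_id), , drop = FALSE]
  bad <- sw$sample_id[sw$start_date > sw$end_date]
  if (length(bad) > 0) {
    stop("start_date after end_date for samples: ", paste(bad, collapse = ", "))
  }
  rownames(sw) <- NULL
  sw
}

# ISO-8601 only; anything else is rejected rather than guessed.
parse_iso_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("could not parse ", what, " as ISO-8601 (YYYY-MM-DD): ",
         paste(utils::head(as.character(x)[is.na(d)], 5), collapse = ", "))
  }
  d
}

#' @export
print.omics_block <- function(x, ...) {
  cat("<omics_block> ome:", x$ome, "|", nrow(x$values), "features x",
      ncol(x$values), "samples\n")
  n_na <- sum(is.na(x$values))
  cat("  missing cells:", n_na,
      sprintf("(%.1f%%)", 100 * n_na / length(x$values)), "\n")
  if (!is.null(x$sample_windows)) {
    cat("  collection windows:", as.character(min(x$sample_windows$start_date)),
        "..", as.character(max(x$sample_windows$end_date)), "\n")
  }
  invisible(x)
}

#' Feature ids of an omics block
#' @param block An `omics_block`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(block) rownames(block$values)

#' Sample ids of an omics block
#' @param block An `omics_block`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(block) colnames(block$values)
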