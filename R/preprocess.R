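#' Log2-transform an omics block
#'
#' Applies `log2(x + pseudocount)` cell-wise. Abundances must be non-negative;
#' missing cells stay missing. Because the transform is strictly monotone,
#' Spearman correlations downstream are unchanged by it.
#'
#' @param block An [omics_block()].
#' @param pseudocount Non-negative offset added before taking logs (default 1;
#'   keeps zero abundances finite).
#' @return The transformed block.
#' @export
log2_transform <- function(block, pseudocount = 1) {
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1, pseudocount >= 0)
  v <- block$values
  neg <- which(v < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative abundance at feature '", rownames(v)[neg[1, 1]],
         "', sample '", colnames(v)[neg[1, 2]], "'")
  }
  block$values <- log2(v + pseudocount)
  block
}

#' Filter features by prevalence
#'
#' Keeps features observed (non-missing) in strictly more than `min_fraction`
#' of the samples; the study convention is presence in more than one-third of
#' samples, hence the strict inequality. Fully observed features are always
#' retained (so `min_fraction = 1` drops exactly the features with any
#' missing value).
#'
#' @param block An [omics_block()].
#' @param min_fraction Fraction in (0, 1].
#' @return The filtered block (annotations subset accordingly).
#' @export
prevalence_filter <- function(block, min_fraction = 1 / 3) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  frac <- rowMeans(!is.na(block$values))
  keep <- frac > min_fraction | frac == 1
  if (any(!keep)) {
    message("prevalence_filter: dropping ", sum(!keep), " of ", length(keep),
            " features")
  }
  block$values <- block$values[keep, , drop = FALSE]
  if (!is.null(block$feature_annotations)) {
    block$feature_annotations <-
      block$feature_annotations[intersect(names(block$feature_annotations),
                                          rownames(block$values))]
  }
  block
}

#' K-nearest-neighbour imputation of missing abundances
#'
#' Each missing cell is replaced by the mean of the same sample's values over
#' the `k` nearest features, where distance between two features is the
#' root-mean-square Euclidean distance over the samples both have observed.
#' Neighbours must themselves be observed at the target sample.
#'
#' @param block An [omics_block()].
#' @param k Number of neighbours (default 5).
#' @return Block with no remaining missing cells.
#' @export
knn_impute <- function(block, k = 5) {
  v <- block$values
  if (!anyNA(v)) return(block)
  if (any(rowSums(!is.na(v)) == 0)) {
    bad <- rownames(v)[rowSums(!is.na(v)) == 0][1]
    stop("feature '", bad, "' has no observed values; cannot impute")
  }
  nf <- nrow(v)
  # pairwise RMS distance over shared observed samples
  dist_rms <- function(i, j) {
    sh <- !is.na(v[i, ]) & !is.na(v[j, ])
    if (!any(sh)) return(NA_real_)
    sqrt(mean((v[i, sh] - v[j, sh])^2))
  }
  miss <- which(is.na(v), arr.ind = TRUE)
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; s <- miss[r, 2]
    cand <- setdiff(which(!is.na(v[, s])), i)
    d <- vapply(cand, function(j) dist_rms(i, j), numeric(1))
    cand <- cand[!is.na(d)]; d <- d[!is.na(d)]
    if (length(cand) < k) {
      stop("feature '", rownames(v)[i], "', sample '", colnames(v)[s],
           "': only ", length(cand), " usable neighbours for k = ", k)
    }
    nb <- cand[order(d, cand)][seq_len(k)]
    block$values[i, s] <- mean(v[nb, s])
  }
  block
}

#' Fiber-intake covariate table
#'
#' Binary period indicators for the two dietary-fiber interventions recorded
#' in the participant's food log: arabinoxylan (2016-01-15 to 2016-01-31) and
#' guar gum (2016-02-22 to 2016-03-17). A sample is flagged when its
#' collection window overlaps the dosing period.
#'
#' @param sample_windows Data frame with `sample_id`, `start_date`,
#'   `end_date` (as in an [omics_block()]).
#' @return Data frame with `sample_id`, `arabinoxylan`, `guar_gum` (0/1).
#' @export
fiber_covariates <- function(sample_windows) {
  sw <- validate_sample_windows(sample_windows,
                                as.character(sample_windows$sample_id))
  periods <- list(
    arabinoxylan = c(as.Date("2016-01-15"), as.Date("2016-01-31")),
    guar_gum = c(as.Date("2016-02-22"), as.Date("2016-03-17"))
  )
  out <- data.frame(sample_id = sw$sample_id, stringsAsFactors = FALSE)
  for (nm in names(periods)) {
    p <- periods[[nm]]
    out[[nm]] <- as.integer(sw$start_date <= p[2] & sw$end_date >= p[1])
  }
  out
}

#' Residualize a block on covariates
#'
#' Per feature, fits ordinary least squares on an intercept plus the supplied
#' covariates and returns residuals recentred at the feature mean, removing
#' covariate-driven variation (here, the fiber-intake periods) while keeping
#' abundances on their original scale. Applying it twice equals applying it
#' once.
#'
#' @param block An [omics_block()] with complete values.
#' @param covariates Data frame with `sample_id` plus numeric covariate
#'   columns, covering every sample of the block.
#' @return The adjusted block.
#' @export
residualize <- function(block, covariates) {
  v <- block$values
  if (anyNA(v)) stop("residualize requires complete values; impute first")
  if (!"sample_id" %in% names(covariates)) {
    stop("`covariates` needs a sample_id column")
  }
  missing <- setdiff(colnames(v), covariates$sample_id)
  if (length(missing) > 0) {
    stop("covariates missing samples: ", paste(missing, collapse = ", "))
  }
  cv <- covariates[match(colnames(v), covariates$sample_id), , drop = FALSE]
  X <- as.matrix(cv[, setdiff(names(cv), "sample_id"), drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("covariates contain missing values")
  design <- cbind(`(Intercept)` = 1, X)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    # constant (all-equal) covariate columns collapse into the intercept;
    # anything else rank-deficient is a design error
    keep <- c(TRUE, apply(X, 2, function(col) stats::var(col) > 0))
    design <- design[, keep, drop = FALSE]
    qr_d <- qr(design)
    if (qr_d$rank < ncol(design)) stop("rank-deficient covariate design")
  }
  Y <- t(v)                                    # samples x features
  resid <- qr.resid(qr_d, Y)
  block$values <- t(resid + rep(colMeans(Y), each = nrow(Y)))
  block
}

#' Align two blocks by collection window
#'
#' Pairs samples of `block_a` with samples of `block_b` whose collection
#' windows overlap by at least one day, or whose gap is at most
#' `tolerance_days`. When a sample matches several, the pair with maximal
#' overlap wins (ties: earliest partner start date), and pairs are accepted
#' greedily by that ranking so the result is one-to-one.
#'
#' @param block_a,block_b [omics_block()]s carrying `sample_windows`.
#' @param tolerance_days Maximum allowed gap in days for non-overlapping
#'   windows (default 2).
#' @return Data frame `sample_a`, `sample_b`, `overlap_days` (0 when paired
#'   through the gap tolerance).
#' @export
align_blocks <- function(block_a, block_b, tolerance_days = 2) {
  wa <- block_a$sample_windows
  wb <- block_b$sample_windows
  if (is.null(wa) || is.null(wb)) stop("both blocks need sample_windows")
  cand <- expand.grid(ia = seq_len(nrow(wa)), ib = seq_len(nrow(wb)))
  ov <- as.integer(pmin(as.numeric(wa$end_date[cand$ia]),
                        as.numeric(wb$end_date[cand$ib])) -
                   pmax(as.numeric(wa$start_date[cand$ia]),
                        as.numeric(wb$start_date[cand$ib]))) + 1L
  keep <- ov >= 1L | (1L - ov) <= tolerance_days
  cand <- cand[keep, , drop = FALSE]
  ov <- ov[keep]
  if (nrow(cand) == 0) {
    stop("no alignable sample pairs; increase tolerance_days")
  }
  ord <- order(-ov, wb$start_date[cand$ib], wa$sample_id[cand$ia],
               wb$sample_id[cand$ib])
  cand <- cand[ord, , drop = FALSE]
  ov <- ov[ord]
  used_a <- logical(nrow(wa)); used_b <- logical(nrow(wb))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    ia <- cand$ia[r]; ib <- cand$ib[r]
    if (used_a[ia] || used_b[ib]) next
    used_a[ia] <- TRUE; used_b[ib] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      sample_a = wa$sample_id[ia], sample_b = wb$sample_id[ib],
      overlap_days = max(0L, ov[r]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$sample_a), , drop = FALSE]
}

#' Standard preprocessing chain
#'
#' Convenience wrapper applying, in order: prevalence filtering, log2
#' transform, KNN imputation, and (optionally) covariate residualization —
#' the preparation every block receives before correlation analysis.
#'
#' @param block An [omics_block()].
#' @param min_fraction Prevalence threshold (strict; default 1/3).
#' @param pseudocount Log2 pseudocount (default 1).
#' @param k Imputation neighbours (default 5).
#' @param covariates Optional covariate table for [residualize()].
#' @return The processed block.
#' @export
preprocess_block <- function(block, min_fraction = 1 / 3, pseudocount = 1,
                             k = 5, covariates = NULL) {
  block <- prevalence_filter(block, min_fraction)
  block <- log2_transform(block, pseudocount)
  block <- knn_impute(block, k)
  if (!is.null(covariates)) block <- residualize(block, covariates)
  block
}
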