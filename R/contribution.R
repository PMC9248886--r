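#' Reduce a feature block to leading principal components
#'
#' Column-centers (and by default z-scores) a sample-by-feature matrix,
#' eigen-decomposes its covariance, and keeps the smallest leading set of
#' components whose cumulative explained-variance fraction strictly exceeds
#' `var_threshold` (study convention: > 80%). Component signs follow a
#' deterministic convention: the largest-magnitude loading of each kept
#' component is positive.
#'
#' @param x Numeric sample-by-feature matrix (>= 2 samples).
#' @param var_threshold Cumulative explained-variance threshold in (0, 1]
#'   (default 0.8, strict).
#' @param scale. Z-score columns before the decomposition (default TRUE;
#'   exposome features carry heterogeneous units).
#' @param category Optional label carried through to [contributions()].
#' @return List with `scores` (samples x kept components), `loadings`,
#'   `explained` (all components), `n_kept`, `category`.
#' @export
pca_reduce <- function(x, var_threshold = 0.8, scale. = TRUE,
                       category = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (anyNA(x)) stop("pca_reduce requires complete values")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("zero-variance block")
  if (scale. && any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(utils::head(colnames(x)[sds == 0], 5), collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  n_kept <- which(cumsum(explained) > var_threshold)[1]
  if (is.na(n_kept)) n_kept <- length(explained)
  keep <- seq_len(n_kept)
  rot <- pc$rotation[, keep, drop = FALSE]
  sco <- pc$x[, keep, drop = FALSE]
  for (a in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, a]))
    if (rot[i, a] < 0) { rot[, a] <- -rot[, a]; sco[, a] <- -sco[, a] }
  }
  list(scores = sco, loadings = rot, explained = explained, n_kept = n_kept,
       category = category)
}

#' Coefficient of determination of an OLS fit
#'
#' Ordinary least squares of `y` on `X` with an intercept;
#' `R^2 = 1 - RSS/TSS`.
#'
#' @param y Outcome vector.
#' @param X Predictor matrix (rows aligned with `y`); must have strictly
#'   fewer columns than rows.
#' @return R-squared in \[0, 1\].
#' @export
fit_r2 <- function(y, X) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y and X misaligned")
  if (nrow(X) <= ncol(X)) {
    stop("need more samples (", nrow(X), ") than predictors (", ncol(X), ")")
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("constant outcome: R^2 undefined")
  fit <- stats::lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  max(0, min(1, 1 - rss / tss))
}

#' PLS variable importance in projection
#'
#' Single-response partial least squares by NIPALS, returning per-predictor
#' VIP scores
#' `VIP_j = sqrt( p * sum_a SS_a w_ja^2 / sum_a SS_a )`
#' with `p` predictors, unit-norm weight vectors `w_a`, and `SS_a` the
#' outcome variance captured by component `a`. Mean squared VIP is 1 by
#' construction (`sum VIP^2 = p`).
#'
#' @param y Outcome vector (centered internally).
#' @param X Predictor matrix (columns centered internally).
#' @param n_components Number of PLS components (capped at the number of
#'   informative components found).
#' @return Named numeric vector of VIP scores, one per column of `X`.
#' @export
pls_vip <- function(y, X, n_components) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y and X misaligned")
  p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  W <- matrix(0, p, 0)
  ss <- numeric(0)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    W <- cbind(W, w)
    ss <- c(ss, q_a^2 * tt)
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - t_a * q_a
  }
  if (ncol(W) == 0) stop("degenerate predictors: no PLS component extracted")
  vip <- sqrt(p * drop(W^2 %*% ss) / sum(ss))
  stats::setNames(vip, colnames(X))
}

#' Per-category contribution shares for one outcome
#'
#' Implements the contribution decomposition: each exposome category's
#' feature block is reduced to leading principal components
#' ([pca_reduce()]); the kept components of all categories are concatenated
#' and regressed on the outcome for an overall `R^2` ([fit_r2()]); PLS VIP
#' scores over the same predictors weight each category's importance; and
#' the category share is `R^2 * sum(VIP in category) / sum(VIP)`, so shares
#' are non-negative and sum exactly to `R^2`.
#'
#' @param y Outcome vector (one cytokine or blood test across samples).
#' @param blocks_by_category Named list of sample-by-feature matrices, one
#'   per exposome category (chemical, biological, environmental, ...),
#'   rows aligned with `y`.
#' @param var_threshold PCA cumulative-variance threshold (default 0.8).
#' @param n_components PLS components; default `min(5, n - 2, p)`.
#' @param scale. Z-score features before PCA (default TRUE).
#' @return List with `r2`, `shares` (named by category), `vip` (per kept
#'   component), `n_pcs` (kept per category).
#' @export
contributions <- function(y, blocks_by_category, var_threshold = 0.8,
                          n_components = NULL, scale. = TRUE) {
  if (is.null(names(blocks_by_category)) ||
      any(!nzchar(names(blocks_by_category)))) {
    stop("blocks_by_category must be a named list")
  }
  pcs <- lapply(names(blocks_by_category), function(cat) {
    pca_reduce(blocks_by_category[[cat]], var_threshold, scale. = scale.,
               category = cat)
  })
  names(pcs) <- names(blocks_by_category)
  score_list <- lapply(names(pcs), function(cat) {
    s <- pcs[[cat]]$scores
    colnames(s) <- paste(cat, colnames(s), sep = ".")
    s
  })
  X <- do.call(cbind, score_list)
  cat_of <- rep(names(pcs), vapply(pcs, function(p) p$n_kept, integer(1)))
  r2 <- fit_r2(y, X)
  if (is.null(n_components)) {
    n_components <- min(5, length(y) - 2, ncol(X))
  }
  vip <- pls_vip(y, X, n_components)
  vip_by_cat <- tapply(vip, cat_of, sum)[names(pcs)]
  shares <- r2 * as.numeric(vip_by_cat) / sum(vip)
  list(r2 = r2, shares = stats::setNames(shares, names(pcs)), vip = vip,
       n_pcs = stats::setNames(vapply(pcs, function(p) p$n_kept, integer(1)),
                               names(pcs)))
}

#' Exposome features linked to an outcome in a correlation network
#'
#' @param network A `correlation_network` from [build_network()].
#' @param outcome_feature Feature id of the outcome node.
#' @param outcome_ome Ome label of the outcome block.
#' @param ome Ome label of the exposome category to extract.
#' @return Character vector of linked feature ids (possibly empty).
#' @export
linked_features <- function(network, outcome_feature, outcome_ome, ome) {
  ed <- network$edges
  a <- ed$source == outcome_feature & ed$source_ome == outcome_ome &
    ed$target_ome == ome
  b <- ed$target == outcome_feature & ed$target_ome == outcome_ome &
    ed$source_ome == ome
  sort(unique(c(ed$target[a], ed$source[b])))
}

#' Contribution decomposition across a panel of outcomes
#'
#' Runs [contributions()] for every outcome feature (cytokines or blood
#' tests). In `"linked"` mode a category contributes the features
#' significantly correlated with that outcome in `network`; outcomes with no
#' linked feature in any category are skipped with a message. In `"all"`
#' mode every feature of each category block enters.
#'
#' @param outcomes An [omics_block()] of outcomes (features x samples).
#' @param category_blocks Named list of exposome [omics_block()]s (values on
#'   the analysis scale, samples aligned with `outcomes`).
#' @param network Correlation network (required for `mode = "linked"`).
#' @param mode `"linked"` or `"all"`.
#' @param var_threshold,n_components,scale. Passed to [contributions()].
#' @return Data frame with one row per analysed outcome: `outcome`, `r2`,
#'   one `share_<category>` column per category, and per-category PC counts.
#' @export
exposome_contributions <- function(outcomes, category_blocks, network = NULL,
                                   mode = c("all", "linked"),
                                   var_threshold = 0.8, n_components = NULL,
                                   scale. = TRUE) {
  mode <- match.arg(mode)
  if (mode == "linked" && is.null(network)) {
    stop("mode = 'linked' needs a correlation network")
  }
  cats <- names(category_blocks)
  rows <- list()
  for (f in feature_ids(outcomes)) {
    y <- outcomes$values[f, ]
    if (anyNA(y)) { message("skipping ", f, ": missing values"); next }
    blocks <- list()
    for (cat in cats) {
      feats <- if (mode == "all") feature_ids(category_blocks[[cat]]) else
        linked_features(network, f, outcomes$ome, cat)
      if (length(feats) == 0) next
      blocks[[cat]] <- t(category_blocks[[cat]]$values[feats, , drop = FALSE])
    }
    if (length(blocks) == 0) {
      message("skipping ", f, ": no linked exposome features")
      next
    }
    res <- tryCatch(
      contributions(y, blocks, var_threshold, n_components, scale.),
      error = function(e) { message("skipping ", f, ": ", conditionMessage(e)); NULL })
    if (is.null(res)) next
    row <- data.frame(outcome = f, r2 = res$r2, stringsAsFactors = FALSE)
    for (cat in cats) {
      row[[paste0("share_", cat)]] <-
        if (cat %in% names(res$shares)) res$shares[[cat]] else 0
      row[[paste0("n_pcs_", cat)]] <-
        if (cat %in% names(res$n_pcs)) res$n_pcs[[cat]] else 0L
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0) {
    stop("no outcome could be analysed")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summaries of explained outcome variation
#'
#' Aggregates per-outcome R-squared values into panel-level summaries: the
#' unweighted mean and the variance-weighted mean (each outcome weighted by
#' its total variance). Both are reported because either aggregation can be
#' meant by a panel-level "explained variation" figure.
#'
#' @param result Data frame from [exposome_contributions()].
#' @param outcomes The outcomes [omics_block()] (for the variance weights).
#' @return Named numeric vector `mean_r2`, `variance_weighted_r2`.
#' @export
explained_variation_summary <- function(result, outcomes) {
  v <- apply(outcomes$values[result$outcome, , drop = FALSE], 1,
             stats::var, na.rm = TRUE)
  c(mean_r2 = mean(result$r2),
    variance_weighted_r2 = sum(result$r2 * v) / sum(v))
}
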