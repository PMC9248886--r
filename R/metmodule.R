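#' Match metabolic features to network metabolites by adduct mass
#'
#' A feature (m/z, polarity) matches metabolite of monoisotopic mass `M`
#' under an adduct with mass shift `s` and charge `z` when the relative error
#' `|mz - (M+s)/|z|| / ((M+s)/|z|) * 1e6` is at most `ppm_tol` and the
#' polarities agree. One feature may match several metabolites or adducts.
#'
#' @param features Data frame with columns `feature_id`, `mz`, `polarity`
#'   (`"+"`/`"-"`).
#' @param network A [metabolic_network()] (nodes without a known mass are
#'   skipped).
#' @param adducts Adduct table as from [default_adducts()].
#' @param ppm_tol Mass tolerance in parts per million (default 10).
#' @return Data frame `feature_id`, `mz`, `metabolite`, `adduct`,
#'   `ppm_error`.
#' @export
match_features <- function(features, network, adducts = default_adducts(),
                           ppm_tol = 10) {
  adducts <- validate_adduct_table(adducts)
  stopifnot(ppm_tol > 0)
  req <- c("feature_id", "mz", "polarity")
  if (!all(req %in% names(features))) {
    stop("features needs columns ", paste(req, collapse = ", "))
  }
  masses <- network$masses[!is.na(network$masses)]
  if (nrow(features) == 0 || length(masses) == 0) {
    return(data.frame(feature_id = character(), mz = numeric(),
                      metabolite = character(), adduct = character(),
                      ppm_error = numeric(), stringsAsFactors = FALSE))
  }
  out <- list()
  for (a in seq_len(nrow(adducts))) {
    pred <- (masses + adducts$mass_shift[a]) / abs(adducts$charge[a])
    feats <- features[features$polarity == adducts$polarity[a], , drop = FALSE]
    if (nrow(feats) == 0) next
    # outer absolute ppm error: features x metabolites
    err <- abs(outer(feats$mz, pred, "-")) / rep(pred, each = nrow(feats)) * 1e6
    hit <- which(err <= ppm_tol, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      feature_id = feats$feature_id[hit[, 1]], mz = feats$mz[hit[, 1]],
      metabolite = names(masses)[hit[, 2]],
      adduct = adducts$adduct_name[a], ppm_error = err[hit],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(feature_id = character(), mz = numeric(),
               metabolite = character(), adduct = character(),
               ppm_error = numeric(), stringsAsFactors = FALSE)
  res <- res[order(res$feature_id, res$metabolite, res$adduct), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract the significant-plus-hidden metabolite subnetwork
#'
#' Keeps every significant metabolite present in the network plus each
#' non-significant ("hidden") metabolite lying in the interior of a simple
#' path of at most `max_steps` reactions between two distinct significant
#' metabolites. Edges are induced.
#'
#' @param network A [metabolic_network()].
#' @param significant Character vector of significant metabolite ids.
#' @param max_steps Maximum connecting path length in reactions (default 3).
#' @return An igraph graph with logical vertex attribute `significant`.
#' @export
extract_subnetwork <- function(network, significant, max_steps = 3) {
  g <- network$graph
  sig <- intersect(unique(significant), igraph::V(g)$name)
  if (length(sig) == 0) stop("empty subnetwork: no significant metabolite maps into the network")
  hidden <- character()
  if (length(sig) >= 2) {
    # interior vertices of simple connecting paths; the small step bound
    # keeps the enumeration cheap even on the full reaction network
    for (s in sig) {
      paths <- igraph::all_simple_paths(g, from = s, to = setdiff(sig, s),
                                        cutoff = max_steps)
      for (p in paths) {
        nm <- names(p)
        interior <- nm[-c(1, length(nm))]
        hidden <- c(hidden, setdiff(interior, sig))
      }
    }
    hidden <- unique(hidden)
  }
  sn <- igraph::induced_subgraph(g, c(sig, hidden))
  igraph::set_vertex_attr(sn, "significant",
                          value = igraph::V(sn)$name %in% sig)
}

#' Detect candidate modules by random-walk clustering
#'
#' Clusters the subnetwork with short-random-walk agglomeration (walktrap,
#' walk length 4), cuts the dendrogram at maximal standard modularity, splits
#' any disconnected cluster into its components, and keeps connected modules
#' with at least three nodes. Deterministic: identical input gives an
#' identical module list.
#'
#' @param sn Subnetwork from [extract_subnetwork()] (vertex attribute
#'   `significant`).
#' @param min_size Minimum module size (default 3).
#' @param steps Walk length (default 4).
#' @return List of candidate modules; each is a list with `members`,
#'   `significant` (logical per member), `n_members`, `n_edges`, `n_input`.
#' @export
detect_modules <- function(sn, min_size = 3, steps = 4) {
  if (igraph::vcount(sn) < min_size || igraph::ecount(sn) == 0) return(list())
  wt <- igraph::cluster_walktrap(sn, steps = steps)
  memb <- igraph::membership(wt)
  mods <- list()
  for (cm in sort(unique(memb))) {
    nodes <- names(memb)[memb == cm]
    sub <- igraph::induced_subgraph(sn, nodes)
    comp <- igraph::components(sub)
    for (cc in seq_len(comp$no)) {
      mem <- names(comp$membership)[comp$membership == cc]
      if (length(mem) < min_size) next
      mem <- sort(mem)
      msub <- igraph::induced_subgraph(sn, mem)
      sig <- igraph::V(msub)$significant[match(mem, igraph::V(msub)$name)]
      mods[[length(mods) + 1L]] <- list(
        members = mem, significant = sig, n_members = length(mem),
        n_edges = igraph::ecount(msub), n_input = sum(sig))
    }
  }
  # deterministic order: by first member id
  if (length(mods) > 1) {
    mods <- mods[order(vapply(mods, function(m) m$members[1], character(1)))]
  }
  mods
}

#' Module activity score
#'
#' Scores a candidate module `M` against the full metabolic network. The
#' adjusted modularity down-weights large modules by the input fraction:
#' `Q_adj = (N_I/N_M) * (E_M/m - sum_{i<j in M} k_i k_j / (2m)^2)` with `m`
#' and the degrees `k` taken from the whole network, `E_M` the module's
#' internal edge count, `N_M` its size, and `N_I` the number of input
#' (significant) metabolites. The activity score is
#' `S = Q_adj * N_IM / N_M`, where `N_IM` counts input metabolites inside
#' the module, so S rewards both internal density and input enrichment.
#'
#' @param module A candidate module from [detect_modules()].
#' @param network The full [metabolic_network()].
#' @param n_input Total number of input metabolites `N_I` (by default all
#'   significant metabolites mapped into the subnetwork under study).
#' @param pair_convention `"unordered"` (default; sum over distinct pairs
#'   `i<j`) or `"ordered_with_diagonal"` (sum over all ordered pairs).
#' @return List with `q_adj` and `s`.
#' @export
activity_score <- function(module, network, n_input,
                           pair_convention = c("unordered",
                                               "ordered_with_diagonal")) {
  pair_convention <- match.arg(pair_convention)
  if (module$n_members == 0) stop("empty module")
  if (n_input < module$n_input) stop("n_input must be >= input members")
  k <- network$degrees[module$members]
  if (anyNA(k)) {
    stop("module members missing from network: ",
         paste(module$members[is.na(k)], collapse = ", "))
  }
  m <- network$m
  s1 <- sum(k); s2 <- sum(k^2)
  pair_sum <- switch(pair_convention,
    unordered = (s1^2 - s2) / 2,
    ordered_with_diagonal = s1^2)
  q_adj <- (n_input / module$n_members) *
    (module$n_edges / m - pair_sum / (2 * m)^2)
  list(q_adj = q_adj, s = q_adj * module$n_input / module$n_members)
}

# run match -> subnetwork -> modules -> scores for one feature set;
# returns a data frame of scored modules (possibly empty)
score_feature_set <- function(features, network, adducts, ppm_tol, max_steps,
                              min_size = 3, pair_convention = "unordered") {
  empty <- data.frame(module = integer(), members = character(),
                      n_members = integer(), n_edges = integer(),
                      n_input_module = integer(), q_adj = numeric(),
                      s = numeric(), stringsAsFactors = FALSE)
  matches <- match_features(features, network, adducts, ppm_tol)
  sig_mets <- unique(matches$metabolite)
  if (length(sig_mets) == 0) return(list(scores = empty, modules = list()))
  sn <- tryCatch(extract_subnetwork(network, sig_mets, max_steps),
                 error = function(e) NULL)
  if (is.null(sn)) return(list(scores = empty, modules = list()))
  mods <- detect_modules(sn, min_size = min_size)
  if (length(mods) == 0) return(list(scores = empty, modules = list()))
  n_input <- sum(igraph::V(sn)$significant)
  rows <- lapply(seq_along(mods), function(i) {
    sc <- activity_score(mods[[i]], network, n_input,
                         pair_convention = pair_convention)
    data.frame(module = i, members = paste(mods[[i]]$members, collapse = ";"),
               n_members = mods[[i]]$n_members, n_edges = mods[[i]]$n_edges,
               n_input_module = mods[[i]]$n_input, q_adj = sc$q_adj,
               s = sc$s, stringsAsFactors = FALSE)
  })
  list(scores = do.call(rbind, rows), modules = mods)
}

#' Resampling null distribution of module activity scores
#'
#' Repeatedly draws decoy "significant" feature sets of the same size
#' uniformly without replacement from the non-significant features, reruns
#' the matching, subnetwork, module-detection and scoring steps, pools the
#' positive null activity scores (negative scores are floored at zero and
#' zeros excluded), and fits a Gamma distribution by maximum likelihood.
#'
#' @param features Data frame of all metabolic features (`feature_id`, `mz`,
#'   `polarity`).
#' @param significant_ids Feature ids of the significant set `L_sig`.
#' @param network A [metabolic_network()].
#' @param adducts Adduct table.
#' @param ppm_tol Mass tolerance in ppm (default 10).
#' @param n_resamples Number of resampled null sets (default 100).
#' @param seed Optional integer seed for the resampling.
#' @param max_steps Hidden-metabolite path bound (default 3).
#' @param min_size Minimum module size (default 3).
#' @return A `module_null` object: `s_null` (pooled positive scores),
#'   `shape`, `scale` (Gamma MLE), `n_resamples`.
#' @export
null_distribution <- function(features, significant_ids, network,
                              adducts = default_adducts(), ppm_tol = 10,
                              n_resamples = 100, seed = NULL, max_steps = 3,
                              min_size = 3) {
  pool <- setdiff(features$feature_id, significant_ids)
  n_sig <- length(intersect(features$feature_id, significant_ids))
  if (n_sig == 0) stop("no significant features present in the feature list")
  if (length(pool) < n_sig) {
    stop("not enough non-significant features to resample from")
  }
  if (!is.null(seed)) set.seed(seed)
  s_null <- numeric()
  for (r in seq_len(n_resamples)) {
    draw <- sample(pool, n_sig)
    res <- score_feature_set(features[features$feature_id %in% draw, ,
                                      drop = FALSE],
                             network, adducts, ppm_tol, max_steps, min_size)
    if (nrow(res$scores) > 0) {
      s_null <- c(s_null, pmax(0, res$scores$s))
    }
  }
  s_pos <- s_null[s_null > 0]
  if (length(s_pos) < 30) {
    stop("only ", length(s_pos),
         " positive null scores pooled; increase n_resamples")
  }
  fit <- fit_gamma_mle(s_pos)
  structure(list(s_null = s_null, shape = fit$shape, scale = fit$scale,
                 n_resamples = n_resamples),
            class = "module_null")
}

#' Gamma maximum-likelihood fit
#'
#' Fits shape and scale of a Gamma distribution to positive values by
#' maximum likelihood (via [fitdistrplus::fitdist()]).
#'
#' @param x Positive numeric values.
#' @return List with `shape` and `scale`.
#' @export
fit_gamma_mle <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0 || any(x <= 0)) stop("gamma fit needs positive values")
  if (stats::var(x) == 0) stop("degenerate fit: all values equal")
  fit <- fitdistrplus::fitdist(x, "gamma", method = "mle")
  list(shape = unname(fit$estimate["shape"]),
       scale = 1 / unname(fit$estimate["rate"]))
}

#' @export
print.module_null <- function(x, ...) {
  cat("<module_null>", length(x$s_null), "pooled null scores from",
      x$n_resamples, "resamples; Gamma(shape =",
      format(x$shape, digits = 4), ", scale =",
      format(x$scale, digits = 4), ")\n")
  invisible(x)
}

#' Module p-values from the Gamma null
#'
#' Upper-tail p-value `p = 1 - F_Gamma(S)` for each scored module;
#' non-positive scores get `p = 1`.
#'
#' @param scores Data frame of scored modules (column `s`), as returned in
#'   `score_feature_set()$scores` or [detect_dysregulated_modules()].
#' @param null A `module_null`.
#' @param alpha Significance threshold used to set the `retained` flag
#'   (default 0.05, strict).
#' @return The input data frame plus columns `p` and `retained`.
#' @export
module_pvalues <- function(scores, null, alpha = 0.05) {
  p <- ifelse(scores$s <= 0, 1,
              stats::pgamma(scores$s, shape = null$shape, scale = null$scale,
                            lower.tail = FALSE))
  scores$p <- p
  scores$retained <- p < alpha
  scores
}

#' Detect dysregulated metabolic modules
#'
#' Full workflow on a set of significant metabolic features: adduct mass
#' matching against the metabolic network, extraction of the
#' significant-plus-hidden subnetwork, random-walk module detection, activity
#' scoring, a resampled Gamma null, and upper-tail p-values. Modules with
#' `p < alpha` are flagged as retained.
#'
#' @inheritParams null_distribution
#' @param alpha Module significance threshold (default 0.05).
#' @return List with `modules` (scored module table with `p`, `retained`),
#'   `null` (the fitted `module_null`), `subnetwork`, and `matches`.
#' @export
detect_dysregulated_modules <- function(features, significant_ids, network,
                                        adducts = default_adducts(),
                                        ppm_tol = 10, n_resamples = 100,
                                        seed = NULL, max_steps = 3,
                                        min_size = 3, alpha = 0.05) {
  sig_feats <- features[features$feature_id %in% significant_ids, ,
                        drop = FALSE]
  res <- score_feature_set(sig_feats, network, adducts, ppm_tol, max_steps,
                           min_size)
  null <- null_distribution(features, significant_ids, network, adducts,
                            ppm_tol, n_resamples, seed, max_steps, min_size)
  scored <- if (nrow(res$scores) > 0) module_pvalues(res$scores, null) else {
    res$scores$p <- numeric(0); res$scores$retained <- logical(0); res$scores
  }
  matches <- match_features(sig_feats, network, adducts, ppm_tol)
  sn <- if (length(unique(matches$metabolite)) > 0) {
    extract_subnetwork(network, unique(matches$metabolite), max_steps)
  } else NULL
  list(modules = scored, null = null, subnetwork = sn, matches = matches,
       module_members = res$modules)
}
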