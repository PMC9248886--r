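#' Spearman rank correlation with t-approximation p-value
#'
#' Pairwise-deletes missing values, ranks both vectors with midranks for
#' ties, and returns the Pearson correlation of the ranks together with a
#' two-sided p-value from the t approximation on `n_obs - 2` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_n Minimum paired non-missing observations (default 5).
#' @return List with `rho`, `p`, `n_obs`.
#' @export
spearman_rho <- function(x, y, min_n = 5) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_n) {
    stop("only ", n, " paired observations (min_n = ", min_n, ")")
  }
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("constant vector: Spearman correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  list(rho = rho, p = spearman_p(rho, n), n_obs = n)
}

# two-sided p from t = rho * sqrt((n-2)/(1-rho^2)); |rho| = 1 gives p = 0
spearman_p <- function(rho, n) {
  rho <- pmin(1, pmax(-1, rho))
  p <- ifelse(abs(rho) >= 1, 0,
              2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2))
  pmin(1, p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (the study's Q-values), delegated
#' to [stats::p.adjust()] after validating the input range.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] with no NA")
  }
  stats::p.adjust(p, method = "BH")
}

new_correlation_network <- function(edges, block_pairs = NULL) {
  cols <- c("source", "source_ome", "target", "target_ome",
            "rho", "n_obs", "p", "q")
  if (nrow(edges) == 0) {
    edges <- data.frame(source = character(), source_ome = character(),
                        target = character(), target_ome = character(),
                        rho = numeric(), n_obs = integer(), p = numeric(),
                        q = numeric(), stringsAsFactors = FALSE)
  }
  edges <- edges[, cols]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- c(node_id(edges$source_ome, edges$source),
             node_id(edges$target_ome, edges$target))
  deg <- if (length(nodes) > 0) table(nodes) else table(character())
  structure(list(edges = edges,
                 degrees = stats::setNames(as.integer(deg), names(deg)),
                 block_pairs = block_pairs),
            class = "correlation_network")
}

node_id <- function(ome, feature) paste(ome, feature, sep = ":")

#' @export
print.correlation_network <- function(x, ...) {
  cat("<correlation_network>", nrow(x$edges), "significant edges among",
      length(x$degrees), "nodes\n")
  if (!is.null(x$block_pairs)) {
    cat("  block pairs:", paste(x$block_pairs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a thresholded Spearman correlation network
#'
#' For each requested block pair computes all feature-pair Spearman
#' correlations on temporally aligned samples, adjusts p-values by
#' Benjamini-Hochberg, and keeps edges with `|rho| > r_min` and `q < q_max`
#' (both strict; study thresholds 0.9 and 0.05). Intra-block pairs
#' (`"ome:ome"`) use unordered feature pairs only, with no self-edges.
#'
#' @param blocks Named list of preprocessed [omics_block()]s.
#' @param pairs Character vector of block pairs `"omeA:omeB"`; an entry
#'   `"ome:ome"` requests the intra-block analysis.
#' @param alignments Optional named list (same names as `pairs`) of alignment
#'   data frames from [align_blocks()]. Missing entries are computed from the
#'   blocks' sample windows, or taken as the identity when sample ids match.
#' @param r_min Absolute correlation threshold (default 0.9).
#' @param q_max FDR threshold (default 0.05).
#' @param min_n Minimum aligned non-missing samples per pair (default 5);
#'   pairs below it, or with a constant member, are skipped.
#' @param fdr_scope Family for the BH adjustment: `"pair"` (all tests of one
#'   block pair, the default), `"per_variable"` (each source feature against
#'   the whole partner block), or `"global"` (all tests of all requested
#'   pairs).
#' @param tolerance_days Passed to [align_blocks()] when alignments are
#'   computed here.
#' @return A `correlation_network`: significant edges with `rho`, `n_obs`,
#'   `p`, `q`, plus node degrees.
#' @export
build_network <- function(blocks, pairs, alignments = NULL, r_min = 0.9,
                          q_max = 0.05, min_n = 5,
                          fdr_scope = c("pair", "per_variable", "global"),
                          tolerance_days = 2) {
  fdr_scope <- match.arg(fdr_scope)
  pair_list <- lapply(pairs, function(p) strsplit(p, ":", fixed = TRUE)[[1]])
  for (pl in pair_list) {
    if (length(pl) != 2 || !all(pl %in% names(blocks))) {
      stop("pair must name two blocks as 'a:b'; unknown: ",
           paste(pl, collapse = ":"))
    }
  }
  tests <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    oa <- pair_list[[i]][1]; ob <- pair_list[[i]][2]
    ba <- blocks[[oa]]; bb <- blocks[[ob]]
    al <- if (!is.null(alignments) && pairs[i] %in% names(alignments)) {
      alignments[[pairs[i]]]
    } else if (identical(sample_ids(ba), sample_ids(bb))) {
      data.frame(sample_a = sample_ids(ba), sample_b = sample_ids(bb),
                 stringsAsFactors = FALSE)
    } else {
      align_blocks(ba, bb, tolerance_days)
    }
    if (nrow(al) == 0) stop("empty alignment for pair ", pairs[i])
    va <- ba$values[, al$sample_a, drop = FALSE]
    vb <- bb$values[, al$sample_b, drop = FALSE]
    tests[[i]] <- pair_correlations(va, vb, oa, ob, intra = oa == ob,
                                    min_n = min_n)
  }
  adjust_in <- function(df, scope_id) {
    if (nrow(df) == 0) { df$q <- numeric(0); return(df) }
    df$q <- NA_real_
    for (s in unique(scope_id)) {
      idx <- scope_id == s
      df$q[idx] <- bh_adjust(df$p[idx])
    }
    df
  }
  all_tests <- do.call(rbind, tests)
  if (is.null(all_tests) || nrow(all_tests) == 0) {
    return(new_correlation_network(data.frame(), block_pairs = pairs))
  }
  scope_id <- switch(fdr_scope,
    global = rep("all", nrow(all_tests)),
    pair = all_tests$block_pair,
    per_variable = paste(all_tests$block_pair, all_tests$source, sep = "\r"))
  all_tests <- adjust_in(all_tests, scope_id)
  keep <- abs(all_tests$rho) > r_min & all_tests$q < q_max
  new_correlation_network(all_tests[keep, , drop = FALSE], block_pairs = pairs)
}

# all feature-pair Spearman tests for one aligned block pair
pair_correlations <- function(va, vb, ome_a, ome_b, intra, min_n) {
  n <- ncol(va)
  complete <- !anyNA(va) && !anyNA(vb)
  fa <- rownames(va); fb <- rownames(vb)
  if (complete && n >= min_n) {
    ra <- t(apply(va, 1, rank))
    rb <- t(apply(vb, 1, rank))
    sd_a <- apply(ra, 1, stats::sd); sd_b <- apply(rb, 1, stats::sd)
    rho <- suppressWarnings(stats::cor(t(ra), t(rb)))
    idx <- arrayInd(seq_along(rho), dim(rho))
    df <- data.frame(source = fa[idx[, 1]], target = fb[idx[, 2]],
                     rho = rho[idx], n_obs = n, stringsAsFactors = FALSE)
    df <- df[sd_a[idx[, 1]] > 0 & sd_b[idx[, 2]] > 0, , drop = FALSE]
  } else {
    rows <- list()
    for (i in seq_along(fa)) {
      for (j in seq_along(fb)) {
        res <- tryCatch(spearman_rho(va[i, ], vb[j, ], min_n = min_n),
                        error = function(e) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          source = fa[i], target = fb[j], rho = res$rho, n_obs = res$n_obs,
          stringsAsFactors = FALSE)
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(source = character(), target = character(), rho = numeric(),
                 n_obs = integer(), stringsAsFactors = FALSE)
  }
  if (intra) {
    df <- df[match(df$source, fa) < match(df$target, fa), , drop = FALSE]
  }
  df$p <- spearman_p(df$rho, df$n_obs)
  df$source_ome <- ome_a
  df$target_ome <- ome_b
  df$block_pair <- paste(ome_a, ome_b, sep = ":")
  df
}

#' High-degree node table
#'
#' Nodes of a correlation network with degree strictly above `min_degree`,
#' sorted by decreasing degree then ascending node id (stable tie-break).
#'
#' @param network A `correlation_network`.
#' @param min_degree Strict lower bound (default 0: every connected node).
#' @return Data frame `node`, `degree`.
#' @export
degree_table <- function(network, min_degree = 0) {
  deg <- network$degrees
  deg <- deg[deg > min_degree]
  out <- data.frame(node = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation network as an igraph graph
#'
#' @param network A `correlation_network`.
#' @return An undirected igraph graph with `rho`, `p`, `q` edge attributes
#'   and `ome` vertex attribute.
#' @export
as_igraph <- function(network) {
  ed <- network$edges
  df <- data.frame(from = node_id(ed$source_ome, ed$source),
                   to = node_id(ed$target_ome, ed$target),
                   rho = ed$rho, p = ed$p, q = ed$q,
                   stringsAsFactors = FALSE)
  verts <- unique(data.frame(name = c(df$from, df$to),
                             ome = c(ed$source_ome, ed$target_ome),
                             stringsAsFactors = FALSE))
  verts <- verts[order(verts$name), , drop = FALSE]
  igraph::graph_from_data_frame(df, directed = FALSE, vertices = verts)
}
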