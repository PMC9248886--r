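#' Upper-tail hypergeometric test
#'
#' Probability of observing `k` or more members of a size-`K` pathway in a
#' draw of `n` features from a universe of `N`, i.e. the classical
#' over-representation p-value `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param N Universe size.
#' @param K Pathway members inside the universe.
#' @param n Selected set size.
#' @param k Hits (selected members in the pathway).
#' @return The p-value.
#' @export
hypergeom_test <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation analysis
#'
#' Hypergeometric test per pathway with Benjamini-Hochberg adjustment across
#' the tested pathways. Pathways are intersected with the universe before
#' counting; pathways disjoint from the universe are skipped. Retained
#' pathways satisfy `q < q_max` and hit count `k > min_hits` (both strict;
#' the study keeps protein pathways with more than 3 hits).
#'
#' @param selected Character vector of selected feature ids (must be a
#'   subset of `universe`).
#' @param universe Character vector of all measured feature ids.
#' @param pathways Pathway list from [read_gmt()] (or any list of elements
#'   with `pathway_id` and `members`).
#' @param min_hits Strict lower bound on hits for retention (default 3 for
#'   protein mode; use 0 for metabolite pathways).
#' @param q_max FDR threshold (default 0.05).
#' @param keep_all Return every tested pathway (with a `retained` flag)
#'   instead of only the retained ones.
#' @return Data frame `pathway_id`, `N`, `K`, `n`, `k`, `p`, `q`,
#'   `retained`, sorted by `p`.
#' @export
enrich <- function(selected, universe, pathways, min_hits = 3, q_max = 0.05,
                   keep_all = FALSE) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(universe) == 0) stop("empty universe")
  outside <- setdiff(selected, universe)
  if (length(outside) > 0) {
    stop("selected ids outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  rows <- list()
  skipped <- 0L
  for (pw in pathways) {
    members <- intersect(unique(pw$members), universe)
    if (length(members) == 0) { skipped <- skipped + 1L; next }
    k <- length(intersect(members, selected))
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_id = pw$pathway_id, N = length(universe), K = length(members),
      n = length(selected), k = k,
      p = hypergeom_test(length(universe), length(members), length(selected), k),
      stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    message("enrich: skipped ", skipped, " pathway(s) disjoint from the universe")
  }
  if (length(rows) == 0) {
    out <- data.frame(pathway_id = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p = numeric(),
                      q = numeric(), retained = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$retained <- out$q < q_max & out$k > min_hits
  out <- out[order(out$p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  if (keep_all) out else out[out$retained, , drop = FALSE]
}
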