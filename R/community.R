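#' Edge betweenness scores
#'
#' For each edge of a simple undirected graph, the sum over unordered node
#' pairs of the fraction of shortest (unweighted) paths between them passing
#' through that edge, endpoints included.
#'
#' @param graph An undirected igraph graph.
#' @return Named numeric vector (names `"a|b"` with the incident vertices in
#'   sorted order).
#' @export
edge_betweenness_scores <- function(graph) {
  if (igraph::ecount(graph) == 0) return(stats::setNames(numeric(), character()))
  eb <- igraph::edge_betweenness(graph, directed = FALSE, weights = NA)
  stats::setNames(eb, edge_keys(graph))
}

edge_keys <- function(graph) {
  en <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  paste(pmin(en[, 1], en[, 2]), pmax(en[, 1], en[, 2]), sep = "|")
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the single edge with the highest betweenness (ties
#' broken by lexicographically smallest sorted vertex-name pair),
#' recomputing betweenness after every removal, until no edges remain. After
#' each removal the connected-component partition is scored with
#' Newman-Girvan modularity computed against the *original* graph
#' (`Q = sum_c (e_c/m - (d_c/2m)^2)` with `m` fixed to the original edge
#' count), and the partition maximizing Q is returned. The initial
#' connected-component partition is included as a candidate, so the best Q is
#' never below it.
#'
#' @param graph An undirected igraph graph with at least one edge.
#' @return List with `partition` (an `exponet_partition`: `membership` named
#'   by vertex, `n_communities`, `modularity`) and `trace` (data frame
#'   `iteration`, `removed_edge`, `modularity`).
#' @export
girvan_newman <- function(graph) {
  if (igraph::ecount(graph) < 1) stop("graph needs at least one edge")
  if (is.null(igraph::V(graph)$name)) {
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))
  }
  g0 <- graph
  memb0 <- igraph::components(g0)$membership
  best_q <- igraph::modularity(g0, memb0)
  best_memb <- memb0
  g <- graph
  it <- 0L
  trace <- list()
  while (igraph::ecount(g) > 0) {
    it <- it + 1L
    eb <- igraph::edge_betweenness(g, directed = FALSE, weights = NA)
    keys <- edge_keys(g)
    top <- which(eb >= max(eb) - 1e-9 * max(1, max(eb)))
    pick <- top[order(keys[top])][1]
    removed <- keys[pick]
    g <- igraph::delete_edges(g, pick)
    memb <- igraph::components(g)$membership
    q <- igraph::modularity(g0, memb[igraph::V(g0)$name])
    trace[[it]] <- data.frame(iteration = it, removed_edge = removed,
                              modularity = q, stringsAsFactors = FALSE)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_memb <- memb
    }
  }
  part <- new_partition(best_memb, best_q)
  list(partition = part, trace = do.call(rbind, trace))
}

new_partition <- function(membership, modularity) {
  membership <- stats::setNames(as.integer(membership), names(membership))
  structure(list(membership = membership,
                 n_communities = length(unique(stats::na.omit(membership))),
                 modularity = modularity),
            class = "exponet_partition")
}

#' @export
print.exponet_partition <- function(x, ...) {
  cat("<exponet_partition>", x$n_communities, "communities over",
      length(x$membership), "nodes; Q =", format(x$modularity, digits = 4),
      "\n")
  invisible(x)
}

#' Drop small communities from a partition
#'
#' Communities with fewer than `min_size` nodes are removed; their nodes
#' become unassigned (`NA`). The study keeps clusters of at least three
#' nodes.
#'
#' @param partition An `exponet_partition`.
#' @param min_size Minimum community size (default 3, inclusive).
#' @return The filtered partition (modularity unchanged: it refers to the
#'   unfiltered partition of the full network).
#' @export
filter_communities <- function(partition, min_size = 3) {
  memb <- partition$membership
  sizes <- table(memb)
  small <- as.integer(names(sizes)[sizes < min_size])
  memb[memb %in% small] <- NA_integer_
  new_partition(memb, partition$modularity)
}

#' Community membership as a data frame
#'
#' @param partition An `exponet_partition`.
#' @return Data frame `node`, `community` (NA for unassigned nodes), sorted
#'   by community size (largest first) then node id.
#' @export
community_table <- function(partition) {
  df <- data.frame(node = names(partition$membership),
                   community = as.integer(partition$membership),
                   stringsAsFactors = FALSE)
  sizes <- table(df$community)
  df$size <- as.integer(sizes[as.character(df$community)])
  df <- df[order(-ifelse(is.na(df$size), -1L, df$size), df$community, df$node), ]
  rownames(df) <- NULL
  df[, c("node", "community", "size")]
}
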