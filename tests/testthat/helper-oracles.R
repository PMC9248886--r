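# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the definition, not by calling the code path it checks.

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} ( p_(j) * N / j ), capped at 1, in input order
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Spearman rho as Pearson correlation of midranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# upper-tail hypergeometric p by direct combinatorial summation;
# choose() is exact in double precision for N <= 25
oracle_hypergeom <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# edge betweenness by all-pairs BFS shortest-path counting (pure R):
# edge (u,v) lies on an s-t geodesic iff d(s,u)+1+d(v,t) == d(s,t) (either
# orientation); the number of such geodesics is nsp_s(u) * nsp_t(v)
oracle_edge_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs_counts <- function(s) {
    d <- rep(Inf, n); nsp <- numeric(n)
    d[s] <- 0; nsp[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer()
      for (u in frontier) {
        for (v in which(adj[u, ] == 1)) {
          if (is.infinite(d[v])) {
            d[v] <- d[u] + 1
            nxt <- c(nxt, v)
          }
          if (d[v] == d[u] + 1) nsp[v] <- nsp[v] + nsp[u]
        }
      }
      frontier <- unique(nxt)
    }
    list(d = d, nsp = nsp)
  }
  info <- lapply(seq_len(n), bfs_counts)
  edges <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  eb <- numeric(nrow(edges))
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ds <- info[[s]]; dt <- info[[t]]
      if (is.infinite(ds$d[t])) next
      total <- ds$nsp[t]
      for (e in seq_len(nrow(edges))) {
        u <- edges[e, 1]; v <- edges[e, 2]
        thr <- 0
        if (ds$d[u] + 1 + dt$d[v] == ds$d[t]) {
          thr <- thr + ds$nsp[u] * dt$nsp[v]
        }
        if (ds$d[v] + 1 + dt$d[u] == ds$d[t]) {
          thr <- thr + ds$nsp[v] * dt$nsp[u]
        }
        eb[e] <- eb[e] + thr / total
      }
    }
  }
  data.frame(u = edges[, 1], v = edges[, 2], betweenness = eb)
}

# module activity score by direct summation over unordered member pairs
oracle_activity <- function(members, n_edges, n_input_module, degrees, m,
                            n_input) {
  k <- degrees[members]
  pair_sum <- 0
  nm <- length(members)
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      pair_sum <- pair_sum + (k[i] / (2 * m)) * (k[j] / (2 * m))
    }
  }
  q_adj <- (n_input / nm) * (n_edges / m - pair_sum)
  list(q_adj = unname(q_adj), s = unname(q_adj * n_input_module / nm))
}

# gamma MLE via the profile likelihood: shape solves
# log(a) - digamma(a) = log(mean(x)) - mean(log(x)); scale = mean(x)/shape
oracle_gamma_mle <- function(x) {
  s <- log(mean(x)) - mean(log(x))
  a <- stats::uniroot(function(a) log(a) - digamma(a) - s,
                      c(1e-6, 1e6), tol = 1e-12)$root
  list(shape = a, scale = mean(x) / a)
}

# independent recount of significant block-pair correlations: per-pair
# rank/Pearson, t-approximation p, BH across the family, strict thresholds
oracle_count_edges <- function(va, vb, r_min = 0.9, q_max = 0.05) {
  rows <- expand.grid(i = seq_len(nrow(va)), j = seq_len(nrow(vb)))
  rho <- p <- numeric(nrow(rows))
  n <- ncol(va)
  for (r in seq_len(nrow(rows))) {
    rho[r] <- oracle_spearman(va[rows$i[r], ], vb[rows$j[r], ])
    tt <- abs(rho[r]) * sqrt((n - 2) / (1 - rho[r]^2))
    p[r] <- if (abs(rho[r]) >= 1) 0 else 2 * stats::pt(-tt, n - 2)
  }
  q <- oracle_bh(p)
  keep <- abs(rho) > r_min & q < q_max
  data.frame(source = rownames(va)[rows$i[keep]],
             target = rownames(vb)[rows$j[keep]],
             stringsAsFactors = FALSE)
}

# toy graphs shared across tests
two_cliques_graph <- function() {
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(1, 5))
  igraph::set_vertex_attr(g, "name", value = letters[1:8])
}

random_graph <- function(n, p_edge) {
  g <- igraph::sample_gnp(n, p_edge)
  igraph::set_vertex_attr(g, "name", value = sprintf("v%02d", seq_len(n)))
}
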