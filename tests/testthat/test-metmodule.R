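toy_network <- function() {
  # triangle x-y-z hanging off a path x-a-b-c-d: 7 edges
  metabolic_network(
    data.frame(from = c("x", "y", "x", "x", "a", "b", "c"),
               to = c("y", "z", "z", "a", "b", "c", "d")),
    stats::setNames(c(180.0634, 120.5, 250.25, 310.1, 410.2, 90.05, 505.4),
                    c("x", "y", "z", "a", "b", "c", "d")))
}

test_that("adduct matching applies the ppm tolerance per polarity", {
  net <- toy_network()
  feats <- data.frame(feature_id = "F1", mz = 181.0707, polarity = "+",
                      stringsAsFactors = FALSE)
  m <- match_features(feats, net, ppm_tol = 10)
  hit <- m[m$adduct == "[M+H]+", ]
  expect_equal(hit$metabolite, "x")       # 180.0634 + 1.007276 = 181.070676
  expect_lt(hit$ppm_error, 1)

  expect_equal(nrow(match_features(feats[0, ], net)), 0L)
  expect_equal(nrow(match_features(feats, net, ppm_tol = 0.01)), 0L)
  neg <- feats; neg$polarity <- "-"
  expect_false("[M+H]+" %in% match_features(neg, net)$adduct)
  expect_error(match_features(feats, net,
                              adducts = default_adducts()[0, ]), "empty")
})

test_that("subnetwork extraction includes hidden connectors within 3 steps", {
  path4 <- metabolic_network(
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")),
    stats::setNames(rep(100, 4), LETTERS[1:4]))
  sn <- extract_subnetwork(path4, c("A", "D"))
  expect_setequal(igraph::V(sn)$name, c("A", "B", "C", "D"))

  path5 <- metabolic_network(
    data.frame(from = c("A", "B", "C", "D"), to = c("B", "C", "D", "E")),
    stats::setNames(rep(100, 5), LETTERS[1:5]))
  sn2 <- extract_subnetwork(path5, c("A", "E"))  # shortest connection 4 > 3
  expect_setequal(igraph::V(sn2)$name, c("A", "E"))
  expect_equal(igraph::ecount(sn2), 0)

  sn3 <- extract_subnetwork(path4, c("A", "B"))
  expect_setequal(igraph::V(sn3)$name, c("A", "B"))
  expect_equal(igraph::ecount(sn3), 1)

  expect_error(extract_subnetwork(path4, "missing"), "empty subnetwork")

  # monotone in the step bound
  set.seed(31)
  g <- igraph::sample_gnp(30, 0.08)
  ids <- sprintf("M%02d", 1:30)
  el <- igraph::as_edgelist(g)
  net <- metabolic_network(
    data.frame(from = ids[el[, 1]], to = ids[el[, 2]]),
    stats::setNames(runif(30, 80, 600), ids))
  sig <- sample(ids, 6)
  sn_a <- extract_subnetwork(net, sig, max_steps = 2)
  sn_b <- extract_subnetwork(net, sig, max_steps = 3)
  expect_true(all(igraph::V(sn_a)$name %in% igraph::V(sn_b)$name))
})

test_that("module detection recovers planted cliques deterministically", {
  g <- two_cliques_graph()
  sn <- igraph::set_vertex_attr(g, "significant", value = TRUE)
  mods <- detect_modules(sn)
  expect_length(mods, 2L)
  expect_setequal(mods[[1]]$members, letters[1:4])
  expect_setequal(mods[[2]]$members, letters[5:8])
  expect_equal(mods[[1]]$n_edges, 6)

  tiny <- igraph::set_vertex_attr(igraph::make_graph(~ a - b), "significant",
                                  value = TRUE)
  expect_length(detect_modules(tiny), 0L)

  mods2 <- detect_modules(sn)
  expect_identical(mods, mods2)
})

test_that("activity score matches the pairwise-summation oracle", {
  net <- toy_network()
  mod <- list(members = c("x", "y", "z"),
              significant = c(TRUE, TRUE, FALSE),
              n_members = 3L, n_edges = 3L, n_input = 2L)
  sc <- activity_score(mod, net, n_input = 2)
  ref <- oracle_activity(c("x", "y", "z"), 3, 2, net$degrees, net$m, 2)
  expect_equal(sc$q_adj, ref$q_adj, tolerance = 1e-12)
  expect_equal(sc$s, ref$s, tolerance = 1e-12)
  # frozen values from the oracle: Q_adj = (2/3)(3/7 - 16/196), S = Q_adj*2/3
  expect_equal(sc$q_adj, 0.2312925, tolerance = 1e-6)
  expect_equal(sc$s, 0.1541950, tolerance = 1e-6)

  none <- mod; none$significant <- rep(FALSE, 3); none$n_input <- 0L
  sc0 <- activity_score(none, net, n_input = 0)
  expect_equal(sc0$q_adj, 0)
  expect_equal(sc0$s, 0)

  # whole network, all inputs: S equals Q_adj
  all_m <- sort(names(net$degrees))
  whole <- list(members = all_m, significant = rep(TRUE, 7),
                n_members = 7L, n_edges = 7L, n_input = 7L)
  sw <- activity_score(whole, net, n_input = 7)
  expect_equal(sw$s, sw$q_adj)

  # random-module property check against the oracle
  set.seed(32)
  for (i in 1:10) {
    g <- igraph::sample_gnp(10, 0.4)
    ids <- sprintf("N%02d", 1:10)
    el <- igraph::as_edgelist(g)
    if (nrow(el) < 3) next
    rnet <- metabolic_network(
      data.frame(from = ids[el[, 1]], to = ids[el[, 2]]),
      stats::setNames(runif(10, 80, 600), ids))
    mem <- sample(names(rnet$degrees), 4)
    sub <- igraph::induced_subgraph(rnet$graph, mem)
    cm <- list(members = mem, significant = c(TRUE, TRUE, FALSE, FALSE),
               n_members = 4L, n_edges = igraph::ecount(sub), n_input = 2L)
    got <- activity_score(cm, rnet, n_input = 3)
    want <- oracle_activity(mem, cm$n_edges, 2, rnet$degrees, rnet$m, 3)
    expect_equal(got$q_adj, want$q_adj, tolerance = 1e-12)
    expect_equal(got$s, want$s, tolerance = 1e-12)
  }
})

test_that("gamma MLE recovers parameters and rejects degenerate input", {
  set.seed(33)
  x <- rgamma(10000, shape = 2, scale = 3)
  fit <- fit_gamma_mle(x)
  ref <- oracle_gamma_mle(x)
  expect_equal(fit$shape, ref$shape, tolerance = 1e-3)
  expect_equal(fit$scale, ref$scale, tolerance = 1e-3)
  expect_lt(abs(fit$shape - 2) / 2, 0.05)
  expect_lt(abs(fit$scale - 3) / 3, 0.05)

  expect_error(fit_gamma_mle(rep(0.5, 40)), "degenerate")
  expect_error(fit_gamma_mle(c(-1, 2)), "positive")
})

test_that("module p-values follow the fitted gamma tail", {
  null <- structure(list(s_null = numeric(), shape = 1, scale = 2,
                         n_resamples = 100), class = "module_null")
  scores <- data.frame(module = 1:3, s = c(0, 2, 50))
  out <- module_pvalues(scores, null)
  expect_equal(out$p[1], 1)                 # S = 0
  expect_equal(out$p[2], exp(-1), tolerance = 1e-9)  # exponential at S = theta
  expect_lt(out$p[3], 1e-10)                # deep tail
  expect_equal(out$retained, c(FALSE, FALSE, TRUE))
})

test_that("the resampling null is seeded and reproducible", {
  spec <- simulation_spec(seed = 5)
  met <- simulate_metabolic_study(spec)
  n1 <- null_distribution(met$features, met$significant_ids, met$network,
                          n_resamples = 30, seed = 99)
  n2 <- null_distribution(met$features, met$significant_ids, met$network,
                          n_resamples = 30, seed = 99)
  expect_identical(n1$s_null, n2$s_null)
  expect_equal(n1$shape, n2$shape)
  expect_gt(n1$shape, 0)
  expect_gt(n1$scale, 0)
})

test_that("the full module workflow flags the planted module", {
  spec <- simulation_spec(seed = 4)
  met <- simulate_metabolic_study(spec)
  res <- detect_dysregulated_modules(met$features, met$significant_ids,
                                     met$network, seed = 17)
  kept <- res$modules[res$modules$retained, , drop = FALSE]
  expect_gt(nrow(kept), 0)
  overlap <- vapply(strsplit(kept$members, ";"), function(m) {
    length(intersect(m, met$module_members)) / length(met$module_members)
  }, numeric(1))
  expect_gt(max(overlap), 0.5)
  expect_true(all(res$modules$p >= 0 & res$modules$p <= 1))
})
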