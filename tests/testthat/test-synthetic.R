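test_that("generators are pure functions of the spec", {
  spec <- simulation_spec(seed = 12)
  a <- simulate_blocks(spec)
  b <- simulate_blocks(spec)
  expect_identical(a$blocks$chemical$values, b$blocks$chemical$values)
  expect_identical(a$windows, b$windows)

  ma <- simulate_metabolic_study(spec)
  mb <- simulate_metabolic_study(spec)
  expect_identical(igraph::as_edgelist(ma$network$graph),
                   igraph::as_edgelist(mb$network$graph))
  expect_identical(ma$features, mb$features)

  oa <- simulate_outcomes(spec, a)
  ob <- simulate_outcomes(spec, b)
  expect_identical(oa$outcomes$values, ob$outcomes$values)

  other <- simulate_blocks(simulation_spec(seed = 13))
  expect_false(identical(a$blocks$chemical$values,
                         other$blocks$chemical$values))
})

test_that("collection windows mirror the study calendar", {
  spec <- simulation_spec(seed = 12)
  w <- simulate_blocks(spec)$windows
  expect_equal(nrow(w), 18L)
  expect_equal(w$start_date[1], as.Date("2016-01-15"))
  lens <- as.integer(w$end_date - w$start_date) + 1L
  expect_true(all(lens %in% 1:3))
  # consecutive: each window starts the day after the previous one ends
  expect_equal(w$start_date[-1], w$end_date[-nrow(w)] + 1)
})

test_that("planted pairs hit their target rank correlation", {
  # rho target 1 with no noise: sample Spearman exactly 1
  pp <- data.frame(ome_a = "chemical", feature_a = 9, ome_b = "metabolome",
                   feature_b = 1, rho = 1, sign = 1)
  spec <- simulation_spec(seed = 14, planted_pairs = pp)
  sim <- simulate_blocks(spec)
  x <- sim$blocks$chemical$values[pp$feature_a, ]
  y <- sim$blocks$metabolome$values[pp$feature_b, ]
  expect_equal(spearman_rho(x, y)$rho, 1)

  # negative sign flips the correlation
  ppn <- pp; ppn$sign <- -1
  simn <- simulate_blocks(simulation_spec(seed = 14, planted_pairs = ppn))
  expect_equal(spearman_rho(simn$blocks$chemical$values[9, ],
                            simn$blocks$metabolome$values[1, ])$rho, -1)

  # at rho 0.97 the average sample Spearman across seeds sits near target
  rhos <- vapply(1:15, function(s) {
    sm <- simulate_blocks(simulation_spec(seed = 100 + s))
    tp <- sm$truth$planted_pairs[1, ]
    spearman_rho(sm$blocks$chemical$values[tp$id_a, ],
                 sm$blocks$metabolome$values[tp$id_b, ])$rho
  }, numeric(1))
  expect_gt(mean(abs(rhos)), 0.9)
})

test_that("missingness masking respects the configured rate", {
  spec <- simulation_spec(seed = 15, missing_rate = 0.1)
  sim <- simulate_blocks(spec)
  all_v <- unlist(lapply(sim$blocks, function(b) b$values))
  rate <- mean(is.na(all_v))
  expect_gt(rate, 0.06)
  expect_lt(rate, 0.14)
  expect_false(anyNA(simulate_blocks(simulation_spec(seed = 15))$blocks$chemical$values))
})

test_that("the metabolic study plants a dense, uniquely matchable module", {
  spec <- simulation_spec(seed = 16)
  met <- simulate_metabolic_study(spec)
  # density 1, size 8: all 28 internal edges present
  sub <- igraph::induced_subgraph(met$network$graph, met$module_members)
  expect_equal(igraph::ecount(sub), choose(8, 2))
  # mass grid spacing 0.05 Da: every feature matches exactly one metabolite
  m <- match_features(met$features, met$network, ppm_tol = 10)
  expect_equal(nrow(m), nrow(met$features))
  expect_equal(m$metabolite[match(met$features$feature_id, m$feature_id)],
               met$features$metabolite)
  expect_length(met$significant_ids, 8L)
})

test_that("outcome generation encodes the planted contribution structure", {
  # single nonzero beta, no noise: R^2 = 1 and that category takes all
  spec1 <- simulation_spec(
    seed = 17,
    outcome_effects = list(betas = c(chemical = 1, biological = 0,
                                     environmental = 0),
                           r2_target = 1, n_outcomes = 2))
  sim1 <- simulate_blocks(spec1)
  out1 <- simulate_outcomes(spec1, sim1)
  expect_equal(out1$truth$noise_sd, 0)
  y <- out1$outcomes$values[1, ]
  drv <- sim1$truth$drivers$chemical
  x <- t(log2(sim1$blocks$chemical$values[drv, ] + 1))
  expect_equal(fit_r2(y, stats::prcomp(x, scale. = TRUE)$x[, 1, drop = FALSE]),
               1, tolerance = 1e-10)

  # all betas zero: outcomes are pure noise, estimated R^2 stays small
  r2s <- vapply(1:50, function(s) {
    spec0 <- simulation_spec(
      seed = 1000 + s,
      outcome_effects = list(betas = c(chemical = 0, biological = 0,
                                       environmental = 0),
                             r2_target = 0.6, n_outcomes = 1))
    sim0 <- simulate_blocks(spec0)
    out0 <- simulate_outcomes(spec0, sim0)
    cb <- lapply(c("chemical", "biological", "environmental"), function(o) {
      b <- log2_transform(sim0$blocks[[o]])
      b$values <- b$values[sim0$truth$drivers[[o]], , drop = FALSE]
      b
    })
    names(cb) <- c("chemical", "biological", "environmental")
    exposome_contributions(out0$outcomes, cb, mode = "all")$r2[1]
  }, numeric(1))
  expect_lt(median(r2s), 0.3)
})

test_that("a simulated study serializes to readable files", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(seed = 18)
  paths <- write_simulated_study(spec, dir)
  expect_true(all(file.exists(
    file.path(dir, c("chemical.tsv", "metabolome.tsv", "windows.tsv",
                     "metabolic_edges.tsv", "metabolite_masses.tsv",
                     "features.tsv", "adducts.tsv", "outcomes.tsv")))))
  back <- read_omics_matrix(file.path(dir, "chemical.tsv"), "chemical",
                            metadata_path = file.path(dir, "windows.tsv"))
  sim <- simulate_blocks(spec)
  expect_identical(back$values, sim$blocks$chemical$values)
  net <- read_metabolic_network(file.path(dir, "metabolic_edges.tsv"),
                                file.path(dir, "metabolite_masses.tsv"))
  expect_equal(net$m, simulate_metabolic_study(spec)$network$m)
  add <- read_adduct_table(file.path(dir, "adducts.tsv"))
  expect_equal(add, default_adducts())
})
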