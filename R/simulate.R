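#' Specification for the synthetic longitudinal study
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' emulate the structure of the monitored study: 18 collection windows of
#' 1-3 days starting 2016-01-15; exposome category blocks (chemical,
#' biological, environmental) whose leading features share a latent factor;
#' a metabolome block receiving planted monotone cross-ome pairs at
#' population Spearman 0.97, planted on the chemical block's non-driver
#' features (restricted to those 20 features versus the 21-feature
#' metabolome, the correlation family is 20 planted pairs among 400 null
#' pairs); a 60-metabolite reaction network with a planted fully connected
#' 8-node module; and outcomes driven by the chemical category's first
#' principal direction at population R-squared 0.6.
#'
#' @param seed Integer seed; every generator is a pure function of the spec.
#' @param n_timepoints Number of collection windows (default 18).
#' @param omes Named list; per ome a list with `n_features`, `n_driver`
#'   (features loading on the category latent factor), `loading` in \[0, 1).
#' @param planted_pairs Data frame `ome_a`, `feature_a`, `ome_b`,
#'   `feature_b` (integer feature indices), `rho` (target |Spearman|),
#'   `sign` (+1/-1).
#' @param planted_module List `n_nodes`, `bg_density`, `size`, `density`
#'   for the synthetic metabolic study.
#' @param outcome_effects List `betas` (named per category), `r2_target`
#'   population R-squared (noise SD derived from it), `n_outcomes`.
#' @param missing_rate Fraction of cells masked missing (default 0).
#' @param start_date First collection day (default 2016-01-15).
#' @param meanlog,sdlog Log-normal abundance scale of the blocks.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 1,
                            n_timepoints = 18,
                            omes = list(
                              chemical = list(n_features = 28, n_driver = 8,
                                              loading = 0.9),
                              biological = list(n_features = 15, n_driver = 8,
                                                loading = 0.9),
                              environmental = list(n_features = 10,
                                                   n_driver = 8,
                                                   loading = 0.9),
                              metabolome = list(n_features = 21, n_driver = 0,
                                                loading = 0)),
                            planted_pairs = default_planted_pairs(),
                            planted_module = list(n_nodes = 60,
                                                  bg_density = 0.05,
                                                  size = 8, density = 1.0),
                            outcome_effects = list(
                              betas = c(chemical = 0.8, biological = 0,
                                        environmental = 0),
                              r2_target = 0.6, n_outcomes = 5),
                            missing_rate = 0,
                            start_date = as.Date("2016-01-15"),
                            meanlog = 4, sdlog = 1) {
  stopifnot(n_timepoints >= 2, missing_rate >= 0, missing_rate < 1)
  if (!is.null(planted_pairs) && nrow(planted_pairs) > 0) {
    stopifnot(all(planted_pairs$rho > 0), all(planted_pairs$rho <= 1),
              all(planted_pairs$sign %in% c(-1, 1)))
  }
  stopifnot(planted_module$size >= 3,
            planted_module$density > 0, planted_module$density <= 1,
            planted_module$bg_density > 0, planted_module$bg_density <= 1)
  structure(list(seed = seed, n_timepoints = n_timepoints, omes = omes,
                 planted_pairs = planted_pairs,
                 planted_module = planted_module,
                 outcome_effects = outcome_effects,
                 missing_rate = missing_rate, start_date = start_date,
                 meanlog = meanlog, sdlog = sdlog),
            class = "simulation_spec")
}

# 20 chemical -> metabolome pairs at |rho| = 0.97, mixed signs; planted on
# the chemical block's free (non-driver) features so unplanted pairs are null
default_planted_pairs <- function() {
  data.frame(ome_a = "chemical", feature_a = 9:28, ome_b = "metabolome",
             feature_b = 1:20, rho = 0.97,
             sign = rep(c(1, 1, 1, -1), 5), stringsAsFactors = FALSE)
}

# deterministic sub-seed so successive generators stay independent of one
# another while remaining pure in spec$seed; kept below 2^31
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 69069 + 12345 * stream) %% 2147483647
}

#' Simulate longitudinal omics blocks with planted correlated pairs
#'
#' Unplanted features are i.i.d. log-normal across time points. Within a
#' category the first `n_driver` features share a latent Gaussian factor
#' (loading per the spec). Each planted cross-ome pair is drawn through a
#' Gaussian copula on ranks: the partner's latent is
#' `sign * (rho_g * z + sqrt(1 - rho_g^2) * eps)` with
#' `rho_g = 2 sin(pi * rho_s / 6)`, the Gaussian correlation whose
#' population Spearman is `rho_s`; the monotone log-normal transform leaves
#' Spearman untouched. Collection windows are consecutive 1-3 day intervals
#' from the spec start date, shared across omes.
#'
#' @param spec A [simulation_spec()].
#' @return List with `blocks` (named [omics_block()]s), `truth`
#'   (`planted_pairs` incl. feature ids, per-ome `drivers`, latent factor
#'   matrix `factors`), and `windows`.
#' @export
simulate_blocks <- function(spec) {
  set.seed(derive_seed(spec$seed, 1))
  n <- spec$n_timepoints
  lens <- sample(1:3, n, replace = TRUE)
  starts <- spec$start_date + c(0, cumsum(utils::head(lens, -1)))
  windows <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                        start_date = starts,
                        end_date = starts + lens - 1,
                        stringsAsFactors = FALSE)
  factors <- sapply(names(spec$omes), function(o) stats::rnorm(n))
  rownames(factors) <- windows$sample_id
  latent <- list()
  for (o in names(spec$omes)) {
    cfg <- spec$omes[[o]]
    z <- matrix(stats::rnorm(cfg$n_features * n), cfg$n_features, n)
    if (cfg$n_driver > 0) {
      lam <- cfg$loading
      for (i in seq_len(cfg$n_driver)) {
        z[i, ] <- lam * factors[, o] + sqrt(1 - lam^2) * z[i, ]
      }
    }
    rownames(z) <- sprintf("%s_f%03d", o, seq_len(cfg$n_features))
    colnames(z) <- windows$sample_id
    latent[[o]] <- z
  }
  pp <- spec$planted_pairs
  if (!is.null(pp) && nrow(pp) > 0) {
    for (r in seq_len(nrow(pp))) {
      za <- latent[[pp$ome_a[r]]][pp$feature_a[r], ]
      rho_g <- 2 * sin(pi * pp$rho[r] / 6)
      eps <- stats::rnorm(n)
      latent[[pp$ome_b[r]]][pp$feature_b[r], ] <-
        pp$sign[r] * (rho_g * za + sqrt(1 - rho_g^2) * eps)
    }
    pp$id_a <- mapply(function(o, i) rownames(latent[[o]])[i],
                      pp$ome_a, pp$feature_a)
    pp$id_b <- mapply(function(o, i) rownames(latent[[o]])[i],
                      pp$ome_b, pp$feature_b)
  }
  blocks <- list()
  for (o in names(latent)) {
    v <- exp(spec$meanlog + spec$sdlog * latent[[o]])
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(length(v)) < spec$missing_rate,
                     nrow(v), ncol(v))
      v[mask] <- NA_real_
    }
    blocks[[o]] <- omics_block(v, o, sample_windows = windows)
  }
  drivers <- lapply(spec$omes, function(cfg) {
    if (cfg$n_driver > 0) seq_len(cfg$n_driver) else integer()
  })
  list(blocks = blocks,
       truth = list(planted_pairs = pp, drivers = drivers, factors = factors),
       windows = windows)
}

#' Simulate a metabolic-network study with a planted dysregulated module
#'
#' Background reaction graph is Erdos-Renyi at the spec's density; a planted
#' module of `size` nodes gets internal edges at the planted density (1 =
#' fully connected). Monoisotopic masses are drawn without replacement from
#' a 0.05 Da grid on 80-600 Da, so at 10 ppm every simulated feature matches
#' exactly one metabolite. Every metabolite contributes one positive-mode
#' \[M+H\]+ feature; the features of planted-module members form the
#' significant set, all others are decoys.
#'
#' @param spec A [simulation_spec()].
#' @return List with `network` ([metabolic_network()]), `features` (data
#'   frame `feature_id`, `mz`, `polarity`, `metabolite`), `significant_ids`,
#'   and `module_members`.
#' @export
simulate_metabolic_study <- function(spec) {
  set.seed(derive_seed(spec$seed, 2))
  pm <- spec$planted_module
  n <- pm$n_nodes
  ids <- sprintf("C%05d", seq_len(n))
  g <- igraph::sample_gnp(n, pm$bg_density)
  ends <- igraph::as_edgelist(g)
  edges <- data.frame(from = ids[ends[, 1]], to = ids[ends[, 2]],
                      stringsAsFactors = FALSE)
  members <- sort(sample(ids, pm$size))
  pairs <- utils::combn(members, 2)
  take <- stats::runif(ncol(pairs)) <= pm$density
  mod_edges <- data.frame(from = pairs[1, take], to = pairs[2, take],
                          stringsAsFactors = FALSE)
  all_edges <- rbind(edges, mod_edges)
  grid <- seq(80, 600, by = 0.05)
  masses <- stats::setNames(sample(grid, n), ids)
  net <- suppressMessages(metabolic_network(all_edges, masses))
  proton <- 1.007276
  features <- data.frame(feature_id = paste0("F_", ids),
                         mz = unname(masses[ids]) + proton,
                         polarity = "+", metabolite = ids,
                         stringsAsFactors = FALSE)
  list(network = net, features = features,
       significant_ids = paste0("F_", members), module_members = members)
}

#' Simulate clinical outcomes from category principal directions
#'
#' Each outcome is a linear function of the per-category first principal
#' direction plus Gaussian noise:
#' `y = sum_c beta_c * PC1_c + eps`, where `PC1_c` is the standardized first
#' principal component score of the category's driver features (log2 scale)
#' and the noise SD is chosen so the population R-squared equals the spec's
#' `r2_target` (noise SD 1 when all betas are zero).
#'
#' @param spec A [simulation_spec()].
#' @param sim Output of [simulate_blocks()] for the same spec.
#' @return List with `outcomes` (an [omics_block()], outcomes x samples) and
#'   `truth` (`betas`, `noise_sd`, `r2_target`, per-outcome dominant
#'   category).
#' @export
simulate_outcomes <- function(spec, sim) {
  set.seed(derive_seed(spec$seed, 3))
  eff <- spec$outcome_effects
  betas <- eff$betas
  cats <- names(betas)
  missing_cat <- setdiff(cats, names(sim$blocks))
  if (length(missing_cat) > 0) {
    stop("outcome betas name unknown categories: ",
         paste(missing_cat, collapse = ", "))
  }
  n <- spec$n_timepoints
  pc1 <- sapply(cats, function(cat) {
    drv <- sim$truth$drivers[[cat]]
    if (length(drv) == 0) drv <- seq_len(nrow(sim$blocks[[cat]]$values))
    x <- t(log2(sim$blocks[[cat]]$values[drv, , drop = FALSE] + 1))
    if (anyNA(x)) stop("simulate_outcomes needs complete blocks (missing_rate 0)")
    s <- stats::prcomp(x, center = TRUE, scale. = TRUE)$x[, 1]
    i <- which.max(abs(stats::cor(x, s)))
    if (stats::cor(x[, i], s) < 0) s <- -s
    as.numeric(scale(s))
  })
  sig_var <- sum(betas^2)
  noise_sd <- if (sig_var == 0) 1 else
    sqrt(sig_var * (1 - eff$r2_target) / eff$r2_target)
  y <- matrix(NA_real_, eff$n_outcomes, n,
              dimnames = list(sprintf("outcome_%02d", seq_len(eff$n_outcomes)),
                              sample_ids(sim$blocks[[1]])))
  for (i in seq_len(eff$n_outcomes)) {
    y[i, ] <- drop(pc1 %*% betas) + stats::rnorm(n, sd = noise_sd)
  }
  dominant <- if (sig_var == 0) NA_character_ else cats[which.max(abs(betas))]
  list(outcomes = omics_block(y, "outcome",
                              sample_windows = sim$windows),
       truth = list(betas = betas, noise_sd = noise_sd,
                    r2_target = eff$r2_target, dominant = dominant,
                    pc1 = pc1))
}

#' Write a simulated study to disk
#'
#' Serializes every generated object in the formats the readers consume:
#' per-ome matrices and the shared window metadata as TSV, the metabolic
#' network edge list and mass table as TSV, features as TSV, and the adduct
#' table as TSV.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_simulated_study <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_blocks(spec)
  out <- character()
  for (o in names(sim$blocks)) {
    p <- file.path(dir, paste0(o, ".tsv"))
    write_omics_matrix(sim$blocks[[o]], p)
    out <- c(out, p)
  }
  wp <- file.path(dir, "windows.tsv")
  utils::write.table(sim$windows, wp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  met <- simulate_metabolic_study(spec)
  el <- igraph::as_edgelist(met$network$graph)
  ep <- file.path(dir, "metabolic_edges.tsv")
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), ep,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mp <- file.path(dir, "metabolite_masses.tsv")
  utils::write.table(
    data.frame(metabolite_id = names(met$network$masses),
               monoisotopic_mass = unname(met$network$masses)),
    mp, sep = "\t", quote = FALSE, row.names = FALSE)
  fp <- file.path(dir, "features.tsv")
  utils::write.table(met$features, fp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ap <- file.path(dir, "adducts.tsv")
  utils::write.table(default_adducts(), ap, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outc <- simulate_outcomes(spec, sim)
  op <- file.path(dir, "outcomes.tsv")
  write_omics_matrix(outc$outcomes, op)
  invisible(c(out, wp, ep, mp, fp, ap, op))
}
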