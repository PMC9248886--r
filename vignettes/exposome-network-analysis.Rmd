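---
title: "Methods: longitudinal exposome / multi-omics network analysis"
author: "exponet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal exposome / multi-omics network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

exponet implements the computational core of a longitudinal
personal-exposome study design: one individual's airborne chemical and
biological exposures, general environmental factors, and internal
multi-omics (gut microbiome, proteome, metabolome, cytokines, blood tests)
are each measured as a feature-by-sample abundance matrix over a shared
calendar of short collection windows, and the question is which external
exposures move with which internal molecules. This vignette is the
package's own account of the statistical machinery: the models, the tunable
parameters and their defaults, the synthetic data used to verify each
stage, and the numerical choices made where the design was genuinely open.

## Data model and preprocessing

An `omics_block` is a feature x sample matrix plus per-sample collection
windows (ISO dates, start <= end). Temporal alignment of two blocks
(`align_blocks`) pairs samples whose windows overlap by at least one day,
or whose gap is at most `tolerance_days` (default 2 days; collection
windows are 1-3 days long, so a short gap still represents the same
exposure episode). Ranking candidate pairs by overlap with ties broken by
earliest partner start, and accepting greedily, yields a deterministic
one-to-one map.

Preprocessing follows the standard untargeted-omics sequence:

* **Prevalence filter** (`prevalence_filter`): keep features observed in
  strictly more than one third of samples. The threshold is a strict
  inequality; fully observed features are always retained.
* **log2 transform** (`log2_transform`) with pseudocount 1 (the data are
  abundances, and a unit offset keeps zeros finite while leaving the rank
  structure, and hence every Spearman correlation downstream, untouched).
* **KNN imputation** (`knn_impute`, k = 5): a missing cell is replaced by
  the mean over the k nearest features, nearest in root-mean-square
  Euclidean distance on the samples both features observe. k = 5 balances
  variance against locality at tens-to-hundreds of features; the method is
  named by the study without a k.
* **Covariate residualization** (`residualize`): per feature, OLS on an
  intercept plus covariates; residuals are recentred at the feature mean so
  abundances stay on their original scale. The operation is idempotent to
  1e-10. The two dietary-fiber interventions recorded in the participant's
  food log (arabinoxylan 2016-01-15 to 2016-01-31, guar gum 2016-02-22 to
  2016-03-17) are encoded by `fiber_covariates` as binary window-overlap
  indicators. Whether the original analysis residualized or carried the
  covariates into downstream models is not determinable; residualization
  was chosen as the cleaner separation of concerns, and the covariate table
  is an explicit argument so either policy is available. On the synthetic
  data the generators plant no fiber effect, so the analysis scripts record
  the covariates but do not apply the adjustment: regressing 18 samples on
  an effect-free indicator only subtracts estimation noise (and the
  guar-gum indicator, overlapping a single synthetic window, would zero
  that sample's residual entirely).

## Correlation networks

All intra- and inter-ome association testing is Spearman rank correlation
(`spearman_rho`): midranks for ties, Pearson correlation of the ranks, and
a two-sided p-value from the t approximation on n - 2 degrees of freedom —
the convention of the common implementations at these sample sizes
(9-18 aligned samples). Pairs with fewer than `min_n = 5` aligned
non-missing samples, or with a constant member, are skipped.

`build_network` computes all feature pairs for each requested block pair,
adjusts p-values with Benjamini-Hochberg (`bh_adjust`, delegating to
`stats::p.adjust`), and keeps edges with |rho| > 0.9 and Q < 0.05, both
strict. The BH family is all tests of one block-pair analysis by default.
The alternative readings of the family — per source variable, or global
across every requested pair — are exposed as `fdr_scope`, because the
published description ("for each variable in one ome ... with all features
in the other omes") admits either and the printed edge counts of the
original study may require one or the other. Intra-block analyses use
unordered feature pairs with no self-pairs.

## Community analysis

`girvan_newman` removes one edge per iteration — the highest
edge-betweenness edge, ties broken by lexicographically smallest sorted
vertex pair, so results are fully deterministic — and recomputes
betweenness after every removal. After each removal the
connected-component partition is scored with Newman-Girvan modularity
`Q = sum_c (e_c/m - (d_c/2m)^2)` against the *original* graph: m stays
fixed at the original edge count so Q values along the trace are
comparable, which is the standard bookkeeping for this algorithm. The
best-Q partition is returned together with the full trace; the initial
connected-component partition is a candidate, so the result is never worse
than not splitting at all. Modularity is computed on the unweighted graph
of significant edges (correlation magnitudes are thresholded away, as in
the source procedure), before any size filtering; `filter_communities`
then drops communities with fewer than three nodes (inclusive bound:
threes survive). Edge betweenness itself counts, per edge, the fraction of
unweighted shortest paths through it over all unordered node pairs,
endpoints included — the tests verify it against a pure-R BFS
path-counting oracle on random graphs.

## Dysregulated metabolic modules

The module detector transfers an activity-score idea from untargeted
metabolomics pathway analysis (mummichog-style) to the exposome setting.
Inputs are a metabolite reaction network (nodes with monoisotopic masses,
edges = reactions), an adduct table, and the m/z features of interest
(`L_sig`, here: the metabolic features correlated with the exposome).

1. **Adduct matching** (`match_features`): feature (mz, polarity) matches
   metabolite mass M under adduct (shift s, charge z) when the relative
   error of mz against (M+s)/|z| is within `ppm_tol`. Default 10 ppm — a
   conventional high-resolution Orbitrap tolerance; the source text names
   no value. The default adduct set is the six common singly charged
   electrospray forms ([M+H]+, [M+Na]+, [M+NH4]+, [M-H]-, [M+CH3COO]-,
   [M+Cl]-).
2. **Subnetwork** (`extract_subnetwork`): matched (significant)
   metabolites plus every *hidden* metabolite in the interior of a simple
   path of at most three reactions between two distinct significant
   metabolites. Simple-path enumeration (cheap at cutoff 3) rather than a
   distance-sum criterion: a shortest-path sum d(s1,v) + d(v,s2) can
   double back through a significant node and would admit vertices that no
   actual connecting path of length <= 3 visits.
3. **Modules** (`detect_modules`): short-random-walk agglomerative
   clustering (walktrap, walk length t = 4 — the algorithm's standard
   default; deterministic by construction), dendrogram cut at maximal
   standard modularity, disconnected clusters split, modules with at least
   three nodes kept.
4. **Activity score** (`activity_score`): for module M,
   `Q_adj = (N_I/N_M) * (E_M/m - sum_{i<j in M} k_i k_j/(2m)^2)` and
   `S = Q_adj * N_IM/N_M`, with m and degrees k from the full network,
   N_M the module size, N_IM its input-metabolite count, and N_I the total
   number of input metabolites in the subnetwork. The N_I/N_M prefactor
   counteracts plain modularity's bias toward large modules. The pair sum
   is over unordered distinct pairs i < j; the published index notation
   does not pin this down, so `pair_convention = "ordered_with_diagonal"`
   is available, and N_I is switchable to N_IM by passing it as `n_input`.
5. **Gamma null** (`null_distribution`): 100 decoy feature sets of size
   |L_sig|, drawn uniformly without replacement from the non-significant
   features, are pushed through steps 1-4; all null scores are pooled
   across resamples (per-resample summaries are the unstated alternative;
   pooling uses all information and is the natural reading of fitting one
   distribution to S_null). Scores are floored at zero and zeros excluded
   before the Gamma maximum-likelihood fit (Gamma support is positive);
   fewer than 30 positive pooled scores is an error rather than a silent
   bad fit. Module p-values are the upper Gamma tail, `p = 1 - F(S)`, and
   modules with p < 0.05 are retained.

## Pathway enrichment

`hypergeom_test` is the exact upper-tail hypergeometric probability
(`P(X >= k)` via `stats::phyper`, log-space internally); `enrich` applies
it per pathway after intersecting pathway members with the universe,
adjusts across tested pathways with BH, and retains pathways with
Q < 0.05 and hits strictly greater than `min_hits` (default 3, the protein
convention; metabolite collections use 0). The universe is the set of
measured features of the relevant ome — not the union of pathway members —
because enrichment should be judged against what could have been detected;
the argument is explicit so either universe can be supplied. The hit
filter is applied after testing and adjustment (it prunes the report, not
the test family); applying it pre-FDR is the unstated alternative.

## Exposome contributions to clinical markers

For each cytokine or blood test y, `contributions` decomposes explained
variation across exposome categories:

1. Per category, features are z-scored and reduced by PCA
   (`pca_reduce`), keeping the smallest leading component set whose
   cumulative explained variance strictly exceeds 80%. Scaling is not
   stated in the source; it is the defensible default for exposome
   features with wildly heterogeneous units. Component signs follow a
   deterministic largest-loading-positive convention.
2. The kept components of all categories are concatenated; OLS with
   intercept gives R^2 (`fit_r2`).
3. A single-response NIPALS PLS over the same predictors yields VIP scores
   (`pls_vip`), `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)`; mean
   squared VIP is 1 by construction, and the implementation is
   cross-checked against an independent PLS package in the tests. The
   component count defaults to `min(5, n - 2, p)` — enough to absorb the
   few informative directions at 9-18 samples without exhausting the rank.
4. Category shares are `R^2 * sum(VIP in category)/sum(VIP)`: VIP is
   computed per principal component and summed within its category (the
   published formula indexes VIP by category directly, but the PLS
   predictors are PCs, so per-PC VIP summed by category is the faithful
   reading). Shares are non-negative and sum to R^2 exactly — an identity
   the tests assert per outcome.

Which features enter a given outcome's model is the one genuinely open
design point: the phrase "corresponding exposome component's PCs" does not
define "corresponding". The default here (`mode = "linked"` in
`exposome_contributions`) uses the exposome features significantly
correlated with that outcome in the correlation network; `mode = "all"`
enters every feature of each category. Panel-level summaries report both
the unweighted mean R^2 and the variance-weighted mean, because a single
"percent of panel variation explained" figure can be either.

## Synthetic data: what it emulates, and what it does not

`simulation_spec()` fixes the study conditions once; all generators are
pure functions of the spec (seeded, bitwise reproducible).

* **Calendar**: 18 consecutive collection windows of 1-3 days from
  2016-01-15, shared across omes.
* **Blocks**: abundances are log-normal (meanlog 4, sdlog 1), so the log2
  preprocessing is exercised on realistic positive skewed data. Within a
  category the first `n_driver` features load on a latent Gaussian factor
  (loading 0.9), giving each exposome category a dominant principal
  direction.
* **Planted correlation pairs**: 20 chemical-metabolome pairs at
  population Spearman 0.97 via a Gaussian copula on ranks — the partner
  latent is `sign * (rho_g z + sqrt(1-rho_g^2) eps)` with
  `rho_g = 2 sin(pi rho_s/6)`, the bivariate-normal correlation whose
  population Spearman is `rho_s`; the monotone log-normal transform
  preserves it exactly. Pairs are planted on non-driver chemical features,
  so restricted to those 20 features against the 21-feature metabolome the
  family is exactly 20 planted among 400 null pairs.
* **Metabolic study**: a 60-node Erdos-Renyi reaction graph (edge
  probability 0.05, mean degree ~3, sparse like real reaction networks)
  with a planted fully connected 8-node module; masses drawn without
  replacement from a 0.05 Da grid on 80-600 Da, so at 10 ppm each [M+H]+
  feature matches exactly one metabolite and matching ambiguity is
  excluded by construction.
* **Outcomes**: `y = sum_c beta_c PC1_c + eps` with beta_chemical = 0.8
  and noise SD set so the population R^2 is 0.6.

Passing tests on these data show the machinery is correct and the planted
effect sizes recoverable at the study's sample sizes. They do not show
that real exposome data meet the assumptions: real blocks have serial
autocorrelation, batch structure, heavy annotation uncertainty, correlated
nulls, and reaction networks with hubs and modules the Erdos-Renyi
background lacks. The synthetic recovery rates are properties of the
generator's conditions, not of any real data set.

## Verification sizes and numerical choices

The test suite checks the kernels against independent oracles — Spearman
vs rank-then-Pearson on 1000 random pairs, BH vs the step-up definition on
1000 random p-vectors, hypergeometric p vs full combinatorial enumeration
for all N <= 25, edge betweenness vs BFS path counting on random <= 12
node graphs, the activity score vs direct pair summation, and the Gamma
MLE vs the profile-likelihood root — plus end-to-end recovery at the
study's scale: one 420-pair correlation family, 20 seeds of
metabolic-module recovery with 100-resample nulls, 100 decoy draws for
null calibration, and 50 seeds of contribution recovery. These sizes keep
the whole suite in a few minutes while leaving the binomial error bands
tight enough to be meaningful; `scripts/acceptance.R` re-runs the same
quantities from scratch at any seed.

Numerical conventions worth knowing: strict inequalities everywhere a
threshold is quoted ("more than", "greater than"); Girvan-Newman ties
broken lexicographically and betweenness compared with a relative 1e-9
epsilon; PCA signs fixed by the largest loading; matrices and edge tables
serialized at 17 significant digits so a write-read round trip is
bit-exact; `NA` is the missing-value token throughout. Degenerate inputs
fail loudly: constant vectors in correlation, zero-variance PCA blocks,
constant outcomes, rank-deficient covariate designs (constant covariate
columns collapse into the intercept and are tolerated), all-equal null
scores, and features with no observed values are all hard errors naming
the offender.

## Known limitations

* The Gamma null is fit to pooled positive scores; if the null
  subnetworks yield almost no modules (very sparse networks or tiny
  feature sets) the fit aborts at the 30-score guard rather than
  extrapolating.
* Walktrap stands in for the unnamed "random walks" clustering of the
  source procedure; other random-walk clusterings could partition
  differently.
* The t-approximation p-value is anticonservative for n below ~7 with
  heavy ties; at the study's 9-18 aligned samples it matches the common
  implementations the field uses.
* `exposome_contributions` fits each outcome independently; no shrinkage
  is shared across the panel, and with 9-18 samples the OLS R^2 is
  optimistic by roughly p/(n-1) per fitted direction — visible in the
  synthetic recovery, where mean estimated R^2 sits slightly above the
  population 0.6.
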