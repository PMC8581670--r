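---
title: "Structural covariance networks from regional cortical thickness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks from regional cortical thickness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The problem

Structural covariance network (SCN) analysis asks how the cortical mantle
co-varies across people: two regions are "connected" in a group if subjects
with a thicker cortex in one tend to have a thicker cortex in the other.
`scnet` implements this analysis for regional mean cortical thickness (CT)
tables — one row per subject, one column per atlas region (by default 360
regions, 180 per hemisphere, mirroring modern multimodal parcellations) — for
cohorts divided into groups, such as children with a monogenic form of autism
(SHANK3 haploinsufficiency), idiopathic autism, and typical development. The
package also covers the accompanying non-network statistics: ANCOVA on global
surface measures and rank correlations between morphological features and
clinical scores.

All image-domain processing (segmentation, surface estimation, smoothing,
vertex-wise maps) is out of scope: the package consumes region-level and
global-level metric tables only.

## The pipeline

1. **Residualization.** For each region, CT is regressed by ordinary least
   squares on an intercept plus nuisance covariates — by default age, sex, and
   the subject's overall mean CT (the unweighted mean over all regions). The
   residuals feed every later stage. The regression is fit **pooled** across
   all subjects by default: group-wise fits with a dozen subjects and three
   covariates are unstable, so per-group fitting is available
   (`scope = "per_group"`) but not the default.

2. **Covariance.** Pearson correlation of residual CT between every region
   pair, within each group, gives one N x N structural covariance matrix per
   group.

3. **Sparsification.** Each matrix is binarized by keeping the top
   `round(s * N(N-1)/2)` region pairs at edge density `s = 0.15`. Ranking is
   by **signed** correlation by default — the dominant convention in CT
   covariance work; ranking by absolute value is available
   (`edge_rule = "absolute"`). Exact ties at the cutoff are broken by
   lexicographic region index, so results are bit-reproducible.

4. **Topology.** Each binary network is characterized by
   * global efficiency `GE = 1/(N(N-1)) * sum_{i != j} 1/L_ij`, with `L_ij`
     the unweighted shortest-path length and disconnected pairs contributing
     0 — the property that lets efficiency handle disconnected graphs;
   * local efficiency `LE = mean_i GE(G_i)`, where `G_i` is the subgraph
     induced on node i's neighbours (the node itself excluded; nodes with
     fewer than two neighbours contribute 0);
   * normalized ratios `nGE = GE/GE(random)` and `nLE = LE/LE(random)`
     against the mean of `n_random = 100` degree-preserving rewired null
     networks (double-edge swaps, 10 x edge-count successful swaps each,
     proposals creating self-loops or multi-edges rejected with an attempt
     cap of 100 x the swap budget);
   * nodal degree (row sums), for hub analysis.
   A network is flagged small-world when `nLE > 1` and `|nGE - 1| <= tau`.
   The comparability criterion "`nGE` approximately 1" carries no published
   tolerance; `tau = 0.1` is this package's documented choice, configurable.

5. **Permutation inference.** Between-group differences in GE/LE (and the
   normalized versions) are tested by randomly reallocating subjects'
   residual CT vectors between the two groups (sizes preserved), rebuilding
   both networks at the same sparsity, and recomputing the difference,
   `K = 1000` times. The 95th percentile of the null is the critical value of
   a one-tailed test at type-I error 0.05; an add-one permutation p-value
   `(1 + #{null >= observed})/(K + 1)` is reported alongside, so p is never
   exactly zero. Residuals are computed once on the real data and then
   permuted; re-residualizing within each relabeled split is not performed
   (the reallocated unit is the subject's prepared regional CT vector).
   The tail must be declared per hypothesis; with `tail = "auto"` the
   direction of the observed difference is used and the result flagged
   post-hoc-directional.

6. **Nodal comparison.** One relabeling per replicate drives all regions, so
   regional p-values share a dependence-preserving null stream. Nodal
   p-values are two-sided (regional increases and decreases are both
   reported in this literature, and no per-region a-priori direction is
   defensible); Benjamini-Hochberg correction runs across the full atlas
   (m = 360 by default), significance at q < 0.05.

7. **Morphometry statistics.** ANCOVA (`metric ~ group + age + sex + tiv`)
   with the omnibus partial F for the group factor, then pairwise post-hoc
   t-tests on covariate-adjusted values. Welch variances are the default
   (the pooled-variance convention is available via `var_equal = TRUE`); the
   developmental quotient can be added as a covariate by configuration but is
   not a default. Spearman rank correlations (midrank ties) relate
   morphological features to clinical scores, BH-corrected across all tested
   feature x scale pairs; correlations with fewer than 5 complete pairs are
   excluded from the FDR family.

## The synthetic cohort generator

No raw morphometry data ship with the package, so validation runs on
synthetic cohorts with *planted, recoverable* structure. The generator's only
distributional commitment matches the pipeline's only assumption: pairwise
linear correlation.

Per group, a ground-truth graph `A` is drawn from a chosen family — ring
lattice (regular), Watts-Strogatz-style rewired lattice (small-world),
Erdos-Renyi, or a custom adjacency for planted-contrast experiments — and the
sampling covariance is

```
Sigma = delta * I + rho * A,   delta = rho * max_degree(A) + noise_sd^2
```

which is strictly diagonally dominant, hence positive definite by Gershgorin,
with no eigenvalue-repair heuristics. Planted edges carry correlation
`rho / delta`; non-edges carry zero. The construction caps edge correlation
at `1/max_degree`, so dense planted graphs necessarily carry weak edges —
a trade of effect size for a guaranteed-valid covariance that tests must
respect (recovery experiments therefore use sparse planted graphs and large
n).

Subject CT vectors are multivariate normal draws (via the Cholesky factor)
shifted by baseline plus linear covariate effects. Defaults, chosen once as
realistic for a preschool cohort and documented here:

* group sizes 12/24/25 with a regular (lattice) topology for the first group
  and small-world topologies for the others, mirroring the contrast the
  pipeline is meant to detect;
* planted mean degree 6, `rho = 0.01`, `noise_sd = 0.15` mm, so regional CT
  deviations have SD near 0.29 mm around a 2.8 mm baseline and planted edges
  carry correlation ~0.12;
* age uniform on 2-8 years; per-group male fractions 6/12, 20/24, 19/25;
  TIV ~ N(1.35e6, 1.2e5) mm^3; covariate effects 0.02 mm/year, 0.03 mm male
  offset, 1e-7 mm per mm^3 of TIV;
* global surface measures (mean CT, fractal dimension, sulcal depth,
  gyrification) drawn at preschool-typical means and spreads;
* clinical scores are monotone sigmoidal transforms of a latent variable
  correlated with one designated region's CT at Pearson
  `r = 2*sin(pi*0.597/6) ~ 0.615`, which under the Gaussian rank formula
  makes the *population Spearman correlation exactly 0.597* — so the
  rank-correlation stage has a known recoverable target.

What the generator does **not** emulate: spatial autocorrelation along the
cortical sheet, hemispheric symmetry of covariance, non-Gaussian or heavy-
tailed thickness distributions, site/scanner effects, and any dependence of
covariance topology on the covariates. Tests passing on these cohorts
demonstrate that the estimators and tests are correct and calibrated under
the model's assumptions — not that any particular real-data finding would
replicate.

## Numerical choices

* Shortest paths use breadth-first search expressed as iterated boolean
  adjacency products (fast under BLAS and exact for unweighted graphs); an
  independently coded Floyd-Warshall oracle in the test suite confirms GE/LE
  to 1e-12 on hundreds of random graphs.
* Sparsification retains `round(s * N(N-1)/2)` edges — at N = 360 and s =
  0.15, exactly 9,693 — and is monotone: edge sets are nested across
  densities.
* Degenerate inputs have defined behaviour: constant regions get zero
  correlations with a warning (configurable to fail); graphs with fewer than
  two edges are returned unchanged by the rewirer with a warning; null
  ensembles with zero mean efficiency yield `NA` ratios, never infinities;
  rank-deficient designs drop the offending covariate with a warning.
* All randomness flows through explicit seeds; a master seed spawns per-stage
  substreams, and library calls restore the caller's RNG state.

## Validation scale

The test suite validates calibration at deliberately reduced problem sizes
chosen to keep the full suite fast while leaving Monte-Carlo error small
relative to the tolerances: type-I error of the permutation test on 500
simulated null cohorts (60 regions, groups of 12 and 24, K = 200, binomial
3-SE acceptance band around 0.05); planted-edge recovery at n = 500 subjects
and 36 regions (precision and recall >= 0.8 at the planted density); and
nodal-degree power on 100 planted-contrast datasets (two 10-cliques, n =
2000 per group, K = 199, mean per-dataset power > 0.8 at q < 0.05). Full-size
(360-region, K = 1000) runs use identical code paths; only N, K, and ensemble
sizes change.

## Known limitations

* Binary undirected networks only: no weighted, partial-correlation, or
  regularized-precision variants.
* Efficiency-family metrics only (GE, LE, normalized versions, degree); no
  betweenness, modularity, or rich-club statistics.
* The permutation test assumes exchangeability of subjects between the two
  groups after residualization; strong group differences in covariate
  distributions are handled only through the linear model.
* Group-level covariance needs adequate subjects per group; correlations from
  n = 12 are noisy, which is precisely why inference is permutation-based
  rather than parametric.

## A worked example

```{r example, eval = FALSE}
sim <- generate_cohort(scn_sim_config(n_regions = 60, seed = 7))
fit <- scn_fit(sim$cohort, sparsity = 0.15, n_random = 20, seed = 1)
summary(fit)

pt <- permute_metric(fit$residuals, c("SHANK3", "TD"), metric = "ge",
                     K = 200, sparsity = 0.15, tail = "less", seed = 2)
pt

nd <- permute_nodal_degree(fit$residuals, c("ASD", "TD"), K = 200,
                           sparsity = 0.15, seed = 3)
nd

ancova_global(sim$cohort, "mean_ct")
```

The same stages run end to end, with a manifest and report, via
`run_pipeline(scn_run_config(...), out_dir)` or the thin command-line wrapper
in `inst/cli/scnet-pipeline.R`.
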