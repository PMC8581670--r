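test_that("permutation test reports a coherent result object", {
  sim <- small_cohort(sizes = c(A = 10, B = 12), n_regions = 16, seed = 23)
  res <- residualize(sim$cohort)
  pt <- permute_metric(res, c("A", "B"), metric = "ge", K = 99,
                       sparsity = 0.2, tail = "greater", seed = 5)
  expect_s3_class(pt, "scn_permtest")
  expect_length(pt$null, 99)
  # add-one estimator recomputed from the returned pieces
  expect_equal(pt$p, (1 + sum(pt$null >= pt$observed)) / 100)
  expect_true(pt$p > 0 && pt$p <= 1)
  # critical value is the null's 95th percentile; significance follows it
  expect_equal(pt$critical, unname(stats::quantile(pt$null, 0.95)))
  expect_identical(pt$significant, pt$observed > pt$critical)

  # lower tail mirrors everything
  pl <- permute_metric(res, c("A", "B"), metric = "ge", K = 99,
                       sparsity = 0.2, tail = "less", seed = 5)
  expect_equal(pl$critical, unname(stats::quantile(pl$null, 0.05)))
  expect_equal(pl$p, (1 + sum(pl$null <= pl$observed)) / 100)

  # same seed, same inputs: identical null vector
  pt2 <- permute_metric(res, c("A", "B"), metric = "ge", K = 99,
                        sparsity = 0.2, tail = "greater", seed = 5)
  expect_identical(pt2$null, pt$null)
  expect_identical(pt2$observed, pt$observed)
})

test_that("degenerate requests are rejected or warned about", {
  sim <- small_cohort(sizes = c(A = 8, B = 8), n_regions = 10, seed = 24)
  res <- residualize(sim$cohort)
  expect_error(permute_metric(res, c("A", "A"), K = 20, seed = 1), "distinct")
  expect_error(permute_metric(res, c("A", "Z"), K = 20, seed = 1), "not present")
  expect_warning(permute_metric(res, c("A", "B"), K = 10, sparsity = 0.2,
                                seed = 1),
                 "cannot resolve")
})

test_that("auto tail follows the observed direction and is flagged post hoc", {
  sim <- small_cohort(sizes = c(A = 10, B = 10), n_regions = 14, seed = 25)
  res <- residualize(sim$cohort)
  pt <- permute_metric(res, c("A", "B"), metric = "ge", K = 49,
                       sparsity = 0.25, tail = "auto", seed = 2)
  expect_true(pt$post_hoc_directional)
  expect_identical(pt$tail, if (pt$observed >= 0) "greater" else "less")
})

test_that("under exchangeable groups the observed rank is uniform in its null", {
  # identical planted covariance in both groups: the observed difference is
  # one more draw from the null; its rank should be uniform
  A0 <- make_reference_graph("lattice", 16, k = 4)
  ranks <- vapply(1:60, function(i) {
    cfg <- scn_sim_config(group_sizes = c(A = 8, B = 8), n_regions = 16,
                          topology = list(A = A0, B = A0), seed = 1000 + i)
    sim <- generate_cohort(cfg)
    res <- residualize(sim$cohort)
    pt <- permute_metric(res, c("A", "B"), metric = "ge", K = 39,
                         sparsity = 0.2, tail = "greater", seed = 2000 + i)
    (sum(pt$null < pt$observed) + 0.5 * sum(pt$null == pt$observed)) / 39
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ranks, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("nodal-degree comparison adjusts across the full atlas", {
  sim <- small_cohort(sizes = c(A = 10, B = 10), n_regions = 20, seed = 26)
  res <- residualize(sim$cohort)
  nd <- permute_nodal_degree(res, c("A", "B"), K = 49, sparsity = 0.2,
                             seed = 3)
  expect_s3_class(nd, "scn_nodal_test")
  expect_equal(attr(nd, "m"), 20L)
  expect_equal(nrow(nd), 20L)
  expect_true(all(nd$q >= nd$p - 1e-12))
  # q is non-decreasing in p rank
  o <- order(nd$p)
  expect_true(all(diff(nd$q[o]) >= -1e-12))
  # observed differences sum to zero: both networks have the same edge count
  expect_equal(sum(nd$observed), 0)
})

test_that("BH adjustment is invariant to region ordering", {
  sim <- small_cohort(sizes = c(A = 10, B = 10), n_regions = 18, seed = 27)
  res <- residualize(sim$cohort)
  nd1 <- permute_nodal_degree(res, c("A", "B"), K = 29, sparsity = 0.2,
                              seed = 4)
  perm <- sample(18)
  res2 <- res
  res2$residuals <- res$residuals[, perm]
  nd2 <- permute_nodal_degree(res2, c("A", "B"), K = 29, sparsity = 0.2,
                              seed = 4)
  expect_equal(nd2$q, nd1$q[perm], tolerance = 1e-12)
  expect_equal(nd2$observed, nd1$observed[perm])
})

test_that("null distributions can be plotted without error", {
  sim <- small_cohort(sizes = c(A = 8, B = 8), n_regions = 10, seed = 28)
  res <- residualize(sim$cohort)
  pt <- permute_metric(res, c("A", "B"), metric = "ge", K = 19,
                       sparsity = 0.25, seed = 1)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(pt))
})
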