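make_manual_cohort <- function(n = 30, n_regions = 8, seed = 1,
                               ct_fn = NULL) {
  set.seed(seed)
  subjects <- data.frame(
    subject_id = sprintf("M%03d", 1:n),
    group = rep(c("A", "B"), length.out = n),
    age = runif(n, 2, 8),
    sex = sample(c("M", "F"), n, replace = TRUE),
    tiv = rnorm(n, 1.35e6, 1e5),
    stringsAsFactors = FALSE)
  ct <- if (is.null(ct_fn)) {
    2.8 + matrix(rnorm(n * n_regions, sd = 0.2), n, n_regions)
  } else ct_fn(subjects, n_regions)
  scn_cohort(subjects, ct)
}

test_that("an exactly linear age effect leaves zero residuals", {
  co <- make_manual_cohort(ct_fn = function(s, p)
    outer(0.1 * s$age + 2, rep(1, p)))
  res <- residualize(co, covariates = "age")
  expect_lt(max(abs(res$residuals)), 1e-10)
})

test_that("residuals are orthogonal to every fitted covariate", {
  sim <- small_cohort(sizes = c(A = 20, B = 20), seed = 5)
  res <- residualize(sim$cohort)
  X <- cbind(age = sim$cohort$subjects$age,
             sex = as.numeric(sim$cohort$subjects$sex == "M"),
             mean_ct = rowMeans(sim$cohort$ct))
  dots <- crossprod(scale(X, scale = FALSE), res$residuals)
  scale_ref <- max(abs(X)) * max(abs(res$residuals)) * nrow(X)
  expect_lt(max(abs(dots)), 1e-8 * scale_ref)
  expect_lt(max(abs(colMeans(res$residuals))), 1e-10 * max(abs(sim$cohort$ct)))
})

test_that("zero-effect covariates leave residuals close to centered CT", {
  cfg <- scn_sim_config(group_sizes = c(G = 500), n_regions = 12,
                        topology = lattice_topology("G", k = 2),
                        covariate_betas = c(age = 0, sex = 0, tiv = 0),
                        seed = 6)
  sim <- generate_cohort(cfg)
  res <- residualize(sim$cohort, covariates = c("age", "sex"))
  centered <- scale(sim$cohort$ct, scale = FALSE)
  cors <- vapply(seq_len(ncol(centered)), function(j)
    stats::cor(res$residuals[, j], centered[, j]), numeric(1))
  expect_true(all(cors > 0.99))
})

test_that("rank-deficient designs drop the offending covariate with a warning", {
  co <- make_manual_cohort()
  co$subjects$sex <- rep("M", nrow(co$ct))  # sex indicator constant
  expect_error(residualize(co, covariates = c("age", "sex")), "constant")
  # per-group: one group single-sex triggers the in-fit drop
  co2 <- make_manual_cohort(n = 40)
  co2$subjects$sex[co2$subjects$group == "A"] <- "M"
  expect_warning(res <- residualize(co2, covariates = c("age", "sex"),
                                    scope = "per_group"),
                 "rank-deficient")
  expect_true(all(is.finite(res$residuals)))
})

test_that("adding a covariate never increases a region's residual sum of squares", {
  sim <- small_cohort(sizes = c(A = 15, B = 15), seed = 9)
  r1 <- residualize(sim$cohort, covariates = "age")
  r2 <- residualize(sim$cohort, covariates = c("age", "sex"))
  rss1 <- colSums(r1$residuals^2)
  rss2 <- colSums(r2$residuals^2)
  expect_true(all(rss2 <= rss1 + 1e-10))
})

test_that("row order has no hidden effect on residuals", {
  sim <- small_cohort(sizes = c(A = 12, B = 12), seed = 10)
  res <- residualize(sim$cohort)
  perm <- sample(nrow(sim$cohort$ct))
  co2 <- scn_cohort(sim$cohort$subjects[perm, ], sim$cohort$ct[perm, ],
                    sim$cohort$atlas)
  res2 <- residualize(co2)
  expect_equal(res2$residuals, res$residuals[perm, ], tolerance = 1e-12)
})

test_that("per-group scope requires enough subjects and records coefficients", {
  sim <- small_cohort(sizes = c(A = 12, B = 12), seed = 13)
  res <- residualize(sim$cohort, scope = "per_group")
  expect_setequal(names(res$coefficients), c("A", "B"))
  expect_equal(dim(res$coefficients$A), c(4L, 20L))  # intercept + 3 covars

  tiny <- small_cohort(sizes = c(A = 4, B = 12), n_regions = 10, seed = 14)
  expect_error(residualize(tiny$cohort, scope = "per_group"), "cannot support")
})

test_that("residuals serialize with a coefficient sidecar", {
  sim <- small_cohort(seed = 15)
  res <- residualize(sim$cohort)
  f <- file.path(withr::local_tempdir(), "resid.tsv")
  write_residuals(res, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(as.matrix(back[, -(1:2)]), res$residuals,
               ignore_attr = TRUE, tolerance = 1e-15)
  expect_true(file.exists(sub("\\.tsv$", "_coefficients.tsv", f)))
})
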