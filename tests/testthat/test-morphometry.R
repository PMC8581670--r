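make_groups_df <- function(n_per = 20, shift = c(A = 0, B = 0, C = 0),
                           seed = 1, beta_age = 0, beta_tiv = 0) {
  set.seed(seed)
  g <- rep(names(shift), each = n_per)
  n <- length(g)
  age <- runif(n, 2, 8)
  tiv <- rnorm(n, 1.35e6, 1e5)
  data.frame(
    subject_id = sprintf("P%03d", 1:n), group = g,
    age = age, sex = sample(c("M", "F"), n, replace = TRUE), tiv = tiv,
    mean_ct = 2.8 + shift[g] + beta_age * age +
      beta_tiv * (tiv - 1.35e6) + rnorm(n, sd = 0.3),
    stringsAsFactors = FALSE)
}

test_that("with no covariates the omnibus test is exactly one-way ANOVA", {
  df <- make_groups_df(shift = c(A = 0, B = 0.2, C = -0.1), seed = 2)
  a <- ancova_global(df, "mean_ct", covariates = character(0))
  oracle <- stats::anova(stats::lm(mean_ct ~ group, data = df))
  expect_equal(a$F, oracle$`F value`[1], tolerance = 1e-10)
  expect_equal(a$p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
  # constant covariates are dropped and reduce to the same ANOVA
  df$site <- 1
  expect_warning(a2 <- ancova_global(df, "mean_ct", covariates = "site"),
                 "constant")
  expect_equal(a2$F, oracle$`F value`[1], tolerance = 1e-10)
})

test_that("ANCOVA adjusts for real covariate effects", {
  # a strong age effect and no group effect: ANCOVA should not reject more
  # than chance, and the adjusted means should be closer than raw means
  df <- make_groups_df(shift = c(A = 0, B = 0, C = 0), seed = 3,
                       beta_age = 0.3)
  # make age imbalanced across groups so raw means differ
  df$age[df$group == "B"] <- df$age[df$group == "B"] + 3
  df$mean_ct <- 2.8 + 0.3 * df$age + rnorm(nrow(df), sd = 0.1)
  a <- ancova_global(df, "mean_ct", covariates = c("age"))
  raw_spread <- diff(range(a$means$raw))
  adj_spread <- diff(range(a$means$adjusted))
  expect_lt(adj_spread, raw_spread / 2)
})

test_that("omnibus p is invariant to affine rescaling of covariates", {
  df <- make_groups_df(shift = c(A = 0, B = 0.3, C = 0), seed = 4,
                       beta_age = 0.1, beta_tiv = 2e-7)
  a1 <- ancova_global(df, "mean_ct", covariates = c("age", "tiv"))
  df2 <- df
  df2$age <- 12 * df2$age + 100     # months, offset
  df2$tiv <- df2$tiv / 1000         # cm^3
  a2 <- ancova_global(df2, "mean_ct", covariates = c("age", "tiv"))
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  expect_equal(a1$p, a2$p, tolerance = 1e-10)
})

test_that("null omnibus rejection rate is close to alpha", {
  rej <- vapply(1:400, function(i) {
    df <- make_groups_df(n_per = 12, seed = 100 + i)
    ancova_global(df, "mean_ct", covariates = c("age", "sex"),
                  posthoc = "never")$p < 0.05
  }, logical(1))
  # binomial 3-SE band around 0.05 at 400 simulations
  expect_gt(mean(rej), 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("post-hoc t directions recover a planted group shift", {
  hits <- vapply(1:100, function(i) {
    df <- make_groups_df(n_per = 12, shift = c(SHANK3 = 0.3, ASD = 0, TD = 0),
                         seed = 200 + i)
    a <- ancova_global(df, "mean_ct", covariates = c("age", "sex"))
    ph <- a$posthoc
    row <- ph[ph$group_a == "ASD" & ph$group_b == "SHANK3", ]
    row$t < 0  # SHANK3 planted thicker than ASD
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("Spearman correlation is exact under monotone noiseless links", {
  x <- c(0.3, 1.2, 0.7, 2.5, 1.9, 0.1, 3.3)
  feats <- data.frame(subject_id = sprintf("s%d", 1:7), fd = x)
  clin <- data.frame(subject_id = sprintf("s%d", 1:7),
                     dq = exp(2 * x) / (1 + exp(2 * x)),   # strictly increasing
                     neg = -x^3)                           # strictly decreasing
  out <- spearman_clinical(feats, clin, fdr = TRUE)
  expect_equal(out$rho[out$scale == "dq"], 1)
  expect_equal(out$rho[out$scale == "neg"], -1)
  expect_true(all(out$q >= out$p - 1e-12))
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(6)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  base <- spearman_clinical(
    data.frame(subject_id = 1:40, f = x),
    data.frame(subject_id = 1:40, s = y))$rho
  warped <- spearman_clinical(
    data.frame(subject_id = 1:40, f = exp(x)),
    data.frame(subject_id = 1:40, s = atan(y)))$rho
  expect_equal(warped, base, tolerance = 1e-12)
})

test_that("insufficient pairs are excluded from the FDR family", {
  feats <- data.frame(subject_id = 1:10, f = rnorm(10))
  clin <- data.frame(subject_id = 1:10,
                     mostly_missing = c(rnorm(3), rep(NA, 7)),
                     complete = rnorm(10))
  out <- spearman_clinical(feats, clin, min_pairs = 5)
  expect_false(out$sufficient[out$scale == "mostly_missing"])
  expect_true(is.na(out$q[out$scale == "mostly_missing"]))
  expect_true(out$sufficient[out$scale == "complete"])
})

test_that("independent feature and score reject at about alpha uncorrected", {
  rej <- vapply(1:400, function(i) {
    set.seed(300 + i)
    out <- spearman_clinical(
      data.frame(subject_id = 1:31, f = rnorm(31)),
      data.frame(subject_id = 1:31, s = rnorm(31)), fdr = FALSE)
    out$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("the generator's clinical link is calibrated near rho 0.6", {
  rhos <- vapply(1:40, function(i) {
    cfg <- scn_sim_config(group_sizes = c(S = 12, A = 24), n_regions = 10,
                          topology = lattice_topology(c("S", "A"), k = 2),
                          seed = 400 + i)
    sim <- generate_cohort(cfg)
    set.seed(500 + i)
    keep <- sample(nrow(sim$cohort$ct), 31)  # assessment subsample
    feats <- data.frame(subject_id = sim$cohort$subjects$subject_id[keep],
                        region_ct = sim$cohort$ct[keep, cfg$clinical_region])
    out <- spearman_clinical(feats,
                             sim$clinical[keep, c("subject_id",
                                                  "griffith_language")])
    out$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.597), 0.1)
})
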