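test_that("planted covariance follows the diagonal-dominance construction", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(build_planted_covariance(A, rho = 0.5, noise_sd = 1),
               matrix(c(1.5, 0.5, 0.5, 1.5), 2, 2))
  expect_equal(build_planted_covariance(matrix(0, 3, 3), 0.5, 1), diag(3))

  # positive definiteness holds for arbitrary planted graphs
  set.seed(21)
  for (i in 1:25) {
    A <- random_graph(sample(4:15, 1), runif(1, 0.1, 0.9))
    S <- build_planted_covariance(A, rho = runif(1, 0.1, 3),
                                  noise_sd = runif(1, 0.05, 2))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }

  bad <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(build_planted_covariance(bad, 0.5, 1), "symmetric")
  hollowless <- matrix(c(1, 1, 1, 0), 2, 2)
  expect_error(build_planted_covariance(hollowless, 0.5, 1), "hollow")
})

test_that("reference graph families have the promised structure", {
  ring <- make_reference_graph("lattice", 6, k = 2)
  expect_equal(rowSums(ring), rep(2, 6))
  expect_equal(sum(ring) / 2, 6)
  # a 6-cycle: neighbours at ring distance 1
  expect_equal(ring[1, ], c(0, 1, 0, 0, 0, 1))

  # no rewiring reproduces the lattice exactly
  expect_equal(make_reference_graph("small_world", 20, k = 4, beta = 0),
               make_reference_graph("lattice", 20, k = 4))

  # rewiring conserves the edge count
  sw <- make_reference_graph("small_world", 100, k = 4, beta = 0.1, seed = 5)
  expect_equal(sum(sw) / 2, 200)
  expect_equal(diag(sw), rep(0, 100))
  expect_equal(sw, t(sw))

  er <- make_reference_graph("erdos_renyi", 50, p = 0.2, seed = 5)
  expect_equal(er, t(er))
  expect_true(sum(er) / 2 > 0)

  expect_error(make_reference_graph("scale_free", 10), "arg")
  expect_error(make_reference_graph("lattice", 10, k = 3), "even")
})

test_that("cohort generation is a pure function of config and seed", {
  cfg <- scn_sim_config(group_sizes = c(A = 5, B = 6), n_regions = 10,
                        topology = lattice_topology(c("A", "B"), k = 2),
                        seed = 7)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$cohort$ct, s2$cohort$ct)
  expect_identical(s1$cohort$subjects, s2$cohort$subjects)
  expect_identical(s1$clinical, s2$clinical)
  s3 <- generate_cohort(scn_sim_config(group_sizes = c(A = 5, B = 6),
                                       n_regions = 10,
                                       topology = lattice_topology(c("A", "B"), k = 2),
                                       seed = 8))
  expect_false(identical(s1$cohort$ct, s3$cohort$ct))
})

test_that("default group structure matches the study cohort", {
  cfg <- scn_sim_config(n_regions = 60)
  sim <- generate_cohort(cfg)
  expect_equal(nrow(sim$cohort$ct), 61)  # 12 + 24 + 25
  expect_equal(as.integer(table(sim$cohort$subjects$group)[c("SHANK3", "ASD", "TD")]),
               c(12L, 24L, 25L))
  expect_true(all(is.na(sim$clinical$ados_severity[sim$cohort$subjects$group == "TD"])))
  expect_true(all(sim$cohort$subjects$age >= 2 & sim$cohort$subjects$age <= 8))
  expect_error(scn_sim_config(group_sizes = c(A = 2, B = 10)), ">= 3")
})

test_that("planted edges carry higher sample correlation than non-edges", {
  cfg <- scn_sim_config(
    group_sizes = c(G1 = 500, G2 = 500), n_regions = 36,
    topology = lattice_topology(c("G1", "G2")),
    rho = 1, noise_sd = 0.5,
    covariate_betas = c(age = 0, sex = 0, tiv = 0), seed = 31)
  sim <- generate_cohort(cfg)
  for (g in c("G1", "G2")) {
    rows <- sim$cohort$subjects$group == g
    R <- stats::cor(sim$cohort$ct[rows, ])
    A <- sim$truth$adjacency[[g]]
    up <- upper.tri(A)
    expect_gt(mean(R[up & A == 1]), mean(R[up & A == 0]))
  }
})

test_that("ground truth serializes to JSON plus edge list", {
  sim <- small_cohort(seed = 17)
  d <- withr::local_tempdir()
  write_ground_truth(sim$truth, d, sim$cohort$atlas)
  j <- jsonlite::read_json(file.path(d, "ground_truth.json"))
  expect_equal(unlist(j$n_edges), c(A = 40, B = 40))  # 20 nodes * k4 / 2
  edges <- utils::read.delim(file.path(d, "ground_truth_edges.tsv"))
  expect_equal(nrow(edges), 80)
  expect_true(all(edges$label_i %in% sim$cohort$atlas$label))
})
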