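#' Reference graph generator for planted covariance topologies
#'
#' Produces the adjacency matrix of a ground-truth graph family used to plant
#' covariance structure in synthetic cohorts: a ring lattice (`"lattice"`,
#' every node tied to its `k` nearest ring neighbours), a Watts-Strogatz style
#' rewired lattice (`"small_world"`, each lattice edge rewired with
#' probability `beta`, edge count conserved), or an Erdos-Renyi random graph
#' (`"erdos_renyi"`, each pair an edge with probability `p`).
#'
#' @param family `"lattice"`, `"small_world"`, or `"erdos_renyi"`.
#' @param n Number of nodes (>= 4).
#' @param k Even number of ring neighbours per node (lattice / small_world).
#' @param beta Rewiring probability in `[0, 1]` (small_world).
#' @param p Edge probability (erdos_renyi).
#' @param seed Optional seed for the stochastic families.
#' @return Symmetric hollow 0/1 matrix.
#' @examples
#' A <- make_reference_graph("lattice", n = 6, k = 2)
#' rowSums(A)  # every degree 2
#' @export
make_reference_graph <- function(family, n, k = 2L, beta = 0.1, p = 0.05,
                                 seed = NULL) {
  family <- match.arg(family, c("lattice", "small_world", "erdos_renyi"))
  n <- as.integer(n)
  if (n < 4L) stop("n must be >= 4", call. = FALSE)
  ring <- function() {
    k <- as.integer(k)
    if (k %% 2L != 0L || k < 2L || k >= n)
      stop("lattice k must be even, >= 2 and < n", call. = FALSE)
    A <- matrix(0, n, n)
    for (d in seq_len(k %/% 2L)) {
      i <- seq_len(n)
      j <- ((i - 1L + d) %% n) + 1L
      A[cbind(i, j)] <- 1
      A[cbind(j, i)] <- 1
    }
    A
  }
  A <- switch(family,
    lattice = ring(),
    small_world = with_seed(seed, {
      A <- ring()
      edges <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
      for (e in seq_len(nrow(edges))) {
        if (stats::runif(1) >= beta) next
        i <- edges[e, 1]; j <- edges[e, 2]
        # rewire the far endpoint to a uniform new target, keeping the graph
        # simple; skip if the node is saturated
        cand <- which(A[i, ] == 0)
        cand <- setdiff(cand, i)
        if (!length(cand)) next
        jnew <- if (length(cand) == 1L) cand else sample(cand, 1L)
        A[i, j] <- A[j, i] <- 0
        A[i, jnew] <- A[jnew, i] <- 1
      }
      A
    }),
    erdos_renyi = with_seed(seed, {
      if (p <= 0 || p >= 1) stop("p must be in (0,1)", call. = FALSE)
      A <- matrix(0, n, n)
      up <- upper_pairs(n)
      hit <- stats::runif(nrow(up)) < p
      A[up[hit, , drop = FALSE]] <- 1
      A[up[hit, 2:1, drop = FALSE]] <- 1
      A
    })
  )
  dimnames(A) <- NULL
  A
}

#' Planted covariance from a ground-truth adjacency
#'
#' Returns `Sigma = delta * I + rho * A` with
#' `delta = rho * max(degree) + noise_sd^2`. The diagonal loading makes the
#' matrix strictly diagonally dominant, hence symmetric positive definite by
#' the Gershgorin circle theorem, with no eigenvalue repair needed. Planted
#' edges then carry pairwise correlation `rho / delta`; non-edges carry zero.
#'
#' @param adjacency Symmetric hollow 0/1 matrix.
#' @param rho Positive covariance weight per planted edge.
#' @param noise_sd Per-region independent noise SD (mm).
#' @return Symmetric positive-definite covariance matrix.
#' @examples
#' A <- matrix(c(0, 1, 1, 0), 2, 2)
#' build_planted_covariance(A, rho = 0.5, noise_sd = 1)
#' @export
build_planted_covariance <- function(adjacency, rho, noise_sd) {
  validate_adjacency(adjacency)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("rho must be a single positive number", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0)
    stop("noise_sd must be a single positive number", call. = FALSE)
  delta <- rho * max(rowSums(adjacency)) + noise_sd^2
  sigma <- rho * adjacency
  diag(sigma) <- delta
  sigma
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the pipeline is designed for:
#' three groups of 12/24/25 subjects (monogenic ASD, idiopathic ASD, typical
#' development), 360 cortical regions, a regular (lattice) planted topology
#' for the monogenic group versus small-world topologies for the other two,
#' linear age/sex/intracranial-volume effects on thickness, and clinical
#' scores monotonically linked to one designated region so the Spearman stage
#' has a known signal (population rank correlation ~0.597).
#'
#' @param group_sizes Named integer vector of subjects per group (all >= 3).
#' @param n_regions Even region count (default 360).
#' @param topology Named list (one entry per group) of either a list
#'   `list(family=, k=, beta=, p=)` accepted by [make_reference_graph()], or a
#'   custom adjacency matrix (for planted-contrast experiments).
#' @param rho Covariance weight per planted edge (> 0).
#' @param noise_sd Independent per-region noise SD, mm.
#' @param covariate_betas Named numeric: `age` (mm/year), `sex` (mm, male
#'   offset), `tiv` (mm per mm^3 about the TIV mean).
#' @param baseline_ct Baseline thickness, mm.
#' @param age_range Uniform age range, years.
#' @param sex_p_male Named per-group probability of male sex.
#' @param tiv_mean,tiv_sd TIV distribution, mm^3.
#' @param clinical_region 1-based index of the region driving clinical scores.
#' @param clinical_link Latent Pearson correlation between the designated
#'   region's thickness and clinical scores. The default `2*sin(pi*0.597/6)`
#'   makes the population Spearman correlation 0.597 under the Gaussian rank
#'   formula.
#' @param seed Integer seed; the whole generator is a pure function of the
#'   config including this seed.
#' @return A validated list of class `scn_sim_config`.
#' @export
scn_sim_config <- function(group_sizes = c(SHANK3 = 12L, ASD = 24L, TD = 25L),
                           n_regions = 360L,
                           topology = NULL,
                           rho = 0.01,
                           noise_sd = 0.15,
                           covariate_betas = c(age = 0.02, sex = 0.03,
                                               tiv = 1e-7),
                           baseline_ct = 2.8,
                           age_range = c(2, 8),
                           sex_p_male = c(SHANK3 = 6 / 12, ASD = 20 / 24,
                                          TD = 19 / 25),
                           tiv_mean = 1.35e6, tiv_sd = 1.2e5,
                           clinical_region = 1L,
                           clinical_link = 2 * sin(pi * 0.597 / 6),
                           seed = 1L) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == ""))
    stop("group_sizes must be named", call. = FALSE)
  if (any(group_sizes < 3L))
    stop("all group sizes must be >= 3", call. = FALSE)
  n_regions <- as.integer(n_regions)
  if (n_regions %% 2L != 0L) stop("n_regions must be even", call. = FALSE)
  if (is.null(topology)) {
    topology <- list()
    for (g in names(group_sizes))
      topology[[g]] <- if (g == names(group_sizes)[1])
        list(family = "lattice", k = 6L)
      else list(family = "small_world", k = 6L, beta = 0.1)
  }
  miss <- setdiff(names(group_sizes), names(topology))
  if (length(miss))
    stop("topology missing for group(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(names(group_sizes) %in% names(sex_p_male))) {
    sex_p_male <- stats::setNames(rep(0.5, length(group_sizes)),
                                  names(group_sizes))
  }
  cfg <- list(group_sizes = group_sizes, n_regions = n_regions,
              topology = topology, rho = rho, noise_sd = noise_sd,
              covariate_betas = covariate_betas, baseline_ct = baseline_ct,
              age_range = age_range, sex_p_male = sex_p_male,
              tiv_mean = tiv_mean, tiv_sd = tiv_sd,
              clinical_region = as.integer(clinical_region),
              clinical_link = clinical_link, seed = as.integer(seed))
  class(cfg) <- "scn_sim_config"
  cfg
}

group_adjacency <- function(cfg, g, seed) {
  spec <- cfg$topology[[g]]
  if (is.matrix(spec)) {
    validate_adjacency(spec)
    if (nrow(spec) != cfg$n_regions)
      stop("custom adjacency for group ", g, " has wrong size", call. = FALSE)
    return(spec)
  }
  make_reference_graph(spec$family, n = cfg$n_regions,
                       k = spec$k %||% 2L, beta = spec$beta %||% 0.1,
                       p = spec$p %||% 0.05, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic multi-group cohort
#'
#' Per group, regional thickness deviations are drawn from a multivariate
#' normal with the planted covariance of [build_planted_covariance()], then
#' shifted by baseline thickness and linear covariate effects (age, sex,
#' intracranial volume). Global surface metrics are simulated at the means and
#' spreads typical of preschool cohorts. Clinical scores (Griffith domains,
#' developmental quotient, ADOS-2 for the two ASD groups) are monotone
#' sigmoidal transforms of a latent variable correlated with the designated
#' region's thickness, so rank correlations carry a known signal.
#'
#' @param config An [scn_sim_config()].
#' @return List with elements `cohort` (an `scn_cohort`), `clinical` (data
#'   frame), and `truth` (per-group planted adjacency and covariance,
#'   covariate betas, clinical link, seed).
#' @examples
#' sim <- generate_cohort(scn_sim_config(
#'   group_sizes = c(A = 5, B = 5), n_regions = 12,
#'   topology = list(A = list(family = "lattice", k = 2),
#'                   B = list(family = "lattice", k = 2)), seed = 1))
#' sim$cohort
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scn_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    groups <- names(cfg$group_sizes)
    adj <- list(); cov <- list()
    subj <- list(); cts <- list()
    counter <- 0L
    for (g in groups) {
      n <- cfg$group_sizes[[g]]
      adj[[g]] <- group_adjacency(cfg, g, seed = NULL)
      cov[[g]] <- build_planted_covariance(adj[[g]], cfg$rho, cfg$noise_sd)
      dev <- rmvn_chol(n, cov[[g]])
      age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
      sex <- ifelse(stats::rbinom(n, 1, cfg$sex_p_male[[g]]) == 1, "M", "F")
      tiv <- stats::rnorm(n, cfg$tiv_mean, cfg$tiv_sd)
      b <- cfg$covariate_betas
      shift <- cfg$baseline_ct + b[["age"]] * age +
        b[["sex"]] * (sex == "M") + b[["tiv"]] * (tiv - cfg$tiv_mean)
      ct <- dev + shift  # recycles shift down columns
      ids <- sprintf("S%03d", counter + seq_len(n))
      counter <- counter + n
      subj[[g]] <- data.frame(
        subject_id = ids, group = g, age = age, sex = sex, tiv = tiv,
        stringsAsFactors = FALSE)
      cts[[g]] <- ct
    }
    subjects <- do.call(rbind, subj)
    ct <- do.call(rbind, cts)
    rownames(subjects) <- NULL

    # global surface metrics: preschool-typical means/SDs
    ntot <- nrow(subjects)
    subjects$mean_ct <- rowMeans(ct)
    subjects$fd <- stats::rnorm(ntot, 2.65, 0.35)
    subjects$sd <- stats::rnorm(ntot, 2.88, 0.80)
    subjects$gi <- stats::rnorm(ntot, 27.25, 0.47)

    # clinical latent: designated region standardized, mixed with independent
    # noise at the configured link correlation; monotone sigmoid onto score
    # scales preserves all rank correlations
    z <- as.numeric(scale(ct[, cfg$clinical_region]))
    r <- cfg$clinical_link
    latent <- function() r * z + sqrt(1 - r^2) * stats::rnorm(ntot)
    sig <- function(l, lo, hi) lo + (hi - lo) * stats::plogis(l)
    subjects$dq <- sig(latent(), 40, 110)

    clinical <- data.frame(
      subject_id = subjects$subject_id,
      griffith_gross_motor = sig(latent(), 20, 110),
      griffith_social = sig(latent(), 20, 110),
      griffith_language = sig(latent(), 20, 110),
      griffith_fine_motor = sig(latent(), 20, 110),
      griffith_performance = sig(latent(), 20, 110),
      ados_severity = pmin(10, pmax(1, round(stats::rnorm(ntot, 6.6, 1.4)))),
      ados_sa = pmax(0, round(stats::rnorm(ntot, 15.9, 4.0))),
      ados_rrb = pmax(0, round(stats::rnorm(ntot, 1.6, 1.3))),
      stringsAsFactors = FALSE)
    clinical$ados_total <- clinical$ados_sa + clinical$ados_rrb
    # ADOS is administered only in the clinical (first two) groups
    if (length(groups) >= 3L) {
      td <- subjects$group %in% groups[-(1:2)]
      clinical[td, grep("^ados_", names(clinical))] <- NA
    }

    # regional CT must stay positive for the cohort validator; with default
    # scales values are ~2.2-3.5 mm, clamp guards pathological configs only
    ct[ct <= 0] <- .Machine$double.eps

    truth <- list(adjacency = adj, covariance = cov,
                  covariate_betas = cfg$covariate_betas,
                  clinical_region = cfg$clinical_region,
                  clinical_link = cfg$clinical_link, seed = cfg$seed)
    list(cohort = scn_cohort(subjects, ct,
                             atlas = default_atlas(cfg$n_regions)),
         clinical = clinical, truth = truth)
  })
}

#' Write generator ground truth to disk
#'
#' Scalar parameters go to JSON; each group's planted adjacency goes to a TSV
#' edge list (`group`, `label_i`, `label_j`).
#'
#' @param truth `truth` element of [generate_cohort()] output.
#' @param dir Output directory (created if needed).
#' @param atlas Atlas providing region labels for the edge list.
#' @return The directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir, atlas) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- truth[c("covariate_betas", "clinical_region", "clinical_link",
                  "seed")]
  meta$groups <- names(truth$adjacency)
  meta$n_edges <- as.list(vapply(truth$adjacency, function(a) sum(a) / 2, 0.0))
  jsonlite::write_json(meta, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  rows <- lapply(names(truth$adjacency), function(g) {
    e <- which(upper.tri(truth$adjacency[[g]]) & truth$adjacency[[g]] == 1,
               arr.ind = TRUE)
    if (!nrow(e)) return(NULL)
    data.frame(group = g, label_i = atlas$label[e[, 1]],
               label_j = atlas$label[e[, 2]], stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  utils::write.table(edges, file.path(dir, "ground_truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
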