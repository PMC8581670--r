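#' Run configuration for the full analysis pipeline
#'
#' Defaults follow the study protocol the pipeline implements: 15% network
#' sparsity, 1,000 permutation replicates with 95th-percentile critical
#' values at type-I error 0.05, a 100-network rewired null ensemble, and a
#' 360-region atlas.
#'
#' @param simulate An [scn_sim_config()] to generate the cohort, or `NULL`
#'   when reading from files.
#' @param cohort_path,clinical_path Input tables when `simulate` is `NULL`.
#' @param covariates Residualization covariates.
#' @param scope Residualization scope.
#' @param sparsity Network edge density (default 0.15).
#' @param K Permutation replicates (default 1000).
#' @param n_random Rewired null networks per group (default 100).
#' @param alpha Significance level (default 0.05).
#' @param metrics Network metrics to test between groups.
#' @param tail Tail rule for [permute_metric()].
#' @param edge_rule Sparsification rule.
#' @param ancova_metrics Global morphometry outcomes for ANCOVA.
#' @param ancova_covariates ANCOVA nuisance covariates.
#' @param clinical_feature Column of the cohort table correlated against the
#'   clinical scores (default `"fd"`).
#' @param seed Master seed; per-stage substreams are derived from it.
#' @return List of class `scn_run_config`.
#' @export
scn_run_config <- function(simulate = scn_sim_config(),
                           cohort_path = NULL, clinical_path = NULL,
                           covariates = c("age", "sex", "mean_ct"),
                           scope = "pooled",
                           sparsity = 0.15, K = 1000L, n_random = 100L,
                           alpha = 0.05, metrics = c("ge", "le"),
                           tail = "auto", edge_rule = "signed",
                           ancova_metrics = c("mean_ct", "fd", "sd", "gi"),
                           ancova_covariates = c("age", "sex", "tiv"),
                           clinical_feature = "fd",
                           seed = 1L) {
  cfg <- list(simulate = simulate, cohort_path = cohort_path,
              clinical_path = clinical_path, covariates = covariates,
              scope = scope, sparsity = sparsity, K = as.integer(K),
              n_random = as.integer(n_random), alpha = alpha,
              metrics = metrics, tail = tail, edge_rule = edge_rule,
              ancova_metrics = ancova_metrics,
              ancova_covariates = ancova_covariates,
              clinical_feature = clinical_feature, seed = as.integer(seed))
  class(cfg) <- "scn_run_config"
  cfg
}

#' Reduced-scale run configuration
#'
#' A named small profile (60 regions, 200 permutations, 20 rewired nulls)
#' used for fast end-to-end runs and continuous testing.
#' @param seed Master seed.
#' @return An `scn_run_config`.
#' @export
scn_test_profile <- function(seed = 1L) {
  scn_run_config(
    simulate = scn_sim_config(n_regions = 60L, seed = seed),
    K = 200L, n_random = 20L, seed = seed)
}

#' Read a run configuration from YAML
#'
#' Scalar fields override the defaults of [scn_run_config()]; a `simulate`
#' block (if present) overrides [scn_sim_config()] defaults.
#' @param path YAML file.
#' @return An `scn_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulate)) {
    sim_args <- raw$simulate
    if (!is.null(sim_args$group_sizes))
      sim_args$group_sizes <- unlist(sim_args$group_sizes)
    sim <- do.call(scn_sim_config, sim_args)
  } else if (is.null(raw$cohort_path)) {
    sim <- scn_sim_config()
  }
  args <- raw[setdiff(names(raw), "simulate")]
  args$simulate <- sim
  do.call(scn_run_config, args)
}

#' Execute the full structural covariance analysis
#'
#' Stage order: obtain the cohort (simulate or read), residualize, build one
#' sparsified network per group, compute efficiency metrics with rewired-null
#' normalization, run between-group permutation tests (global metrics and
#' nodal degree with FDR), ANCOVA with post-hoc t-tests on the global
#' morphometry, and Spearman clinical correlations. All stage outputs, a JSON
#' manifest (config echo, seeds, input hashes) and a plain-text report are
#' written under `out_dir`. A single master seed spawns per-stage substreams,
#' so the run directory is reproducible.
#'
#' @param config An `scn_run_config`.
#' @param out_dir Output directory (created; contents overwritten).
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "scn_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  cat(sprintf("pipeline start (seed %d)\n", config$seed), file = logf)
  note <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE,
                            sep = "")
  stage_seeds <- spawn_seeds(config$seed, 4L)

  stage <- "input"
  result <- tryCatch({
    # --- cohort ---
    if (!is.null(config$simulate)) {
      sim <- generate_cohort(config$simulate)
      cohort <- sim$cohort
      clinical <- sim$clinical
      write_ground_truth(sim$truth, file.path(out_dir, "ground_truth"),
                         cohort$atlas)
      note("simulated cohort: %d subjects", nrow(cohort$ct))
    } else {
      if (is.null(config$cohort_path) || !file.exists(config$cohort_path))
        stop("cohort input file not found: ",
             config$cohort_path %||% "<missing>", call. = FALSE)
      cohort <- read_cohort(config$cohort_path,
                            atlas = default_atlas(360L))
      clinical <- if (!is.null(config$clinical_path))
        read_clinical(config$clinical_path, cohort) else NULL
      note("read cohort: %d subjects", nrow(cohort$ct))
    }
    write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
    if (!is.null(clinical))
      write_clinical(clinical, file.path(out_dir, "clinical.tsv"))

    # --- fit: residualize + networks + metrics ---
    stage <- "fit"
    fit <- scn_fit(cohort, covariates = config$covariates,
                   scope = config$scope, sparsity = config$sparsity,
                   edge_rule = config$edge_rule,
                   n_random = config$n_random, seed = stage_seeds[1])
    write_residuals(fit$residuals, file.path(out_dir, "residuals.tsv"))
    for (g in fit$groups) {
      utils::write.table(
        as.data.frame(apply(unclass(fit$covariance[[g]]), 2, format_full)),
        file.path(out_dir, sprintf("covariance_%s.tsv", g)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_network(fit$networks[[g]],
                    file.path(out_dir, sprintf("network_%s.tsv", g)),
                    cov = fit$covariance[[g]])
    }
    mt <- summary(fit)$table
    utils::write.table(mt, file.path(out_dir, "metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(mt, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    note("fit: %d group networks at sparsity %.3f", length(fit$groups),
         config$sparsity)

    # --- permutation inference ---
    stage <- "permutation"
    pair_list <- utils::combn(fit$groups, 2, simplify = FALSE)
    perm_seeds <- spawn_seeds(stage_seeds[2],
                              length(pair_list) * (length(config$metrics) + 1))
    si <- 0L
    perm_rows <- list(); nodal_rows <- list()
    perms <- list()
    for (pr in pair_list) {
      for (m in config$metrics) {
        si <- si + 1L
        pt <- permute_metric(fit$residuals, pr, metric = m, K = config$K,
                             sparsity = config$sparsity, tail = config$tail,
                             seed = perm_seeds[si],
                             edge_rule = config$edge_rule,
                             n_random = config$n_random,
                             alpha = config$alpha)
        perms[[paste(pr[1], pr[2], m, sep = "_")]] <- pt
        perm_rows[[length(perm_rows) + 1L]] <- data.frame(
          group_a = pr[1], group_b = pr[2], metric = m,
          observed = pt$observed, critical = pt$critical, p = pt$p,
          tail = pt$tail, significant = pt$significant,
          stringsAsFactors = FALSE)
      }
      si <- si + 1L
      nd <- permute_nodal_degree(fit$residuals, pr, K = config$K,
                                 sparsity = config$sparsity,
                                 seed = perm_seeds[si],
                                 edge_rule = config$edge_rule,
                                 alpha = config$alpha)
      ndf <- as.data.frame(nd)
      ndf$group_a <- pr[1]; ndf$group_b <- pr[2]
      nodal_rows[[length(nodal_rows) + 1L]] <- ndf
    }
    perm_tab <- do.call(rbind, perm_rows)
    nodal_tab <- do.call(rbind, nodal_rows)
    utils::write.table(perm_tab, file.path(out_dir, "permutation_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(nodal_tab, file.path(out_dir, "nodal_degree_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("permutation: %d global tests, %d nodal comparisons",
         nrow(perm_tab), length(nodal_rows))

    # --- morphometry statistics ---
    stage <- "morphometry"
    anc_rows <- list(); ancovas <- list()
    for (m in intersect(config$ancova_metrics, names(cohort$subjects))) {
      a <- ancova_global(cohort, m, covariates = config$ancova_covariates)
      ancovas[[m]] <- a
      ph <- a$posthoc
      anc_rows[[m]] <- data.frame(metric = m, F = a$F, p = a$p,
                                  stringsAsFactors = FALSE)
    }
    anc_tab <- do.call(rbind, anc_rows)
    utils::write.table(anc_tab, file.path(out_dir, "ancova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    corr <- NULL
    if (!is.null(clinical) &&
        config$clinical_feature %in% names(cohort$subjects)) {
      feats <- cohort$subjects[, c("subject_id", config$clinical_feature)]
      corr <- spearman_clinical(feats, clinical, fdr = TRUE)
      utils::write.table(as.data.frame(corr),
                         file.path(out_dir, "clinical_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # --- manifest + report ---
    stage <- "report"
    manifest <- list(
      package = "scnet",
      version = as.character(utils::packageVersion("scnet")),
      seed = config$seed, stage_seeds = stage_seeds,
      config = config[setdiff(names(config), "simulate")],
      simulate = if (!is.null(config$simulate))
        config$simulate[setdiff(names(config$simulate), "topology")],
      n_subjects = nrow(cohort$ct), n_regions = ncol(cohort$ct),
      n_edges_per_network = attr(fit$networks[[1]], "n_edges"),
      input_hashes = local({
        fl <- c("cohort.tsv", "residuals.tsv")
        stats::setNames(lapply(file.path(out_dir, fl), function(f)
          if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_), fl)
      }))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep_path <- file.path(out_dir, "report.txt")
    con <- file(rep_path, "w"); on.exit(close(con), add = TRUE)
    writeLines(c(
      "Structural covariance network analysis report",
      sprintf("Subjects: %d; regions: %d; sparsity: %.3f (%d edges per group network)",
              nrow(cohort$ct), ncol(cohort$ct), config$sparsity,
              attr(fit$networks[[1]], "n_edges")),
      "", "Group network metrics:",
      utils::capture.output(print.data.frame(mt, digits = 4,
                                             row.names = FALSE)),
      "", "Permutation tests (global metrics):",
      utils::capture.output(print.data.frame(perm_tab, digits = 4,
                                             row.names = FALSE)),
      "", sprintf("Nodal-degree comparisons significant at q < %.2f: %d",
                  config$alpha, sum(nodal_tab$significant)),
      "", "ANCOVA (global morphometry):",
      utils::capture.output(print.data.frame(anc_tab, digits = 4,
                                             row.names = FALSE)),
      if (!is.null(corr)) c("", "Clinical correlations:",
        utils::capture.output(print.data.frame(as.data.frame(corr),
                                               digits = 3,
                                               row.names = FALSE)))),
      con)
    note("done")
    list(cohort = cohort, fit = fit, permutation = perms,
         permutation_table = perm_tab, nodal = nodal_tab,
         ancova = ancovas, correlations = corr, out_dir = out_dir)
  }, error = function(e) {
    err <- list(stage = stage, error = conditionMessage(e))
    jsonlite::write_json(err, file.path(out_dir, "error.json"),
                         auto_unbox = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
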