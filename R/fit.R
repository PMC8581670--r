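#' Fit group structural covariance networks
#'
#' The central estimator of the package: residualizes regional cortical
#' thickness against nuisance covariates, builds one Pearson covariance matrix
#' per group, sparsifies and binarizes each at a common edge density, and
#' characterizes every group network by global/local efficiency, their
#' normalized versions against degree-preserving rewired null networks, nodal
#' degree, and a small-world flag.
#'
#' @param cohort An `scn_cohort`.
#' @param covariates Nuisance covariates removed before covariance estimation
#'   (default: age, sex, overall mean CT).
#' @param scope Residualization scope, `"pooled"` (default) or `"per_group"`.
#' @param sparsity Retained fraction of possible edges (default 0.15).
#' @param edge_rule `"signed"` (default) or `"absolute"` correlation ranking.
#' @param n_random Size of the rewired null ensemble per group (default 100).
#' @param tau Tolerance on `|nGE - 1|` in the small-world criterion.
#' @param seed Seed for the null ensembles.
#' @return Object of class `scn_fit`: list with `residuals`
#'   (`scn_residuals`), `covariance` (per-group `scn_covariance`), `networks`
#'   (per-group `scn_network`), `metrics` (per-group `scn_metrics`), `groups`,
#'   and the call parameters.
#' @examples
#' sim <- generate_cohort(scn_sim_config(
#'   group_sizes = c(A = 10, B = 10), n_regions = 20,
#'   topology = list(A = list(family = "lattice", k = 4),
#'                   B = list(family = "small_world", k = 4, beta = 0.2)),
#'   seed = 5))
#' fit <- scn_fit(sim$cohort, sparsity = 0.2, n_random = 5, seed = 1)
#' summary(fit)
#' @export
scn_fit <- function(cohort, covariates = c("age", "sex", "mean_ct"),
                    scope = "pooled", sparsity = 0.15,
                    edge_rule = "signed", n_random = 100L, tau = 0.1,
                    seed = NULL) {
  stopifnot(inherits(cohort, "scn_cohort"))
  res <- residualize(cohort, covariates = covariates, scope = scope)
  groups <- unique(cohort$subjects$group)
  seeds <- spawn_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1L),
                       length(groups))
  covm <- nets <- mets <- stats::setNames(vector("list", length(groups)),
                                          groups)
  for (i in seq_along(groups)) {
    g <- groups[i]
    covm[[g]] <- group_covariance(res, group = g)
    nets[[g]] <- sparsify_binarize(covm[[g]], sparsity = sparsity,
                                   edge_rule = edge_rule)
    mets[[g]] <- normalized_efficiencies(unclass_adj(nets[[g]]),
                                         n_random = n_random,
                                         seed = seeds[i], tau = tau)
  }
  structure(list(residuals = res, covariance = covm, networks = nets,
                 metrics = mets, groups = groups, sparsity = sparsity,
                 edge_rule = edge_rule, n_random = as.integer(n_random),
                 tau = tau, seed = seed, covariates = covariates,
                 n_subjects = table(cohort$subjects$group)),
            class = "scn_fit")
}

# strip S3 class/attrs so metric functions see a plain 0/1 matrix
unclass_adj <- function(net) {
  A <- unclass(net)
  attributes(A) <- list(dim = dim(A), dimnames = dimnames(A))
  A
}

#' @export
print.scn_fit <- function(x, ...) {
  cat("Structural covariance network fit\n")
  cat(sprintf("  %d group(s), %d regions, sparsity %.3f (%d edges/network), %s rule\n",
              length(x$groups), ncol(x$residuals$residuals), x$sparsity,
              attr(x$networks[[1]], "n_edges"), x$edge_rule))
  cat("  covariates removed:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.scn_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$groups, function(g) {
    m <- object$metrics[[g]]
    data.frame(group = g, n = as.integer(object$n_subjects[[g]]),
               ge = m$ge, le = m$le, nge = m$nge, nle = m$nle,
               small_world = m$small_world, stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, sparsity = object$sparsity,
                 n_random = object$n_random, tau = object$tau),
            class = "summary.scn_fit")
}

#' @export
print.summary.scn_fit <- function(x, ...) {
  cat(sprintf("Group network metrics at sparsity %.3f (null ensemble: %d rewired networks)\n",
              x$sparsity, x$n_random))
  print.data.frame(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.scn_fit <- function(object, ...) object$residuals$coefficients

#' @export
residuals.scn_fit <- function(object, ...) object$residuals$residuals

#' Parametric bootstrap from a fitted SCN model
#'
#' Draws new residual matrices from each group's estimated correlation
#' structure (multivariate normal with the group covariance of the fit),
#' returning one `scn_residuals` per simulation. Useful for bootstrap
#' stability checks of the network metrics.
#'
#' @param object An `scn_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` `scn_residuals` objects.
#' @export
simulate.scn_fit <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- spawn_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1L),
                       nsim)
  lapply(seq_len(nsim), function(s) {
    with_seed(seeds[s], {
      rows <- lapply(object$groups, function(g) {
        n <- as.integer(object$n_subjects[[g]])
        # ridge the estimated correlation matrix minimally so chol succeeds
        # when subjects < regions
        S <- unclass(object$covariance[[g]])
        S <- S + diag(1e-8 + max(0, -min(eigen(S, symmetric = TRUE,
                                               only.values = TRUE)$values)),
                      nrow(S))
        rmvn_chol(n, S)
      })
      M <- do.call(rbind, rows)
      colnames(M) <- colnames(object$residuals$residuals)
      structure(list(residuals = M, coefficients = list(),
                     covariates = object$covariates, scope = "simulated",
                     group = rep(object$groups,
                                 times = as.integer(object$n_subjects[object$groups])),
                     subjects = sprintf("B%04d", seq_len(nrow(M)))),
                class = "scn_residuals")
    })
  })
}

#' Plot method for fitted SCN models
#'
#' Bar panels of global/local efficiency and normalized efficiencies per
#' group, plus nodal-degree distributions.
#'
#' @param x An `scn_fit`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.scn_fit <- function(x, ...) {
  s <- summary(x)$table
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(s$ge, names.arg = s$group, main = "Global efficiency",
                    ylab = "GE", col = "steelblue", ...)
  graphics::barplot(s$le, names.arg = s$group, main = "Local efficiency",
                    ylab = "LE", col = "steelblue", ...)
  graphics::barplot(rbind(s$nge, s$nle), beside = TRUE, names.arg = s$group,
                    main = "Normalized efficiencies",
                    legend.text = c("nGE", "nLE"), col = c("grey60", "tomato"))
  graphics::abline(h = 1, lty = 2)
  degs <- lapply(x$groups, function(g) x$metrics[[g]]$degree)
  graphics::boxplot(degs, names = x$groups, main = "Nodal degree",
                    ylab = "degree")
  invisible(x)
}
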