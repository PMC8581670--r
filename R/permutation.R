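# Group-reallocation permutation inference for network metrics.

# Fast internal path shared by the permutation loops: correlation matrix of a
# subject subset, ranked upper-triangle, top-k edge pairs.
fast_cor <- function(M) {
  R <- suppressWarnings(stats::cor(M))
  R[!is.finite(R)] <- 0
  R
}

top_pairs <- function(R, pairs, n_keep, edge_rule) {
  r <- R[pairs]
  if (edge_rule == "absolute") r <- abs(r)
  ord <- order(-r, pairs[, 1], pairs[, 2])
  pairs[ord[seq_len(n_keep)], , drop = FALSE]
}

adjacency_from_pairs <- function(keep, n) {
  A <- matrix(0, n, n)
  A[keep] <- 1
  A[keep[, 2:1, drop = FALSE]] <- 1
  A
}

#' Permutation test of a between-group network-metric difference
#'
#' Computes the observed metric difference (group A minus group B) from the
#' groups' sparsified covariance networks, then builds a null distribution by
#' randomly reallocating subjects' residual CT vectors between the two groups
#' (sizes preserved), rebuilding both networks at the same sparsity, and
#' recomputing the difference, `K` times (default 1,000). The critical value
#' is the 95th percentile of the null for an upper-tailed test (5th for
#' lower-tailed) and significance follows that critical-value rule at type-I
#' error 0.05; an add-one permutation p-value `(1 + #{null >= obs}) / (K + 1)`
#' is reported alongside.
#'
#' @param residuals An `scn_residuals` (residuals are computed once on the
#'   real data and their rows permuted, matching reallocation of each
#'   subject's prepared regional CT vector).
#' @param groups Character vector of two distinct group labels, `c(A, B)`.
#' @param metric `"ge"`, `"le"`, `"nge"`, or `"nle"`.
#' @param K Number of permutation replicates (default 1000). `K < 19` cannot
#'   resolve p below 0.05 and triggers a warning.
#' @param sparsity Edge density used for every network, real and permuted.
#' @param tail `"greater"`, `"less"`, or `"auto"` (direction of the observed
#'   difference; flagged as post-hoc directional in the result).
#' @param seed Seed for the relabeling stream (and rewiring, for normalized
#'   metrics).
#' @param edge_rule Passed to the sparsification step.
#' @param n_random Rewired null networks per evaluation for `"nge"`/`"nle"`.
#' @param alpha Significance level of the critical-value rule.
#' @return Object of class `scn_permtest`.
#' @export
permute_metric <- function(residuals, groups, metric = c("ge", "le", "nge", "nle"),
                           K = 1000L, sparsity = 0.15,
                           tail = c("auto", "greater", "less"),
                           seed = NULL, edge_rule = c("signed", "absolute"),
                           n_random = 20L, alpha = 0.05) {
  stopifnot(inherits(residuals, "scn_residuals"))
  metric <- match.arg(metric)
  tail <- match.arg(tail)
  edge_rule <- match.arg(edge_rule)
  if (length(groups) != 2L || groups[1] == groups[2])
    stop("groups must name two distinct group labels", call. = FALSE)
  if (!all(groups %in% residuals$group))
    stop("group(s) not present in residuals", call. = FALSE)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K < 19L)
    warning("K < 19 cannot resolve p-values at alpha = 0.05", call. = FALSE)

  M <- residuals$residuals
  n_reg <- ncol(M)
  pairs <- upper_pairs(n_reg)
  n_keep <- round(sparsity * nrow(pairs))
  if (n_keep < 1L) stop("sparsity retains zero edges", call. = FALSE)

  rows_a <- which(residuals$group == groups[1])
  rows_b <- which(residuals$group == groups[2])
  pooled <- c(rows_a, rows_b)
  n_a <- length(rows_a)

  seeds <- spawn_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1L),
                       K + 1L)
  metric_fn <- function(A, s) {
    switch(metric,
      ge = global_efficiency(A),
      le = local_efficiency(A),
      nge = normalized_efficiencies(A, n_random = n_random, seed = s)$nge,
      nle = normalized_efficiencies(A, n_random = n_random, seed = s)$nle)
  }
  needs_null <- metric %in% c("nge", "nle")
  diff_fn <- function(ra, rb, s) {
    ss <- if (needs_null) spawn_seeds(s, 2L) else c(NA, NA)
    Aa <- adjacency_from_pairs(
      top_pairs(fast_cor(M[ra, , drop = FALSE]), pairs, n_keep, edge_rule),
      n_reg)
    Ab <- adjacency_from_pairs(
      top_pairs(fast_cor(M[rb, , drop = FALSE]), pairs, n_keep, edge_rule),
      n_reg)
    metric_fn(Aa, ss[1]) - metric_fn(Ab, ss[2])
  }

  observed <- diff_fn(rows_a, rows_b, seeds[1])
  post_hoc <- tail == "auto"
  if (post_hoc) tail <- if (observed >= 0) "greater" else "less"

  null <- numeric(K)
  for (k in seq_len(K)) {
    perm <- with_seed(seeds[k + 1L], sample(pooled))
    null[k] <- diff_fn(perm[seq_len(n_a)], perm[-seq_len(n_a)], seeds[k + 1L])
  }

  crit_prob <- if (tail == "greater") 1 - alpha else alpha
  critical <- unname(stats::quantile(null, crit_prob))
  p <- if (tail == "greater") (1 + sum(null >= observed)) / (K + 1)
       else (1 + sum(null <= observed)) / (K + 1)
  significant <- if (tail == "greater") observed > critical
                 else observed < critical

  structure(list(metric = metric, groups = groups, observed = observed,
                 null = null, K = as.integer(K), critical = critical,
                 crit_prob = crit_prob, p = p, significant = significant,
                 tail = tail, post_hoc_directional = post_hoc,
                 alpha = alpha, sparsity = sparsity, seed = seed),
            class = "scn_permtest")
}

#' @export
print.scn_permtest <- function(x, ...) {
  cat(sprintf("Permutation test: %s, %s - %s\n", toupper(x$metric),
              x$groups[1], x$groups[2]))
  cat(sprintf("  observed = %.5f, critical (%s%% of %d-replicate null) = %.5f\n",
              x$observed, format(100 * x$crit_prob), x$K, x$critical))
  cat(sprintf("  one-tailed (%s%s) p = %.4g, significant at alpha %.2f: %s\n",
              x$tail, if (x$post_hoc_directional) ", post-hoc direction" else "",
              x$p, x$alpha, x$significant))
  invisible(x)
}

#' @export
plot.scn_permtest <- function(x, ...) {
  graphics::hist(x$null, breaks = 30, col = "grey85", border = "white",
                 main = sprintf("%s: %s - %s", toupper(x$metric),
                                x$groups[1], x$groups[2]),
                 xlab = "null metric difference", ...)
  graphics::abline(v = x$observed, col = "firebrick", lwd = 2)
  graphics::abline(v = x$critical, col = "navy", lty = 2)
  graphics::legend("topright", legend = c("observed", "critical"),
                   col = c("firebrick", "navy"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Permutation comparison of nodal degree with FDR correction
#'
#' Per region, the observed degree difference (group A minus group B) between
#' the groups' sparsified networks is compared against a permutation null in
#' which one relabeling per replicate drives all regions simultaneously,
#' preserving cross-region dependence. Two-sided add-one p-values are adjusted
#' with Benjamini-Hochberg across the full atlas (m = number of regions).
#'
#' @inheritParams permute_metric
#' @return Object of class `scn_nodal_test`: data frame with columns `region`,
#'   `observed` (degree difference), `p`, `q`, `significant` (q < alpha);
#'   attributes `m`, `K`, `groups`, `sparsity`, `alpha`.
#' @export
permute_nodal_degree <- function(residuals, groups, K = 1000L,
                                 sparsity = 0.15, seed = NULL,
                                 edge_rule = c("signed", "absolute"),
                                 alpha = 0.05) {
  stopifnot(inherits(residuals, "scn_residuals"))
  edge_rule <- match.arg(edge_rule)
  if (length(groups) != 2L || groups[1] == groups[2])
    stop("groups must name two distinct group labels", call. = FALSE)
  if (!all(groups %in% residuals$group))
    stop("group(s) not present in residuals", call. = FALSE)
  if (K < 19L)
    warning("K < 19 cannot resolve p-values at alpha = 0.05", call. = FALSE)

  M <- residuals$residuals
  n_reg <- ncol(M)
  pairs <- upper_pairs(n_reg)
  n_keep <- round(sparsity * nrow(pairs))
  rows_a <- which(residuals$group == groups[1])
  rows_b <- which(residuals$group == groups[2])
  pooled <- c(rows_a, rows_b)
  n_a <- length(rows_a)

  deg_of <- function(rows) {
    keep <- top_pairs(fast_cor(M[rows, , drop = FALSE]), pairs, n_keep,
                      edge_rule)
    tabulate(c(keep[, 1], keep[, 2]), nbins = n_reg)
  }
  diff_of <- function(ra, rb) deg_of(ra) - deg_of(rb)

  observed <- diff_of(rows_a, rows_b)
  seeds <- spawn_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1L), K)
  exceed <- integer(n_reg)
  for (k in seq_len(K)) {
    perm <- with_seed(seeds[k], sample(pooled))
    nd <- diff_of(perm[seq_len(n_a)], perm[-seq_len(n_a)])
    exceed <- exceed + (abs(nd) >= abs(observed))
  }
  p <- (1 + exceed) / (K + 1)
  q <- bh_adjust(p)
  out <- data.frame(region = colnames(M) %||% as.character(seq_len(n_reg)),
                    observed = observed, p = p, q = q,
                    significant = q < alpha, stringsAsFactors = FALSE)
  structure(out, class = c("scn_nodal_test", "data.frame"),
            m = n_reg, K = as.integer(K), groups = groups,
            sparsity = sparsity, alpha = alpha, seed = seed)
}

#' @export
print.scn_nodal_test <- function(x, ...) {
  cat(sprintf("Nodal-degree permutation comparison: %s - %s (m = %d regions, K = %d)\n",
              attr(x, "groups")[1], attr(x, "groups")[2], attr(x, "m"),
              attr(x, "K")))
  sig <- x[x$significant, , drop = FALSE]
  cat(sprintf("  %d region(s) significant at q < %.2f\n", nrow(sig),
              attr(x, "alpha")))
  if (nrow(sig)) print.data.frame(utils::head(sig[order(sig$q), ], 10))
  invisible(x)
}
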