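# Global morphometry group statistics and clinical correlations.

#' ANCOVA on a global morphometric measure with post-hoc t-tests
#'
#' Fits `metric ~ group + covariates` by least squares and reports the
#' omnibus partial F test for the group factor (full vs. covariate-only
#' model). Post-hoc pairwise comparisons are Welch two-sample t-tests on
#' covariate-adjusted values (the metric minus the fitted covariate
#' contributions, covariates centered). With an empty covariate list this is
#' exactly a one-way ANOVA followed by plain Welch t-tests.
#'
#' @param cohort An `scn_cohort` (or a plain data frame with a `group` column
#'   and the metric / covariate columns).
#' @param metric Name of the outcome column (e.g. `"mean_ct"`, `"fd"`,
#'   `"sd"`, `"gi"`).
#' @param covariates Covariate names; default age, sex, total intracranial
#'   volume. Constant covariates are dropped with a warning.
#' @param posthoc `"always"`, `"if_significant"` (only when omnibus p < alpha),
#'   or `"never"`.
#' @param var_equal Use pooled-variance t-tests instead of Welch.
#' @param alpha Gate for `posthoc = "if_significant"`.
#' @return Object of class `scn_ancova`: list with `metric`, `F`, `df`, `p`,
#'   `covariates`, `means` (raw and adjusted per group), `posthoc` (data frame
#'   of pairwise t, df, p), `model`.
#' @export
ancova_global <- function(cohort, metric,
                          covariates = c("age", "sex", "tiv"),
                          posthoc = c("always", "if_significant", "never"),
                          var_equal = FALSE, alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  df <- if (inherits(cohort, "scn_cohort")) cohort$subjects else cohort
  if (!metric %in% names(df)) stop("unknown metric: ", metric, call. = FALSE)
  y <- as.numeric(df[[metric]])
  g <- factor(df$group)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)

  Xc <- NULL
  kept <- character(0)
  for (cv in covariates) {
    v <- if (cv == "sex") as.numeric(df$sex == "M") else as.numeric(df[[cv]])
    if (is.null(v)) stop("unknown covariate: ", cv, call. = FALSE)
    if (stats::var(v, na.rm = TRUE) == 0) {
      warning("dropping constant covariate '", cv, "'", call. = FALSE)
      next
    }
    Xc <- cbind(Xc, v)
    kept <- c(kept, cv)
  }
  if (!is.null(Xc)) colnames(Xc) <- kept

  dat <- data.frame(y = y, g = g)
  if (length(kept)) {
    dat <- cbind(dat, as.data.frame(Xc))
    full <- stats::lm(stats::reformulate(c("g", kept), "y"), data = dat)
    red <- stats::lm(stats::reformulate(kept, "y"), data = dat)
  } else {
    full <- stats::lm(y ~ g, data = dat)
    red <- stats::lm(y ~ 1, data = dat)
  }
  cmp <- stats::anova(red, full)
  Fstat <- cmp$F[2]
  pval <- cmp$`Pr(>F)`[2]

  # covariate-adjusted outcome: subtract fitted covariate effects about their
  # means, so adjusted group means stay on the raw scale
  if (length(kept)) {
    beta <- stats::coef(full)[kept]
    beta[is.na(beta)] <- 0
    y_adj <- y - scale(Xc, scale = FALSE) %*% beta
    y_adj <- as.numeric(y_adj)
  } else y_adj <- y

  means <- data.frame(group = levels(g),
                      raw = tapply(y, g, mean),
                      adjusted = tapply(y_adj, g, mean),
                      n = as.integer(table(g)),
                      row.names = NULL)

  ph <- NULL
  if (posthoc == "always" || (posthoc == "if_significant" && pval < alpha)) {
    pairsL <- utils::combn(levels(g), 2, simplify = FALSE)
    ph <- do.call(rbind, lapply(pairsL, function(pr) {
      tt <- stats::t.test(y_adj[g == pr[1]], y_adj[g == pr[2]],
                          var.equal = var_equal)
      data.frame(group_a = pr[1], group_b = pr[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }))
  }
  structure(list(metric = metric, F = Fstat,
                 df = c(cmp$Df[2], cmp$Res.Df[2]), p = pval,
                 covariates = kept, means = means, posthoc = ph,
                 model = full),
            class = "scn_ancova")
}

#' @export
print.scn_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA on '%s' (covariates: %s)\n", x$metric,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "none"))
  cat(sprintf("  group effect: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc t-tests on adjusted values:\n")
    print.data.frame(x$posthoc, digits = 4)
  }
  invisible(x)
}

#' Spearman correlations between morphological features and clinical scores
#'
#' Rank correlation (midrank tie handling) of every feature column against
#' every clinical score column, on subjects with complete pairs, with
#' Benjamini-Hochberg correction across all pairs actually tested.
#' Correlations with fewer than `min_pairs` complete observations are marked
#' insufficient and excluded from the FDR family.
#'
#' @param features Data frame: `subject_id` plus numeric feature columns.
#' @param clinical Data frame: `subject_id` plus numeric score columns.
#' @param fdr Apply BH correction (default TRUE).
#' @param min_pairs Minimum complete pairs per correlation (default 5).
#' @param alpha Significance level on q (or p when `fdr = FALSE`).
#' @return Data frame of class `scn_correlations`: `feature`, `scale`, `rho`,
#'   `p`, `q`, `n`, `sufficient`, `significant`.
#' @export
spearman_clinical <- function(features, clinical, fdr = TRUE, min_pairs = 5L,
                              alpha = 0.05) {
  if (!"subject_id" %in% names(features) || !"subject_id" %in% names(clinical))
    stop("both tables need a subject_id column", call. = FALSE)
  merged <- merge(features, clinical, by = "subject_id",
                  suffixes = c(".feature", ".scale"))
  fcols <- setdiff(names(features), "subject_id")
  scols <- setdiff(names(clinical), "subject_id")
  fcols_m <- ifelse(fcols %in% scols, paste0(fcols, ".feature"), fcols)
  scols_m <- ifelse(scols %in% fcols, paste0(scols, ".scale"), scols)
  grid <- expand.grid(f = seq_along(fcols), s = seq_along(scols))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fx <- merged[[fcols_m[grid$f[i]]]]
    sx <- merged[[scols_m[grid$s[i]]]]
    ok <- stats::complete.cases(fx, sx)
    n <- sum(ok)
    if (n < min_pairs)
      return(data.frame(feature = fcols[grid$f[i]], scale = scols[grid$s[i]],
                        rho = NA_real_, p = NA_real_, n = n,
                        sufficient = FALSE, stringsAsFactors = FALSE))
    ct <- suppressWarnings(
      stats::cor.test(fx[ok], sx[ok], method = "spearman", exact = FALSE))
    data.frame(feature = fcols[grid$f[i]], scale = scols[grid$s[i]],
               rho = unname(ct$estimate), p = ct$p.value, n = n,
               sufficient = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  if (fdr) out$q[out$sufficient] <- bh_adjust(out$p[out$sufficient])
  out$significant <- !is.na(out$p) &
    (if (fdr) out$q < alpha else out$p < alpha)
  structure(out, class = c("scn_correlations", "data.frame"),
            fdr = fdr, alpha = alpha)
}

#' @export
print.scn_correlations <- function(x, ...) {
  cat(sprintf("Spearman clinical correlations: %d pair(s) tested, %d significant%s\n",
              sum(x$sufficient), sum(x$significant),
              if (attr(x, "fdr")) " (FDR-corrected)" else ""))
  print.data.frame(x[order(x$p), ], digits = 3)
  invisible(x)
}
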