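#' Remove nuisance-covariate effects from regional cortical thickness
#'
#' Fits, for every region, an ordinary least-squares model of thickness on an
#' intercept plus the named covariates, and returns the residuals used for
#' covariance-network construction. The default covariates are age, sex, and
#' each subject's overall mean thickness (the unweighted mean of all regional
#' values). The default scope fits one model per region across all subjects
#' (`"pooled"`); `"per_group"` fits within each group separately.
#'
#' Rank-deficient designs (e.g. a single-sex subset making the sex indicator
#' constant) drop the offending covariate with a warning instead of failing.
#'
#' @param cohort An `scn_cohort`.
#' @param covariates Character vector of covariate names: any numeric subject
#'   column, plus `"sex"` (coded F=0, M=1) and `"mean_ct"` (computed from the
#'   regional matrix).
#' @param scope `"pooled"` (default) or `"per_group"`.
#' @return Object of class `scn_residuals`: list with `residuals` (subjects x
#'   regions matrix, same dimnames as the thickness matrix), `coefficients`
#'   (list per scope of coefficient matrices), `covariates`, `scope`, `group`
#'   (per-subject labels), `subjects`.
#' @examples
#' sim <- generate_cohort(scn_sim_config(
#'   group_sizes = c(A = 8, B = 8), n_regions = 12,
#'   topology = list(A = list(family = "lattice", k = 2),
#'                   B = list(family = "lattice", k = 2)), seed = 3))
#' res <- residualize(sim$cohort)
#' max(abs(colMeans(res$residuals)))  # ~0: residuals are mean-zero per region
#' @export
residualize <- function(cohort,
                        covariates = c("age", "sex", "mean_ct"),
                        scope = c("pooled", "per_group")) {
  stopifnot(inherits(cohort, "scn_cohort"))
  scope <- match.arg(scope)
  Y <- cohort$ct
  X <- build_design(cohort, covariates)
  res <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  coefs <- list()
  fit_block <- function(rows, tag) {
    if (length(rows) <= ncol(X) + 1L)
      stop(sprintf("scope '%s': %d subjects cannot support %d covariates",
                   tag, length(rows), ncol(X) - 1L), call. = FALSE)
    Xb <- drop_deficient(X[rows, , drop = FALSE], tag)
    qrX <- qr(Xb)
    res[rows, ] <<- qr.resid(qrX, Y[rows, , drop = FALSE])
    cf <- qr.coef(qrX, Y[rows, , drop = FALSE])
    coefs[[tag]] <<- cf
  }
  if (scope == "pooled") {
    fit_block(seq_len(nrow(Y)), "pooled")
  } else {
    for (g in unique(cohort$subjects$group))
      fit_block(which(cohort$subjects$group == g), g)
  }
  structure(list(residuals = res, coefficients = coefs,
                 covariates = covariates, scope = scope,
                 group = cohort$subjects$group,
                 subjects = cohort$subjects$subject_id),
            class = "scn_residuals")
}

# Design matrix: intercept + requested covariates, with sex as an indicator
# and mean_ct computed live from the regional matrix.
build_design <- function(cohort, covariates) {
  n <- nrow(cohort$ct)
  cols <- list(`(Intercept)` = rep(1, n))
  for (cv in covariates) {
    cols[[cv]] <- switch(cv,
      sex = as.numeric(cohort$subjects$sex == "M"),
      mean_ct = rowMeans(cohort$ct),
      {
        v <- cohort$subjects[[cv]]
        if (is.null(v)) stop("unknown covariate: ", cv, call. = FALSE)
        as.numeric(v)
      })
    if (stats::var(cols[[cv]]) == 0)
      stop("covariate '", cv, "' is constant", call. = FALSE)
  }
  do.call(cbind, cols)
}

# Drop columns (never the intercept) until the design has full column rank.
drop_deficient <- function(X, tag) {
  repeat {
    q <- qr(X)
    if (q$rank == ncol(X)) return(X)
    drop_idx <- q$pivot[(q$rank + 1):ncol(X)]
    drop_idx <- setdiff(drop_idx, 1L)
    warning(sprintf("residualize [%s]: dropping rank-deficient covariate(s) %s",
                    tag, paste(colnames(X)[drop_idx], collapse = ", ")),
            call. = FALSE)
    X <- X[, -drop_idx, drop = FALSE]
  }
}

#' @export
print.scn_residuals <- function(x, ...) {
  cat(sprintf("Residualized CT: %d subjects x %d regions (scope: %s)\n",
              nrow(x$residuals), ncol(x$residuals), x$scope))
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Write residuals and fitted coefficients to TSV
#' @param res An `scn_residuals`.
#' @param path Residual-matrix TSV path; a `*_coefficients.tsv` sidecar is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_residuals <- function(res, path) {
  df <- data.frame(subject_id = res$subjects, group = res$group,
                   apply(res$residuals, 2, format_full),
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("(\\.[^.]+)?$", "_coefficients.tsv", path)
  cf <- do.call(rbind, lapply(names(res$coefficients), function(tag) {
    m <- res$coefficients[[tag]]
    data.frame(scope = tag, term = rownames(m),
               apply(m, 2, format_full),
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  utils::write.table(cf, side, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
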