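#' Group-level Pearson covariance (correlation) matrix
#'
#' Pearson correlation between the residualized thickness vectors of every
#' region pair, across the subjects of one group. This is the structural
#' covariance matrix of that group.
#'
#' @param residuals An `scn_residuals` object (or a plain subjects x regions
#'   matrix if `group_labels` is supplied).
#' @param group Group label to subset, or `NULL` to use all rows.
#' @param group_labels Per-row group labels when `residuals` is a bare matrix.
#' @param on_constant `"zero"` (default): a region constant across the group
#'   gets zero correlations with a warning; `"fail"`: error.
#' @return N x N correlation matrix of class `scn_covariance` with attributes
#'   `group` and `n_subjects`; symmetric with unit diagonal.
#' @export
group_covariance <- function(residuals, group = NULL, group_labels = NULL,
                             on_constant = c("zero", "fail")) {
  on_constant <- match.arg(on_constant)
  if (inherits(residuals, "scn_residuals")) {
    M <- residuals$residuals
    group_labels <- residuals$group
  } else {
    M <- as.matrix(residuals)
  }
  if (!is.null(group)) {
    if (is.null(group_labels)) stop("group labels required", call. = FALSE)
    M <- M[group_labels == group, , drop = FALSE]
  }
  if (nrow(M) < 3L)
    stop("need at least 3 subjects to estimate correlations", call. = FALSE)
  sds <- apply(M, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    if (on_constant == "fail")
      stop("constant region(s): ",
           paste(colnames(M)[const], collapse = ", "), call. = FALSE)
    warning(sum(const), " degenerate (constant) region(s); correlations set to 0",
            call. = FALSE)
  }
  R <- suppressWarnings(stats::cor(M))
  R[const, ] <- 0
  R[, const] <- 0
  diag(R) <- 1
  R <- (R + t(R)) / 2  # kill asymmetric floating-point dust
  structure(R, class = c("scn_covariance", "matrix", "array"),
            group = group %||% "all", n_subjects = nrow(M))
}

#' Sparsify and binarize a covariance matrix into a network
#'
#' Ranks all N(N-1)/2 region pairs by correlation (`edge_rule = "signed"`,
#' the default: most positive first) or by absolute correlation
#' (`"absolute"`), and keeps the top `round(sparsity * N(N-1)/2)` pairs as
#' edges of an undirected binary network. Exact ties at the cutoff are broken
#' by lexicographic region-index order, so the result is deterministic.
#'
#' @param cov Correlation matrix (ideally from [group_covariance()]).
#' @param sparsity Fraction of possible edges to retain, in (0, 1);
#'   default 0.15.
#' @param edge_rule `"signed"` or `"absolute"`.
#' @return Binary adjacency matrix of class `scn_network` with attributes
#'   `sparsity`, `n_edges`, `edge_rule`, `group`.
#' @examples
#' R <- diag(4); R[1, 2] <- R[2, 1] <- 0.9; R[3, 4] <- R[4, 3] <- 0.8
#' sum(sparsify_binarize(R, 1 / 3)) / 2  # 2 edges
#' @export
sparsify_binarize <- function(cov, sparsity = 0.15,
                              edge_rule = c("signed", "absolute")) {
  edge_rule <- match.arg(edge_rule)
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity <= 0 || sparsity >= 1)
    stop("sparsity must be in (0, 1)", call. = FALSE)
  M <- unclass(cov)
  n <- nrow(M)
  pairs <- upper_pairs(n)
  r <- M[pairs]
  keyed <- if (edge_rule == "absolute") abs(r) else r
  n_keep <- round(sparsity * nrow(pairs))
  if (n_keep < 1L)
    stop("sparsity retains zero edges at N = ", n, call. = FALSE)
  ord <- order(-keyed, pairs[, 1], pairs[, 2])
  keep <- pairs[ord[seq_len(n_keep)], , drop = FALSE]
  A <- matrix(0, n, n, dimnames = dimnames(M))
  A[keep] <- 1
  A[keep[, 2:1, drop = FALSE]] <- 1
  structure(A, class = c("scn_network", "matrix", "array"),
            sparsity = sparsity, n_edges = n_keep, edge_rule = edge_rule,
            group = attr(cov, "group"))
}

#' @export
print.scn_network <- function(x, ...) {
  cat(sprintf("Binary network '%s': %d nodes, %d edges (sparsity %.3f, %s rule)\n",
              attr(x, "group") %||% "?", nrow(x), attr(x, "n_edges"),
              attr(x, "sparsity"), attr(x, "edge_rule")))
  invisible(x)
}

#' Write a network as an edge list plus adjacency TSV
#' @param network An `scn_network`.
#' @param cov The covariance matrix it came from (for edge weights in the
#'   list); optional.
#' @param path Edge-list TSV path; an `*_adjacency.tsv` sidecar is written
#'   next to it.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, cov = NULL) {
  e <- which(upper.tri(network) & network == 1, arr.ind = TRUE)
  labels <- colnames(network) %||% as.character(seq_len(ncol(network)))
  df <- data.frame(label_i = labels[e[, 1]], label_j = labels[e[, 2]],
                   stringsAsFactors = FALSE)
  if (!is.null(cov)) df$r <- format_full(unclass(cov)[e])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  adj <- sub("(\\.[^.]+)?$", "_adjacency.tsv", path)
  utils::write.table(as.data.frame(unclass(network)), adj, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
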