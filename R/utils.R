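# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' library code never clobbers a user's random stream. With `seed = NULL` the
#' expression runs on the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a vector of child seeds from one master seed, each < 2^31.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Validate a binary adjacency matrix
#'
#' Requires a square, symmetric, hollow (zero-diagonal) 0/1 matrix with no
#' missing values. Used by every graph-metric entry point.
#' @noRd
validate_adjacency <- function(A, n_min = 1L) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("adjacency must be a square matrix", call. = FALSE)
  if (anyNA(A)) stop("adjacency contains missing values", call. = FALSE)
  if (!all(A %in% c(0, 1)))
    stop("adjacency must be binary (0/1)", call. = FALSE)
  if (any(diag(A) != 0))
    stop("adjacency must be hollow (zero diagonal)", call. = FALSE)
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE)))
    stop("adjacency must be symmetric", call. = FALSE)
  if (nrow(A) < n_min)
    stop(sprintf("adjacency needs at least %d nodes", n_min), call. = FALSE)
  invisible(TRUE)
}

# Multivariate normal draws via the Cholesky factor: n x ncol(Sigma) matrix.
rmvn_chol <- function(n, sigma) {
  p <- ncol(sigma)
  U <- chol(sigma)
  matrix(stats::rnorm(n * p), n, p) %*% U
}

# Benjamini-Hochberg adjustment; single chokepoint so every module shares the
# same multiple-testing path.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Upper-triangle index pairs (i < j) of an N x N matrix, as a 2-column matrix.
upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}
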