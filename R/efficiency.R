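# Efficiency-based topology measures on binary undirected networks.

#' All-pairs unweighted shortest-path lengths
#'
#' Breadth-first search expressed as iterated boolean products of the
#' adjacency matrix: the wavefront reachable within d+1 steps is the set of
#' neighbours of the wavefront at d. Unreached pairs stay `Inf`.
#'
#' @param adjacency Symmetric hollow 0/1 matrix.
#' @return N x N matrix of path lengths (0 on the diagonal, `Inf` where
#'   disconnected).
#' @export
graph_distances <- function(adjacency) {
  validate_adjacency(adjacency)
  n <- nrow(adjacency)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  B <- adjacency
  diag(B) <- 1
  R <- B
  d <- 1
  repeat {
    new <- R > 0 & is.infinite(D)
    if (!any(new)) break
    D[new] <- d
    if (d >= n - 1L) break
    R <- (R %*% B > 0) + 0
    d <- d + 1
  }
  D
}

#' Global efficiency of a binary network
#'
#' `GE = 1/(N(N-1)) * sum_{i != j} 1 / L_ij`, with `L_ij` the unweighted
#' shortest-path length. Disconnected pairs contribute 0 (`1/Inf`), which is
#' what lets the measure handle disconnected graphs; GE lies in `[0, 1]` and
#' equals 1 exactly for the complete graph.
#'
#' @param adjacency Symmetric hollow 0/1 matrix, N >= 2.
#' @return Scalar in `[0, 1]`.
#' @examples
#' K4 <- 1 - diag(4)
#' global_efficiency(K4)  # 1
#' @export
global_efficiency <- function(adjacency) {
  validate_adjacency(adjacency, n_min = 2L)
  D <- graph_distances(adjacency)
  inv <- 1 / D
  diag(inv) <- 0
  n <- nrow(adjacency)
  sum(inv) / (n * (n - 1))
}

#' Local efficiency of a binary network
#'
#' Mean over nodes of the global efficiency of the subgraph induced on each
#' node's immediate neighbours (the node itself excluded). Nodes with fewer
#' than two neighbours contribute 0.
#'
#' @inheritParams global_efficiency
#' @return Scalar in `[0, 1]`.
#' @examples
#' star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
#' local_efficiency(star)  # 0: the hub's neighbours are mutually unconnected
#' @export
local_efficiency <- function(adjacency) {
  validate_adjacency(adjacency, n_min = 2L)
  n <- nrow(adjacency)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adjacency[i, ] != 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(adjacency[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Nodal degree
#'
#' Number of immediate neighbours of each node (row sums of the binary
#' adjacency); used to identify network hubs.
#'
#' @inheritParams global_efficiency
#' @return Integer vector of length N (named if the adjacency has dimnames).
#' @export
nodal_degree <- function(adjacency) {
  validate_adjacency(adjacency)
  deg <- as.integer(rowSums(adjacency))
  names(deg) <- rownames(adjacency)
  deg
}

#' Degree-preserving random rewiring (double-edge swaps)
#'
#' Randomizes a network while preserving every node's degree: repeatedly picks
#' two edges (a,b), (c,d) with four distinct endpoints and replaces them with
#' (a,d), (c,b) if neither already exists. Proposals that would create a
#' self-loop or multi-edge are rejected and retried; attempts are capped at
#' `100 * n_swaps` to guarantee termination.
#'
#' @param adjacency Symmetric hollow 0/1 matrix with >= 2 edges (graphs with
#'   fewer are returned unchanged with a warning).
#' @param n_swaps Number of successful swaps to perform; default 10 x edge
#'   count.
#' @param seed Optional seed.
#' @return Rewired adjacency with the same degree sequence and edge count.
#' @export
rewire_preserving_degree <- function(adjacency, n_swaps = NULL, seed = NULL) {
  validate_adjacency(adjacency)
  el <- which(upper.tri(adjacency) & adjacency == 1, arr.ind = TRUE)
  m <- nrow(el)
  if (m < 2L) {
    warning("fewer than 2 edges; returning the graph unchanged", call. = FALSE)
    return(adjacency)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * m
  if (n_swaps < 1L) stop("n_swaps must be >= 1", call. = FALSE)
  with_seed(seed, {
    A <- adjacency
    successes <- 0L
    attempts <- 0L
    cap <- 100L * n_swaps
    while (successes < n_swaps && attempts < cap) {
      attempts <- attempts + 1L
      e <- sample.int(m, 2L)
      a <- el[e[1L], 1L]; b <- el[e[1L], 2L]
      c <- el[e[2L], 1L]; d <- el[e[2L], 2L]
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      if (a == c || a == d || b == c || b == d) next
      if (A[a, d] == 1 || A[c, b] == 1) next
      A[a, b] <- A[b, a] <- 0
      A[c, d] <- A[d, c] <- 0
      A[a, d] <- A[d, a] <- 1
      A[c, b] <- A[b, c] <- 1
      el[e[1L], ] <- c(min(a, d), max(a, d))
      el[e[2L], ] <- c(min(c, b), max(c, b))
      successes <- successes + 1L
    }
    A
  })
}

#' Efficiencies normalized against degree-preserving random networks
#'
#' Computes GE and LE of the network, the means of GE and LE over `n_random`
#' independent degree-preserving rewired realizations, the normalized ratios
#' `nGE = GE(real)/GE(random)` and `nLE = LE(real)/LE(random)`, nodal degree,
#' and a small-world flag. The small-world criterion is `nLE > 1` together
#' with `nGE ~ 1` (within `tau`, default 0.1).
#'
#' @inheritParams global_efficiency
#' @param n_random Number of rewired null networks to average (default 100).
#' @param seed Optional seed driving the whole null ensemble.
#' @param tau Tolerance for `|nGE - 1|` in the small-world flag.
#' @param n_swaps Swaps per rewiring (default 10 x edge count).
#' @return Object of class `scn_metrics`: list with `ge`, `le`, `ge_random`,
#'   `le_random`, `nge`, `nle`, `degree`, `n_random`, `tau`,
#'   `small_world`. Degenerate null ensembles (mean 0) yield `NA` ratios
#'   rather than infinities.
#' @export
normalized_efficiencies <- function(adjacency, n_random = 100L, seed = NULL,
                                    tau = 0.1, n_swaps = NULL) {
  validate_adjacency(adjacency, n_min = 2L)
  if (n_random < 1L) stop("n_random must be >= 1", call. = FALSE)
  ge <- global_efficiency(adjacency)
  le <- local_efficiency(adjacency)
  seeds <- if (is.null(seed)) rep(list(NULL), n_random)
           else as.list(spawn_seeds(seed, n_random))
  ge_r <- le_r <- numeric(n_random)
  for (i in seq_len(n_random)) {
    Ar <- rewire_preserving_degree(adjacency, n_swaps = n_swaps,
                                   seed = seeds[[i]])
    ge_r[i] <- global_efficiency(Ar)
    le_r[i] <- local_efficiency(Ar)
  }
  mge <- mean(ge_r); mle <- mean(le_r)
  nge <- if (mge > 0) ge / mge else NA_real_
  nle <- if (mle > 0) le / mle else NA_real_
  structure(list(ge = ge, le = le, ge_random = mge, le_random = mle,
                 nge = nge, nle = nle, degree = nodal_degree(adjacency),
                 n_random = as.integer(n_random), tau = tau,
                 small_world = isTRUE(nle > 1 && abs(nge - 1) <= tau)),
            class = "scn_metrics")
}

#' @export
print.scn_metrics <- function(x, digits = 4, ...) {
  cat("Network efficiency metrics\n")
  cat(sprintf("  GE = %.*f, LE = %.*f\n", digits, x$ge, digits, x$le))
  cat(sprintf("  nGE = %s, nLE = %s (null ensemble: %d rewired networks)\n",
              formatC(x$nge, digits = digits, format = "f"),
              formatC(x$nle, digits = digits, format = "f"), x$n_random))
  cat(sprintf("  small-world (nLE > 1 and |nGE - 1| <= %.2f): %s\n",
              x$tau, x$small_world))
  invisible(x)
}
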