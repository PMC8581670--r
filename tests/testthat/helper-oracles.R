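# Independent oracles for graph metrics, coded separately from the production
# BFS path (Floyd-Warshall relaxation + scalar accumulation loops).

fw_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

ge_oracle <- function(A) {
  n <- nrow(A)
  D <- fw_distances(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
  s / (n * (n - 1))
}

le_oracle <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    ge_oracle(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

random_graph <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up[stats::runif(length(up)) < p]] <- 1
  A + t(A)
}

# Named graphs used in closed-form checks
complete_graph <- function(n) 1 - diag(n)
path3 <- local({
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1; A
})
star_graph <- function(leaves) {
  A <- matrix(0, leaves + 1, leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1
  A
}
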