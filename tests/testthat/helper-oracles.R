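# Independent oracles and fixture builders.  Every oracle takes the dumb,
# exhaustive route on purpose: enumeration and straight formulas, sharing
# no code path with the package implementation.

# enumerate every centre/neighbour-pair triple and classify it
oracle_count_triples <- function(B) {
  B <- (B != 0) * 1
  n <- nrow(B)
  clustered <- 0L; spanning <- 0L
  for (centre in seq_len(n)) {
    nb <- which(B[centre, ] == 1)
    if (length(nb) < 2L) next
    prs <- utils::combn(nb, 2L)
    for (p in seq_len(ncol(prs))) {
      if (B[prs[1L, p], prs[2L, p]] == 1) clustered <- clustered + 1L
      else spanning <- spanning + 1L
    }
  }
  list(clustered = clustered, spanning = spanning,
       total = clustered + spanning)
}

# exhaustive threshold scan with the enumerating triple counter,
# minimizing the normalized balance gap |C - S| / (C + S)
oracle_cst <- function(W) {
  cand <- sort(unique(W[upper.tri(W)]))
  cand <- cand[cand > 0]
  best <- NULL
  for (t in cand) {
    B <- (W >= t) * 1; diag(B) <- 0
    ct <- oracle_count_triples(B)
    if (ct$total == 0L) next
    gap <- abs(ct$clustered - ct$spanning) / ct$total
    if (is.null(best) || gap < best$gap)
      best <- list(threshold = t, gap = gap,
                   imbalance = abs(ct$clustered - ct$spanning))
  }
  best  # NULL when no admissible candidate
}

# independent embedding + arccos route (unit scaling); ordering by
# descending |lambda| with positive-first ties, like the convention under
# test, but built directly on eigen() output
oracle_angles <- function(W, k = 3L) {
  e <- eigen(W, symmetric = TRUE)
  ord <- order(-abs(e$values), -e$values)
  V <- e$vectors[, ord[seq_len(k)], drop = FALSE]
  n <- nrow(W)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(V[i, ] * V[j, ])
    den <- sqrt(sum(V[i, ]^2)) * sqrt(sum(V[j, ]^2))
    A[i, j] <- acos(min(1, max(-1, num / den)))
  }
  diag(A) <- 0
  A
}

# power-iteration eigenvector centrality
oracle_power_ec <- function(W, iters = 10000L, tol = 1e-14) {
  v <- rep(1, nrow(W)) / sqrt(nrow(W))
  for (i in seq_len(iters)) {
    v2 <- W %*% v
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < tol) break
    v <- as.vector(v2)
  }
  as.vector(v)
}

# random symmetric weighted graph with edge probability p
random_weighted_graph <- function(n, p = 0.5) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- up[stats::runif(length(up)) < p]
  W[on] <- stats::runif(length(on))
  W + t(W)
}

# named small graphs
graph_p3 <- function() {
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 3] <- 1
  W + t(W)
}

graph_cst_example <- function() {
  W <- matrix(0, 4, 4)
  W[1, 2] <- .9; W[1, 3] <- .8; W[2, 3] <- .7
  W[3, 4] <- .5; W[1, 4] <- .3; W[2, 4] <- .2
  W + t(W)
}

graph_weighted4 <- function() {
  matrix(c(0, .8, .3, 0,
           .8, 0, .5, .3,
           .3, .5, 0, .9,
           0, .3, .9, 0), 4, 4)
}

# weighted star: hub 1, distinct leaf weights so the spectrum is simple
graph_star <- function(n_leaves = 5) {
  n <- n_leaves + 1L
  W <- matrix(0, n, n)
  W[1, 2:n] <- W[2:n, 1] <- 0.5 + 0.4 * seq_len(n_leaves) / n_leaves
  W
}
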