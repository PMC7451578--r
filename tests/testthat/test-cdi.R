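# small fixture: embed + scale + positions for any weighted matrix
cdi_inputs <- function(W, k = 3, scaling = "cdi") {
  emb <- suppressWarnings(dominant_eigenpairs(W, k = k))
  emb <- scale_embedding(emb, scaling)
  list(P = position_vectors(emb),
       ec = eigenvector_centrality(emb), W = W)
}

test_that("a dominant hub is the unique leader of a star", {
  x <- cdi_inputs(graph_star(5))
  d <- sqrt(rowSums(x$P^2))
  expect_gt(d[1], max(d[-1]))          # embedding puts the hub farthest
  leaders <- find_leaders(x$P, x$W)
  expect_identical(as.integer(leaders), 1L)
})

test_that("every component owns at least one leader", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- .9; W[3, 4] <- .4
  W <- W + t(W)
  x <- cdi_inputs(W, k = 2, scaling = "unit")
  leaders <- as.integer(suppressWarnings(find_leaders(x$P, x$W)))
  expect_true(any(leaders %in% 1:2))
  expect_true(any(leaders %in% 3:4))
})

test_that("fully tied components promote their lowest-index maximum with a flag", {
  x <- cdi_inputs(graph_p3(), scaling = "unit")
  expect_warning(leaders <- find_leaders(x$P, x$W), "promoted")
  expect_identical(as.integer(leaders), 1L)
  expect_true(attr(leaders, "degenerate"))
})

test_that("an edgeless graph is a degenerate topology", {
  P <- matrix(stats::rnorm(9), 3, 3)
  expect_error(find_leaders(P, matrix(0, 3, 3)), "no edges")
})

test_that("a single leader absorbs every node", {
  x <- cdi_inputs(graph_star(5))
  part <- assign_communities(x$P, x$W, find_leaders(x$P, x$W),
                             ec = x$ec)
  expect_true(all(part$membership == 1L))
  ranked <- rank_communities(part, x$ec)
  expect_identical(ranked$ranks, 1L)
})

test_that("disconnected cliques form separate communities along component lines", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- .8; W[5:8, 5:8] <- .6
  diag(W) <- 0
  # break ties within cliques so each has a strict leader
  W[1, 2] <- W[2, 1] <- .95; W[5, 6] <- W[6, 5] <- .75
  x <- cdi_inputs(W)
  leaders <- find_leaders(x$P, x$W)
  part <- suppressWarnings(
    assign_communities(x$P, x$W, leaders, ec = x$ec))
  comp1 <- unique(part$membership[1:4])
  comp2 <- unique(part$membership[5:8])
  expect_length(intersect(comp1, comp2), 0L)
})

test_that("assignment maximizes the position dot product among reachable leaders", {
  set.seed(201)
  for (rep in 1:20) {
    W <- random_weighted_graph(10, p = .5)
    if (sum(W != 0) == 0) next
    x <- cdi_inputs(W)
    leaders <- suppressWarnings(find_leaders(x$P, x$W))
    part <- assign_communities(x$P, x$W, leaders, ec = x$ec)
    li <- as.integer(leaders)
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      (W != 0) * 1, mode = "undirected"))$membership
    for (i in seq_len(10)) {
      if (i %in% li) {
        expect_identical(part$membership[i], match(i, li))
        next
      }
      reach <- which(comp[li] == comp[i])
      dots <- vapply(reach, function(r) sum(x$P[li[r], ] * x$P[i, ]),
                     numeric(1))
      expect_identical(part$membership[i], reach[which.max(dots)])
    }
  }
})

test_that("community ranking equals the sort-by-max-EC oracle", {
  set.seed(211)
  for (rep in 1:20) {
    W <- random_weighted_graph(12, p = .4)
    if (sum(W != 0) == 0) next
    x <- cdi_inputs(W)
    part <- suppressWarnings(cdi_partition(x$P, x$W, x$ec))
    k <- length(part$leaders)
    max_ec <- vapply(seq_len(k), function(c)
      max(x$ec[part$membership == c]), numeric(1))
    oracle_order <- order(-max_ec, part$leaders)
    expect_identical(part$ranks[oracle_order], seq_len(k))
    # the global EC argmax always sits in the rank-1 community
    expect_identical(part$ranks[part$membership[which.max(x$ec)]], 1L)
  }
})

test_that("size profiles summarize the influence extremes", {
  part <- structure(list(membership = rep(1:3, c(7, 3, 2)),
                         leaders = c(1L, 8L, 11L),
                         ranks = c(1L, 2L, 3L), degenerate = FALSE),
                    class = "cdi_partition")
  prof <- community_size_profile(part)
  expect_identical(prof$most, 7L)
  expect_identical(prof$least, 2L)
  expect_identical(prof$mean_two_most, 5)
  expect_identical(prof$mean_two_least, 2.5)
  expect_identical(prof$n_communities, 3L)
  expect_false(prof$single_community)

  solo <- structure(list(membership = rep(1L, 6), leaders = 2L,
                         ranks = 1L, degenerate = FALSE),
                    class = "cdi_partition")
  prof1 <- community_size_profile(solo)
  expect_identical(prof1$most, 6L)
  expect_identical(prof1$least, 6L)
  expect_true(prof1$single_community)
})

test_that("CDI is deterministic, total and disjoint, with strict or flagged leaders", {
  set.seed(221)
  for (rep in 1:15) {
    W <- random_weighted_graph(12, p = .5)
    if (sum(W != 0) == 0) next
    x <- cdi_inputs(W)
    p1 <- suppressWarnings(cdi_partition(x$P, x$W, x$ec))
    p2 <- suppressWarnings(cdi_partition(x$P, x$W, x$ec))
    expect_identical(p1, p2)
    # total and disjoint: one community per node, all communities used
    expect_identical(length(p1$membership), 12L)
    expect_true(all(p1$membership %in% seq_along(p1$leaders)))
    expect_setequal(unique(p1$membership), seq_along(p1$leaders))
    # each community contains its leader
    for (c in seq_along(p1$leaders))
      expect_identical(p1$membership[p1$leaders[c]], c)
    # leaders strictly out-distance neighbours unless degeneracy flagged
    d <- sqrt(rowSums(x$P^2))
    strict <- vapply(p1$leaders, function(l) {
      nb <- which(W[l, ] != 0)
      length(nb) == 0L || d[l] > max(d[nb])
    }, logical(1))
    expect_true(all(strict) || p1$degenerate)
    expect_true(is.integer(p1$ranks) &&
                  setequal(p1$ranks, seq_along(p1$leaders)))
  }
})

test_that("partitions are invariant to eigenvector sign flips and equivariant to permutation", {
  set.seed(231)
  W <- random_weighted_graph(10, p = .6)
  emb <- suppressWarnings(dominant_eigenpairs(W, k = 3))
  emb <- scale_embedding(emb, "cdi")
  ec <- eigenvector_centrality(emb)
  P <- position_vectors(emb)
  base <- suppressWarnings(cdi_partition(P, W, ec))

  Pf <- P; Pf[, 2] <- -Pf[, 2]; Pf[, 3] <- -Pf[, 3]
  flipped <- suppressWarnings(cdi_partition(Pf, W, ec))
  expect_identical(flipped$membership, base$membership)
  expect_identical(flipped$leaders, base$leaders)

  perm <- sample(10)
  emb_p <- suppressWarnings(dominant_eigenpairs(W[perm, perm], k = 3))
  emb_p <- scale_embedding(emb_p, "cdi")
  part_p <- suppressWarnings(cdi_partition(
    position_vectors(emb_p), W[perm, perm],
    eigenvector_centrality(emb_p)))
  # communities as node sets must match under the permutation
  comm_of <- function(part, node) which(part$membership == part$membership[node])
  for (i in 1:10)
    expect_setequal(comm_of(part_p, match(i, perm)),
                    match(comm_of(base, i), perm))
})
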