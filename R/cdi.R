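#' Find CDI community leaders
#'
#' A node is a leader when it lies strictly further from the origin of the
#' embedded coordinate frame than every one of its topological neighbours.
#' Nodes with no connections are vacuously leaders of their own singleton
#' communities.  On perfectly symmetric graphs the strict rule can leave a
#' connected component with no leader (all distances tied); the component's
#' maximum-distance node (lowest index on ties) is then promoted and a
#' degeneracy flag recorded, so a partition always exists.
#'
#' @param positions n x k matrix from [position_vectors()] (the scaled
#'   frame used for the whole CDI assessment).
#' @param topology Thresholded weight matrix (nonzero = edge).
#' @return Integer vector of leader node indices, with logical attribute
#'   `degenerate` marking promoted leaders' components.
#' @export
find_leaders <- function(positions, topology) {
  P <- unclass(positions)
  W <- if (inherits(topology, "fc_matrix")) as_weight_matrix(topology)
       else unclass(topology)
  n <- nrow(P)
  if (nrow(W) != n)
    stop("positions and topology must share the node set", call. = FALSE)
  B <- W != 0
  if (!any(B))
    stop("degenerate topology: graph has no edges", call. = FALSE)
  d <- sqrt(rowSums(P^2))
  leader <- vapply(seq_len(n), function(i) {
    nb <- which(B[i, ])
    length(nb) == 0L || d[i] > max(d[nb])
  }, logical(1))
  comp <- graph_components(B)
  degenerate <- FALSE
  for (cmp in seq_len(comp$no)) {
    members <- which(comp$membership == cmp)
    if (!any(leader[members])) {
      top <- members[which.max(d[members])]  # lowest index wins ties
      leader[top] <- TRUE
      degenerate <- TRUE
    }
  }
  if (degenerate)
    warning("tied embedding distances: promoted the maximum-distance ",
            "node of a leaderless component", call. = FALSE)
  structure(which(leader), degenerate = degenerate)
}

#' Assign every node to a leader's community
#'
#' Non-leader nodes may only join leaders reachable through the topology
#' (same connected component -- the weakest faithful reading of "lies on a
#' path that connects to the leader").  Among reachable leaders a node
#' joins the one whose position vector has the largest dot product with
#' its own, i.e. the most closely aligned leader in the scaled frame.
#' Ties go to the leader with higher eigenvector centrality, then lower
#' index.
#'
#' @param positions n x k position matrix (scaled frame).
#' @param topology Thresholded weight matrix.
#' @param leaders Leader indices from [find_leaders()].
#' @param ec Optional EC vector for tie-breaking; defaults to the first
#'   position coordinate (a positive multiple of EC in this frame).
#' @return Object of class `"cdi_partition"`: `membership` (node ->
#'   community id as index into `leaders`), `leaders`, `ranks` (filled by
#'   [rank_communities()]), `degenerate`.
#' @export
assign_communities <- function(positions, topology, leaders, ec = NULL) {
  P <- unclass(positions)
  W <- if (inherits(topology, "fc_matrix")) as_weight_matrix(topology)
       else unclass(topology)
  n <- nrow(P)
  leaders_idx <- as.integer(leaders)
  if (length(leaders_idx) < 1L)
    stop("need at least one leader", call. = FALSE)
  if (any(leaders_idx < 1L | leaders_idx > n))
    stop("leader index out of range", call. = FALSE)
  if (is.null(ec)) ec <- P[, 1L]
  comp <- graph_components(W != 0)
  membership <- integer(n)
  for (i in seq_len(n)) {
    li <- match(i, leaders_idx)
    if (!is.na(li)) { membership[i] <- li; next }
    reach <- which(comp$membership[leaders_idx] == comp$membership[i])
    if (length(reach) == 0L)
      stop("internal error: component without leader", call. = FALSE)
    dots <- as.numeric(P[leaders_idx[reach], , drop = FALSE] %*% P[i, ])
    best <- reach[order(-dots, -ec[leaders_idx[reach]],
                        leaders_idx[reach])][1L]
    membership[i] <- best
  }
  structure(list(membership = membership, leaders = leaders_idx,
                 ranks = NULL,
                 degenerate = isTRUE(attr(leaders, "degenerate"))),
            class = "cdi_partition")
}

#' Rank communities by their most central member
#'
#' The community containing the node with the largest eigenvector
#' centrality is ranked 1 (most influential); the rest follow in
#' descending order of their maximum member EC.  Ties break toward the
#' lower leader index.
#'
#' @param partition A [assign_communities()] partition.
#' @param ec Eigenvector-centrality vector over nodes.
#' @return The partition with `ranks` filled: `ranks[c]` is the influence
#'   rank of community `c` (1 = most influential).
#' @export
rank_communities <- function(partition, ec) {
  stopifnot(inherits(partition, "cdi_partition"))
  k <- length(partition$leaders)
  if (length(ec) < max(partition$leaders))
    stop("ec and partition must share the node set", call. = FALSE)
  max_ec <- vapply(seq_len(k), function(c)
    max(ec[partition$membership == c]), numeric(1))
  ord <- order(-max_ec, partition$leaders)
  ranks <- integer(k)
  ranks[ord] <- seq_len(k)
  partition$ranks <- ranks
  partition$max_ec <- max_ec
  partition
}

#' Community size profile at the influence extremes
#'
#' Sizes of the most and least influential communities, the means of the
#' two most and two least influential, and the community count -- the
#' statistics compared between subject groups.  With a single community
#' all fields equal its size and `single_community` is flagged.
#'
#' @param partition A ranked [rank_communities()] partition.
#' @return List: `most`, `least`, `mean_two_most`, `mean_two_least`,
#'   `n_communities`, `single_community`.
#' @export
community_size_profile <- function(partition) {
  stopifnot(inherits(partition, "cdi_partition"))
  if (is.null(partition$ranks))
    stop("partition must be ranked first (rank_communities)",
         call. = FALSE)
  sizes <- tabulate(partition$membership,
                    nbins = length(partition$leaders))
  by_rank <- sizes[order(partition$ranks)]
  k <- length(by_rank)
  single <- k < 2L
  list(most = by_rank[1L],
       least = by_rank[k],
       mean_two_most = mean(by_rank[seq_len(min(2L, k))]),
       mean_two_least = mean(by_rank[seq.int(max(1L, k - 1L), k)]),
       n_communities = k,
       single_community = single)
}

#' Communities of dynamical influence
#'
#' One-call CDI: finds leaders, assigns every node to its most aligned
#' reachable leader, and ranks communities by maximum member EC.  CDI is
#' fully deterministic -- identical input always yields the identical
#' partition.
#'
#' @param positions n x k scaled position matrix.
#' @param topology Thresholded weight matrix.
#' @param ec Eigenvector-centrality vector (used for ranking and
#'   tie-breaks).
#' @return A ranked `"cdi_partition"`.
#' @export
cdi_partition <- function(positions, topology, ec) {
  leaders <- find_leaders(positions, topology)
  part <- assign_communities(positions, topology, leaders, ec = ec)
  rank_communities(part, ec)
}

#' @export
print.cdi_partition <- function(x, ...) {
  k <- length(x$leaders)
  sizes <- tabulate(x$membership, nbins = k)
  cat(sprintf("CDI partition: %d communities over %d nodes\n",
              k, length(x$membership)))
  if (!is.null(x$ranks)) {
    ord <- order(x$ranks)
    cat("  rank  leader  size\n")
    for (c in ord)
      cat(sprintf("  %4d  %6d  %4d\n", x$ranks[c], x$leaders[c],
                  sizes[c]))
  }
  if (x$degenerate)
    cat("  note: contains a promoted leader (tied distances)\n")
  invisible(x)
}
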