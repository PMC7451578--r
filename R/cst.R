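#' Count clustered and spanning triples of a binary topology
#'
#' A triple is a centre node together with two of its neighbours.  It is
#' *clustered* when the two neighbours are themselves adjacent (each
#' triangle therefore contributes three clustered triples, one per
#' vertex), and *spanning* otherwise.  The total over all centres is
#' `sum(choose(degree, 2))`; triangles are counted through
#' `trace(B^3)/6`.
#'
#' @param topology Square symmetric 0/1 matrix with zero diagonal (any
#'   nonzero entry is treated as an edge).
#' @return List with integer fields `clustered`, `spanning`, `total`.
#' @examples
#' tri <- matrix(0, 3, 3); tri[cbind(c(1, 1, 2), c(2, 3, 3))] <- 1
#' tri <- tri + t(tri)
#' count_triples(tri)  # 3 clustered, 0 spanning
#' @export
count_triples <- function(topology) {
  B <- (as_weight_matrix(topology) != 0) * 1
  if (nrow(B) != ncol(B))
    stop("topology must be square", call. = FALSE)
  if (any(diag(B) != 0))
    stop("topology must have a zero diagonal", call. = FALSE)
  if (any(B != t(B)))
    stop("topology must be symmetric", call. = FALSE)
  deg <- rowSums(B)
  total <- sum(choose(deg, 2))
  b2 <- B %*% B
  clustered <- sum(b2 * B) / 2  # = 3 * n_triangles = trace(B^3)/2
  list(clustered = as.integer(round(clustered)),
       spanning = as.integer(round(total - clustered)),
       total = as.integer(round(total)))
}

#' Select the Cluster-Span Threshold of a weighted matrix
#'
#' The Cluster-Span Threshold (CST) is the edge-weight cutoff at which the
#' binarized topology balances clustered (closed) against spanning (open)
#' triples.  Candidate cutoffs are the sorted unique strictly positive
#' weights; for each, edges with weight `>= t` are kept, triples counted,
#' and candidates producing no connected triple at all are discarded (an
#' empty topology balances 0 = 0 vacuously and carries no information).
#' Exact equality of the two integer counts is rarely attainable, so the
#' returned threshold minimizes the normalized balance gap
#' `|clustered - spanning| / (clustered + spanning)`; ties go to the
#' smallest threshold, i.e. the densest admissible topology, which limits
#' disconnection ahead of the spectral embedding.  The gap is normalized
#' rather than taken on raw counts because every near-empty topology has
#' a raw imbalance of 0 or 1 (a lone open triple), which would
#' systematically draw the raw-count minimum away from the genuine
#' balance crossing toward almost-edgeless graphs.
#'
#' @param matrix Weighted symmetric matrix ([fc_matrix()] or plain).
#' @return Object of class `"cst"`: `threshold`, `counts` (triple counts
#'   at the threshold), `imbalance` (`|clustered - spanning|`),
#'   `balance_gap` (normalized imbalance in `[0, 1]`, the minimized
#'   quantity), `candidates_examined`.
#' @examples
#' w <- matrix(0, 4, 4)
#' w[1, 2] <- .9; w[1, 3] <- .8; w[2, 3] <- .7; w[3, 4] <- .5
#' w[1, 4] <- .3; w[2, 4] <- .2
#' w <- w + t(w)
#' cluster_span_threshold(w)$threshold  # 0.5
#' @export
cluster_span_threshold <- function(matrix) {
  W <- if (inherits(matrix, "fc_matrix")) as_weight_matrix(matrix)
       else fc_matrix_like(matrix)
  n <- nrow(W)
  if (n < 3L) stop("need at least 3 nodes", call. = FALSE)
  cand <- sort(unique(W[upper.tri(W)]))
  cand <- cand[cand > 0]
  if (length(cand) == 0L)
    stop("no strictly positive weight: cannot threshold", call. = FALSE)
  best <- NULL
  for (t in cand) {
    B <- (W >= t) * 1
    diag(B) <- 0
    ct <- count_triples(B)
    if (ct$total == 0L) next  # inadmissible: no triple information
    imb <- abs(ct$clustered - ct$spanning)
    gap <- imb / ct$total
    if (is.null(best) || gap < best$balance_gap) {
      best <- list(threshold = t, counts = ct, imbalance = imb,
                   balance_gap = gap)
    }
  }
  if (is.null(best))
    stop("degenerate topology: no candidate threshold yields any triple",
         call. = FALSE)
  best$candidates_examined <- length(cand)
  class(best) <- "cst"
  best
}

#' @export
print.cst <- function(x, ...) {
  cat(sprintf(paste0(
    "Cluster-Span Threshold: %.6g\n",
    "  triples at threshold: %d clustered / %d spanning",
    " (balance gap %.3f)\n",
    "  candidates examined:  %d\n"),
    x$threshold, x$counts$clustered, x$counts$spanning, x$balance_gap,
    x$candidates_examined))
  invisible(x)
}

#' Apply a weight threshold, keeping surviving weights
#'
#' Entries with weight `< t` are set to zero; surviving entries keep their
#' original (weighted) values -- the topology is thresholded, never
#' binarized.  Symmetry and the zero diagonal are preserved.
#'
#' @param matrix Weighted symmetric matrix.
#' @param t Threshold in weight units (edges with `w >= t` survive).
#' @return Plain numeric matrix with attribute `threshold`.
#' @export
apply_threshold <- function(matrix, t) {
  if (!is.finite(t)) stop("threshold must be finite", call. = FALSE)
  W <- if (inherits(matrix, "fc_matrix")) as_weight_matrix(matrix)
       else fc_matrix_like(matrix)
  W[W < t] <- 0
  diag(W) <- 0
  attr(W, "threshold") <- t
  attr(W, "subject_id") <- attr(matrix, "subject_id")
  W
}

# minimal structural check for plain-matrix entry points that do not need
# the full fc_matrix validation (keeps negative/asymmetric-noise handling
# in one place while letting already-validated matrices pass cheaply)
fc_matrix_like <- function(W) {
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W))
    stop("expected a square numeric matrix", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-8)
    stop("matrix is not symmetric", call. = FALSE)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}
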