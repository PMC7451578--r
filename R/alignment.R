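#' Alignment angle between two position vectors
#'
#' The eigenvector alignment (EA) angle is
#' `theta = acos(r . s / (|r| |s|))`, in radians in `[0, pi]`.  The cosine
#' is clamped to `[-1, 1]` before `acos`: floating-point dot products of
#' perfectly aligned vectors can exceed 1 by ~1e-16 and would otherwise
#' yield `NaN`.  Small angles mean strong alignment.
#'
#' @param r,s Position vectors of equal length, neither exactly zero.
#' @return Angle in radians.
#' @examples
#' alignment_angle(c(1, 0), c(0, 1))  # pi/2
#' @export
alignment_angle <- function(r, s) {
  if (length(r) != length(s))
    stop("position vectors must have equal length", call. = FALSE)
  nr <- sqrt(sum(r^2)); ns <- sqrt(sum(s^2))
  if (nr == 0 || ns == 0)
    stop("zero-length position vector: apply the zero-repair rule first",
         call. = FALSE)
  acos(min(1, max(-1, sum(r * s) / (nr * ns))))
}

#' All-pairs alignment angle matrix
#'
#' Computes the EA angle between every pair of node positions.  Symmetric
#' with an exactly zero diagonal.
#'
#' @param positions n x k matrix from [position_vectors()].
#' @return n x n matrix of angles in radians.
#' @export
alignment_matrix <- function(positions) {
  P <- unclass(positions)
  nr <- sqrt(rowSums(P^2))
  if (any(nr == 0))
    stop("zero-length position vector: apply the zero-repair rule first",
         call. = FALSE)
  C <- (P %*% t(P)) / outer(nr, nr)
  A <- matrix(acos(pmin(1, pmax(-1, C))), nrow(P), nrow(P))
  A <- (A + t(A)) / 2  # enforce exact symmetry against rounding
  diag(A) <- 0
  A
}

#' Group-level alignment summary
#'
#' Elementwise mean and standard deviation of per-subject angle matrices,
#' plus the per-ROI alignment-consistency statistic: for ROI `i`,
#' `sigma_i` is the standard deviation over `j != i` of the mean angles
#' `mean_angles[i, j]`.  A ROI with consistently tight (or consistently
#' loose) alignments has large sigma; one whose alignments hover uniformly
#' has small sigma, and such ROIs rarely convert connectivity change into
#' detectable alignment change.  The diagonal (self-alignment 0) is
#' excluded so it cannot deflate sigma.
#'
#' @param angles List of n x n per-subject angle matrices (same ROI
#'   ordering).
#' @return List of class `"ea_group_summary"`: `mean_angles`,
#'   `sd_angles`, `consistency` (length n), `n_subjects`.
#' @export
group_alignment_summary <- function(angles) {
  if (length(angles) < 1L)
    stop("need at least one subject", call. = FALSE)
  dims <- unique(lapply(angles, dim))
  if (length(dims) != 1L)
    stop("angle matrices must share dimensions", call. = FALSE)
  n <- dims[[1L]][1L]
  S <- length(angles)
  stack <- array(unlist(angles, use.names = FALSE), dim = c(n, n, S))
  m <- apply(stack, c(1L, 2L), mean)
  sdm <- if (S > 1L) apply(stack, c(1L, 2L), stats::sd)
         else matrix(0, n, n)
  consistency <- vapply(seq_len(n),
                        function(i) stats::sd(m[i, -i]), numeric(1))
  structure(list(mean_angles = m, sd_angles = sdm,
                 consistency = consistency, n_subjects = S),
            class = "ea_group_summary")
}

#' @export
print.ea_group_summary <- function(x, ...) {
  n <- nrow(x$mean_angles)
  off <- x$mean_angles[upper.tri(x$mean_angles)]
  cat(sprintf(paste0(
    "Group alignment summary: %d subjects, %d ROIs\n",
    "  mean angle (off-diagonal): %.3f rad [%.3f, %.3f]\n",
    "  per-ROI consistency sigma: %.3f [%.3f, %.3f]\n"),
    x$n_subjects, n, mean(off), min(off), max(off),
    mean(x$consistency), min(x$consistency), max(x$consistency)))
  invisible(x)
}
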