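# Seed discipline: every generator runs under a locally-set RNG state and
# restores the caller's state afterwards, so library code never perturbs a
# session's random stream.

snapshot_rng <- function() {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# deterministic derived seeds, kept within 32-bit integer range
derive_seeds <- function(seed, count) {
  as.integer((as.double(seed) * 48271 + 7919 * seq_len(count)) %%
               2147483647)
}

#' Random uniform connectivity matrix
#'
#' Symmetric matrix with iid uniform(0, 1) strictly-upper entries mirrored
#' below and a zero diagonal: the random functional-connectivity model the
#' significance filter compares against.
#'
#' @param n Node count (>= 3).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An [fc_matrix()].
#' @export
random_uniform_matrix <- function(n, seed = NULL) {
  if (n < 3L) stop("n must be at least 3", call. = FALSE)
  if (!is.null(seed)) {
    restore <- snapshot_rng()
    on.exit(restore())
    set.seed(as.integer(seed))
  }
  fc_matrix(sym_uniform(n), subject_id = sprintf("null_n%d", n))
}

#' Specify a synthetic cohort
#'
#' Describes the structured matrices the generator emulates: a two-level
#' community structure (within-block coupling `mu_in`, baseline
#' between-block coupling `mu_out`), strongly coupled homotopic
#' (bilateral) ROI pairs at weight `rho`, a disease-like degradation
#' `delta` that multiplies the homotopic couplings by `1 - delta`, and
#' iid Gaussian edge noise per subject.  Pair-level base couplings are
#' themselves Gaussian draws around the block means (SD `base_sd`),
#' frozen by `template_seed`: real Fisher-z matrices have a continuous
#' spread of couplings, and a weight continuum is what lets the
#' Cluster-Span Threshold find a genuine balance crossing.  The template
#' seed is deliberately *separate* from the subject seed and shared
#' between cohorts by default -- two compared cohorts represent the same
#' anatomy with different subjects and disease state.
#'
#' The defaults describe the desk-scale study conditions used throughout
#' the package's tests: 20 ROIs in two bilateral functional systems, 10
#' subjects, 10 homotopic pairs `(i, i+10)`, strong healthy homotopic
#' coupling `rho = 0.8` over a moderate continuum background
#' (`mu_in = 0.35` / `mu_out = 0.25`, pair-level spread 0.10) and
#' subject noise SD 0.1, all on the Fisher-z scale.  Under these
#' conditions the Cluster-Span Threshold lands around 0.27-0.34 and the
#' thresholded subjects stay connected, and a homotopic pair's tightness
#' is carried by its own strong edge, so degrading that edge loosens the
#' pair -- the behaviour group comparisons are meant to recover.
#'
#' @param n_roi Number of ROIs.
#' @param n_subjects Subjects per cohort.
#' @param homotopic_pairs Two-column integer matrix of disjoint ROI
#'   pairs.
#' @param rho Healthy homotopic coupling (weight units).
#' @param blocks List of integer vectors partitioning (a subset of) the
#'   ROIs into communities.  The default builds two *bilateral*
#'   functional systems, each spanning both hemispheres, so homotopic
#'   partners share a block -- with purely hemispheric blocks the block
#'   pull dominates the homotopic edge and homotopic pairs are never
#'   tight, unlike real data.
#' @param mu_in,mu_out Within-/between-block mean couplings, `mu_in >
#'   mu_out >= 0`.
#' @param base_sd Pair-level spread of the base couplings.
#' @param delta Fractional homotopic degradation in `[0, 1]`.
#' @param degraded_pairs Integer indices (rows of `homotopic_pairs`)
#'   whose couplings `delta` degrades; `NULL` (default) degrades all of
#'   them.  A proper subset leaves the remaining homotopic pairs as
#'   intact within-cohort controls.
#' @param noise_sd Per-subject Gaussian edge-noise SD (weight units).
#' @param seed Integer seed for the subject draws.
#' @param template_seed Integer seed freezing the pair-level base
#'   couplings (shared across cohorts by default).
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_roi = 20L, n_subjects = 10L,
                        homotopic_pairs =
                          cbind(seq_len(n_roi %/% 2),
                                seq_len(n_roi %/% 2) + n_roi %/% 2),
                        rho = 0.8,
                        blocks = bilateral_blocks(n_roi),
                        mu_in = 0.35, mu_out = 0.25, base_sd = 0.10,
                        delta = 0, degraded_pairs = NULL,
                        noise_sd = 0.1, seed = 1L,
                        template_seed = 20201L) {
  homotopic_pairs <- as.matrix(homotopic_pairs)
  if (delta < 0 || delta > 1)
    stop("delta must lie in [0, 1]", call. = FALSE)
  if (!(mu_in > mu_out && mu_out >= 0))
    stop("need mu_in > mu_out >= 0", call. = FALSE)
  if (anyDuplicated(as.vector(homotopic_pairs)))
    stop("homotopic pairs must be disjoint", call. = FALSE)
  if (any(homotopic_pairs < 1L | homotopic_pairs > n_roi))
    stop("homotopic pair index out of range", call. = FALSE)
  if (is.null(degraded_pairs))
    degraded_pairs <- seq_len(nrow(homotopic_pairs))
  degraded_pairs <- as.integer(degraded_pairs)
  if (any(degraded_pairs < 1L | degraded_pairs > nrow(homotopic_pairs)))
    stop("degraded_pairs must index rows of homotopic_pairs",
         call. = FALSE)
  structure(list(n_roi = as.integer(n_roi),
                 n_subjects = as.integer(n_subjects),
                 homotopic_pairs = homotopic_pairs, rho = rho,
                 blocks = blocks, mu_in = mu_in, mu_out = mu_out,
                 base_sd = base_sd, delta = delta,
                 degraded_pairs = degraded_pairs, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 template_seed = as.integer(template_seed)),
            class = "cohort_spec")
}

# two functional systems, each with a left and a right half, so that
# homotopic partners (i, i + n/2) fall inside the same system
bilateral_blocks <- function(n_roi) {
  h <- n_roi %/% 2
  q <- max(1L, h %/% 2)
  list(c(seq_len(q), h + seq_len(q)),
       c(seq.int(q + 1L, h), h + seq.int(q + 1L, h)))
}

cohort_template <- function(spec) {
  n <- spec$n_roi
  M <- matrix(spec$mu_out, n, n)
  for (b in spec$blocks) M[b, b] <- spec$mu_in
  restore <- snapshot_rng()
  on.exit(restore())
  set.seed(spec$template_seed)
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  W[up] <- M[up] + stats::rnorm(sum(up), sd = spec$base_sd)
  W <- W + t(W)
  for (r in seq_len(nrow(spec$homotopic_pairs))) {
    i <- spec$homotopic_pairs[r, 1L]; j <- spec$homotopic_pairs[r, 2L]
    w <- if (r %in% spec$degraded_pairs)
      spec$rho * (1 - spec$delta) else spec$rho
    W[i, j] <- W[j, i] <- w
  }
  diag(W) <- 0
  W
}

#' Generate a synthetic subject cohort
#'
#' Builds the deterministic template from the spec (blocks, homotopic
#' couplings degraded by `1 - delta`) and adds, per subject, iid Gaussian
#' edge noise which is then symmetrized by averaging; weights are clipped
#' to `[-1, 1]` to stay in a Fisher-z-plausible range.  Bit-reproducible
#' from `(spec, spec$seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param label Group label (default `"synthetic"`).
#' @return A [subject_group()] of `spec$n_subjects` matrices.
#' @export
generate_cohort <- function(spec, label = "synthetic") {
  stopifnot(inherits(spec, "cohort_spec"))
  template <- cohort_template(spec)
  n <- spec$n_roi
  restore <- snapshot_rng()
  on.exit(restore())
  set.seed(spec$seed)
  mats <- lapply(seq_len(spec$n_subjects), function(s) {
    E <- matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
    W <- template + (E + t(E)) / 2
    W[W > 1] <- 1
    W[W < -1] <- -1
    diag(W) <- 0
    fc_matrix(W, subject_id = sprintf("%s_%02d", label, s))
  })
  subject_group(label, mats)
}

#' Four-node demonstration network
#'
#' A fixed weighted network on nodes A, B, C, D whose B-D edge weight is
#' the `boost` argument.  At the baseline `boost = 0.3`, node A is fully
#' aligned with D (angle 0) and B is orthogonal to both A and D; raising
#' the boost to 1 pulls B and D together (theta drops to about 0.92 rad)
#' while A, whose link is no longer D's dominant influence, loses its
#' perfect alignment (theta rises to about 0.94 rad).  These angles are
#' produced by embedding the unthresholded matrix on the three largest
#' algebraic eigenvalues with unit scaling -- see [toy_alignment()].
#'
#' @param boost B-D edge weight in `[0.3, 1]`.
#' @return An [fc_matrix()] with nodes ordered A, B, C, D.
#' @export
toy_network <- function(boost = 0.3) {
  if (boost < 0.3 || boost > 1)
    stop("boost must lie in [0.3, 1]", call. = FALSE)
  W <- matrix(0, 4, 4)
  W[1, 2] <- 0.3  # A-B
  W[1, 3] <- 0.5  # A-C
  W[1, 4] <- 1.0  # A-D
  W[2, 3] <- 0.2  # B-C
  W[3, 4] <- 0.5  # C-D
  W[2, 4] <- boost  # B-D
  fc_matrix(W + t(W), subject_id = sprintf("toy_boost_%g", boost))
}

#' Alignment angles of the demonstration network
#'
#' Embeds [toy_network()] without thresholding on the three largest
#' algebraic eigenvalues with unit-norm vectors and returns the all-pairs
#' angle matrix.  This is the convention under which the four-node demo
#' reproduces its reference angles; the full pipeline's defaults
#' (magnitude ordering, CDI scaling after CST) coincide with it on dense
#' positive connectivity matrices but not on tiny toys, where the most
#' negative eigenvalue can outrank a positive one in magnitude.
#'
#' @param boost B-D edge weight in `[0.3, 1]`.
#' @return 4 x 4 angle matrix (radians), dimnames A-D.
#' @export
toy_alignment <- function(boost = 0.3) {
  W <- toy_network(boost)
  emb <- dominant_eigenpairs(W, k = 3L, ordering = "algebraic")
  A <- alignment_matrix(position_vectors(emb))
  dimnames(A) <- list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  A
}
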