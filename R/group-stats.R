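# Vectorized Welch machinery: the same closed form drives the scalar
# test and the per-pair grids, where calling a model-fitting routine per
# ROI pair (thousands of pairs x thousands of null samples) would
# dominate runtime.

welch_core <- function(m1, v1, n1, m2, v2, n2) {
  se1 <- v1 / n1
  se2 <- v2 / n2
  t <- (m1 - m2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Welch's unequal-variance t test
#'
#' Two-sided two-sample t test with the Welch-Satterthwaite degrees of
#' freedom.  Used throughout the group comparisons precisely because the
#' compared samples have very different sizes (about 10 subjects against
#' hundreds or a thousand random-model values) and no variance equality
#' can be assumed.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @return List of class `"welch_test"`: `t`, `df`, `p`, `mean_diff`
#'   (`mean(a) - mean(b)`).
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5, 6))
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must be finite", call. = FALSE)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) {
    if (mean(a) == mean(b))
      return(structure(list(t = 0, df = length(a) + length(b) - 2,
                            p = 1, mean_diff = 0),
                       class = "welch_test"))
    stop("degenerate samples: both variances are zero", call. = FALSE)
  }
  res <- welch_core(mean(a), v1, length(a), mean(b), v2, length(b))
  res$mean_diff <- mean(a) - mean(b)
  class(res) <- "welch_test"
  res
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, p = %.4g (mean diff %.4f)\n",
              x$t, x$df, x$p, x$mean_diff))
  invisible(x)
}

# mean/variance of a stack of matrices along the 3rd dimension
stack_moments <- function(stack) {
  S <- dim(stack)[3L]
  m <- rowMeans(stack, dims = 2L)
  v <- rowSums((stack - as.vector(m))^2, dims = 2L) / (S - 1)
  list(mean = m, var = v, n = S)
}

# Welch grids: elementwise test of two stacks of angle/weight matrices
welch_grid <- function(stack1, stack2) {
  a <- stack_moments(stack1)
  b <- stack_moments(stack2)
  res <- welch_core(a$mean, a$var, a$n, b$mean, b$var, b$n)
  res$mean1 <- a$mean
  res$mean2 <- b$mean
  res
}

#' Random-model null alignment sets
#'
#' Generates `n_sets` independent sets of `R` connectivity matrices with
#' iid uniform(0, 1) off-diagonal weights and pushes each through exactly
#' the same pipeline as the subjects (CST -> embedding at the same
#' k/ordering/scaling -> all-pairs angles), retaining the per-pair angle
#' samples.  These are the reference distributions against which a group's
#' alignments must differ before any group-vs-group test is trusted.  A
#' random matrix failing CST admissibility is replaced by the next draw of
#' the stream (counted in `regenerated`); with dense uniform weights this
#' is essentially never needed.  Set `raw = TRUE` to embed the uniform
#' matrices without thresholding.
#'
#' @param n Node count (must match the subjects' ROI count).
#' @param R Matrices per set (1000 reproduces the full-scale filter; 200
#'   is the reduced fast mode).
#' @param n_sets Number of independent sets (default 3).
#' @param seed Integer seed; per-set streams are derived from it.
#' @param k,ordering,scaling,multiplier Embedding configuration, as in
#'   [eigenalign()].
#' @param raw If `TRUE`, skip CST on the null matrices.
#' @return List of class `"ea_null"`: one element per set, each an
#'   `n x n x R` array of angles; attributes record the provenance
#'   (seeds, R, config).
#' @export
random_model_null <- function(n, R = 1000L, n_sets = 3L, seed = 1L,
                              k = 3L, ordering = "algebraic",
                              scaling = "cdi", multiplier = 1,
                              raw = FALSE) {
  if (R < 2L) stop("R must be at least 2", call. = FALSE)
  set_seeds <- derive_seeds(seed, n_sets)
  regenerated <- 0L
  sets <- vector("list", n_sets)
  restore <- snapshot_rng()
  on.exit(restore())
  for (s in seq_len(n_sets)) {
    angles <- array(NA_real_, dim = c(n, n, R))
    set.seed(set_seeds[s])
    r <- 1L
    while (r <= R) {
      W <- sym_uniform(n)
      ang <- try(null_angles(W, k, ordering, scaling, multiplier, raw),
                 silent = TRUE)
      if (inherits(ang, "try-error")) {  # CST inadmissible: next draw
        regenerated <- regenerated + 1L
        next
      }
      angles[, , r] <- ang
      r <- r + 1L
    }
    sets[[s]] <- angles
  }
  structure(sets, class = "ea_null",
            seed = seed, set_seeds = set_seeds, R = R,
            k = k, ordering = ordering, scaling = scaling,
            multiplier = multiplier, raw = raw,
            regenerated = regenerated)
}

null_angles <- function(W, k, ordering, scaling, multiplier, raw) {
  Wt <- if (raw) W else
    apply_threshold(W, cluster_span_threshold(W)$threshold)
  emb <- suppressWarnings(dominant_eigenpairs(Wt, k = k,
                                              ordering = ordering))
  emb <- scale_embedding(emb, mode = scaling, multiplier = multiplier)
  alignment_matrix(position_vectors(emb))
}

sym_uniform <- function(n) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2)
  W + t(W)
}

#' Random-model eligibility mask
#'
#' A ROI pair is eligible for the group-vs-group comparison when, within
#' every null set, its subject-level angles differ significantly (Welch
#' `p <= alpha`) from the null angle sample for *either* of the two
#' compared groups.  Requiring consistency across all (by default three)
#' independent null sets screens out pairs whose apparent signal is an
#' artefact of one particular random draw.
#'
#' @param angles1,angles2 `n x n x S` angle stacks for the two groups
#'   (from [stack_angles()] or [analyze_group()]).
#' @param nulls An [random_model_null()] object.
#' @param alpha Eligibility level (default 0.05).
#' @return Symmetric logical n x n matrix (diagonal `FALSE`) with the
#'   filter provenance in attributes.
#' @export
eligible_pairs <- function(angles1, angles2, nulls, alpha = 0.05) {
  if (length(nulls) < 1L)
    stop("need at least one null set", call. = FALSE)
  n <- dim(angles1)[1L]
  mask <- matrix(TRUE, n, n)
  for (s in seq_along(nulls)) {
    p1 <- welch_grid(angles1, nulls[[s]])$p
    p2 <- welch_grid(angles2, nulls[[s]])$p
    mask <- mask & (p1 <= alpha | p2 <= alpha)
  }
  diag(mask) <- FALSE
  mask <- mask & t(mask)
  structure(mask,
            n_sets = length(nulls), R = attr(nulls, "R"),
            alpha = alpha, seed = attr(nulls, "seed"))
}

new_comparison <- function(mode, grids, alpha, labels, extra = list()) {
  structure(c(list(mode = mode, alpha = alpha,
                   group1 = labels[1L], group2 = labels[2L]),
              grids, extra),
            class = "ea_comparison")
}

#' Compare eigenvector alignment between two groups
#'
#' Per eligible ROI pair, a two-sided Welch test of the subject-level
#' angles of group 1 against group 2.  The direction vocabulary follows
#' the alignment reading: a *decrease* in angle is an *increase* in
#' alignment, reported from group 1's perspective (direction
#' `"increase"` when the group-1 mean angle is smaller).  Per-ROI counts
#' of significant changes (row sums over significant pairs) give the
#' ranking statistic used to profile which regions realign most.  No
#' multiple-testing correction is applied; the random-model eligibility
#' filter is the false-detection control.
#'
#' @param angles1,angles2 `n x n x S` subject angle stacks.
#' @param mask Eligibility mask from [eligible_pairs()], or `NULL` to
#'   test every off-diagonal pair.
#' @param alpha Significance level (default 0.05).
#' @param labels Character vector of two group labels.
#' @return Object of class `"ea_comparison"` with grids `t`, `df`, `p`,
#'   `mean1`, `mean2`, `delta` (= mean1 - mean2), `direction`
#'   (`"increase"`/`"decrease"` in alignment), `eligible`, `tested`,
#'   `significant`, and `roi_counts`.
#' @export
compare_alignment <- function(angles1, angles2, mask = NULL,
                              alpha = 0.05,
                              labels = c("group1", "group2")) {
  n <- dim(angles1)[1L]
  if (dim(angles1)[3L] < 2L || dim(angles2)[3L] < 2L)
    stop("both groups need at least 2 subjects", call. = FALSE)
  if (is.null(mask)) {
    mask <- matrix(TRUE, n, n); diag(mask) <- FALSE
  }
  g <- welch_grid(angles1, angles2)
  tested <- mask
  direction <- matrix(NA_character_, n, n)
  direction[tested] <- ifelse(g$mean1[tested] < g$mean2[tested],
                              "increase", "decrease")
  significant <- tested & !is.na(g$p) & g$p <= alpha
  for (nm in c("t", "df", "p")) g[[nm]][!tested] <- NA_real_
  roi_counts <- as.integer(rowSums(significant))
  new_comparison("alignment",
                 list(t = g$t, df = g$df, p = g$p,
                      mean1 = g$mean1, mean2 = g$mean2,
                      delta = g$mean1 - g$mean2,
                      direction = direction, eligible = mask,
                      tested = tested, significant = significant,
                      roi_counts = roi_counts),
                 alpha, labels)
}

#' Compare eigenvector centrality between two groups
#'
#' Per-ROI two-sided Welch test of subject-level EC values.  Direction is
#' `"increase"` when group 1's mean EC exceeds group 2's.
#'
#' @param ec1,ec2 `n x S` matrices of per-subject EC vectors (columns =
#'   subjects).
#' @param alpha Significance level.
#' @param labels Group labels.
#' @return `"ea_comparison"` with per-ROI vectors `t`, `df`, `p`,
#'   `mean1`, `mean2`, `direction`, `significant`.
#' @export
compare_centrality <- function(ec1, ec2, alpha = 0.05,
                               labels = c("group1", "group2")) {
  if (ncol(ec1) < 2L || ncol(ec2) < 2L)
    stop("both groups need at least 2 subjects", call. = FALSE)
  m1 <- rowMeans(ec1); m2 <- rowMeans(ec2)
  v1 <- apply(ec1, 1L, stats::var); v2 <- apply(ec2, 1L, stats::var)
  res <- welch_core(m1, v1, ncol(ec1), m2, v2, ncol(ec2))
  significant <- !is.na(res$p) & res$p <= alpha
  new_comparison("centrality",
                 list(t = res$t, df = res$df, p = res$p,
                      mean1 = m1, mean2 = m2, delta = m1 - m2,
                      direction = ifelse(m1 > m2, "increase",
                                         "decrease"),
                      significant = significant),
                 alpha, labels)
}

#' Compare raw functional connectivity between two groups
#'
#' Per ROI pair, a two-sided Welch test on the *pre-threshold* edge
#' weights -- the classical pairwise FC comparison EA is contrasted with.
#' Per-ROI counts of significant FC changes are returned alongside.
#' Direction is `"increase"` when group 1's mean weight exceeds group
#' 2's.
#'
#' @param group1,group2 [subject_group()] objects (raw matrices).
#' @param alpha Significance level.
#' @return Pairwise `"ea_comparison"` with `roi_counts`.
#' @export
compare_connectivity <- function(group1, group2, alpha = 0.05) {
  s1 <- stack_weights(group1)
  s2 <- stack_weights(group2)
  if (dim(s1)[3L] < 2L || dim(s2)[3L] < 2L)
    stop("both groups need at least 2 subjects", call. = FALSE)
  n <- dim(s1)[1L]
  g <- welch_grid(s1, s2)
  tested <- matrix(TRUE, n, n); diag(tested) <- FALSE
  significant <- tested & !is.na(g$p) & g$p <= alpha
  for (nm in c("t", "df", "p")) g[[nm]][!tested] <- NA_real_
  direction <- matrix(NA_character_, n, n)
  direction[tested] <- ifelse(g$mean1[tested] > g$mean2[tested],
                              "increase", "decrease")
  new_comparison("connectivity",
                 list(t = g$t, df = g$df, p = g$p,
                      mean1 = g$mean1, mean2 = g$mean2,
                      delta = g$mean1 - g$mean2,
                      direction = direction, eligible = tested,
                      tested = tested, significant = significant,
                      roi_counts = as.integer(rowSums(significant))),
                 alpha, c(group1$label, group2$label))
}

#' Compare CDI community sizes between two groups
#'
#' Welch tests on four per-subject statistics of the ranked partitions:
#' size of the most influential community, size of the least influential,
#' and the mean sizes of the two most / two least influential.
#'
#' @param profiles1,profiles2 Lists of [community_size_profile()] results
#'   (one per subject).
#' @return Data frame with one row per statistic: means, `t`, `df`, `p`.
#' @export
compare_community_sizes <- function(profiles1, profiles2) {
  stats_names <- c("most", "least", "mean_two_most", "mean_two_least")
  rows <- lapply(stats_names, function(nm) {
    a <- vapply(profiles1, `[[`, numeric(1), nm)
    b <- vapply(profiles2, `[[`, numeric(1), nm)
    w <- welch_t_test(a, b)
    data.frame(statistic = nm, mean_group1 = mean(a),
               mean_group2 = mean(b), t = w$t, df = w$df, p = w$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Substitute one ROI's connectivity between paired subjects
#'
#' For each pairing `(host_m, donor_m)`, the host subject's row and
#' column for the given ROI are replaced by the donor subject's,
#' preserving symmetry and the zero diagonal.  Comparing the altered host
#' group against the original isolates how much of a region's group
#' difference is carried by its own connectivity profile as opposed to
#' network-wide change.
#'
#' @param host,donor [subject_group()] objects with a shared ROI
#'   ordering.
#' @param roi 1-based ROI index to transplant.
#' @param pairing Integer vector of host subject indices: position `m`
#'   pairs host subject `pairing[m]` with donor subject `m`.  Defaults to
#'   index order over `min(length(host), length(donor))` subjects.
#' @return A [subject_group()] of the altered hosts (size =
#'   `length(pairing)`), labelled `"<host>+roi<roi>"`.
#' @export
substitute_roi <- function(host, donor, roi,
                           pairing = seq_len(min(length(host),
                                                 length(donor)))) {
  n <- nrow(host$matrices[[1L]])
  if (nrow(donor$matrices[[1L]]) != n)
    stop("host and donor must share the ROI set", call. = FALSE)
  roi <- as.integer(roi)
  if (roi < 1L || roi > n)
    stop(sprintf("roi must be in 1..%d", n), call. = FALSE)
  if (length(pairing) > length(host) || length(pairing) > length(donor))
    stop("pairing longer than the smaller group", call. = FALSE)
  altered <- lapply(seq_along(pairing), function(m) {
    h <- as_weight_matrix(host$matrices[[pairing[m]]])
    d <- as_weight_matrix(donor$matrices[[m]])
    h[roi, ] <- d[roi, ]
    h[, roi] <- d[, roi]
    h[roi, roi] <- 0
    fc_matrix(h, subject_id = paste0(
      attr(host$matrices[[pairing[m]]], "subject_id"), "+roi", roi))
  })
  subject_group(paste0(host$label, "+roi", roi), altered)
}

#' Stack per-subject matrices into an array
#'
#' @param group A [subject_group()].
#' @return `n x n x S` numeric array of raw weights.
#' @export
stack_weights <- function(group) {
  n <- nrow(group$matrices[[1L]])
  array(unlist(lapply(group$matrices, as_weight_matrix),
               use.names = FALSE),
        dim = c(n, n, length(group$matrices)))
}

#' @export
print.ea_comparison <- function(x, ...) {
  cat(sprintf("Group comparison [%s]: %s vs %s (alpha = %g)\n",
              x$mode, x$group1, x$group2, x$alpha))
  if (is.matrix(x$significant)) {
    n_sig <- sum(x$significant[upper.tri(x$significant)])
    n_el <- sum(x$eligible[upper.tri(x$eligible)])
    cat(sprintf("  eligible pairs: %d, significant: %d\n", n_el, n_sig))
    if (n_sig > 0L) {
      top <- order(-x$roi_counts)[seq_len(min(5L, sum(x$roi_counts > 0)))]
      cat("  most affected ROIs (significant-pair counts):\n")
      for (i in top)
        cat(sprintf("    ROI %d: %d\n", i, x$roi_counts[i]))
    }
  } else {
    cat(sprintf("  significant ROIs: %d of %d\n",
                sum(x$significant), length(x$significant)))
  }
  invisible(x)
}

#' @export
summary.ea_comparison <- function(object, ...) {
  print(object)
  if (is.matrix(object$significant)) {
    idx <- which(object$significant & upper.tri(object$significant),
                 arr.ind = TRUE)
    if (nrow(idx)) {
      df <- data.frame(roi_i = idx[, 1L], roi_j = idx[, 2L],
                       p = object$p[idx],
                       direction = object$direction[idx])
      df <- df[order(df$p), , drop = FALSE]
      cat("\nSignificant pairs (by p):\n")
      print(utils::head(df, 20L), row.names = FALSE)
      invisible(df)
    }
  }
}
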