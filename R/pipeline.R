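#' Fit the eigenvector-alignment model to one subject
#'
#' Runs the full per-subject stack on a weighted connectivity matrix:
#' Cluster-Span Thresholding (or a fixed/absent threshold), dominant
#' eigenpair embedding, CDI-convention scaling, eigenvector centrality,
#' all-pairs alignment angles, and the communities of dynamical
#' influence.  This is the single entry point the group comparisons build
#' on.
#'
#' @param matrix Weighted symmetric matrix ([fc_matrix()] or plain
#'   numeric), Fisher-z correlation units.
#' @param k Number of dominant eigenvectors (2-5 sensible; default 3).
#' @param scaling `"cdi"` (default) or `"unit"`, see
#'   [scale_embedding()].
#' @param multiplier Positive v1 scale multiplier (CDI mode), default 1.
#' @param ordering Eigenvalue ordering: `"algebraic"` (default -- the k
#'   largest eigenvalues, the consensus-dynamics reading under which
#'   strongly coupled pairs align) or `"magnitude"` (largest `|lambda|`,
#'   which admits antisymmetric negative modes that anti-align the very
#'   pairs they join); see [dominant_eigenpairs()] and the methods
#'   vignette.
#' @param threshold `"cst"` (default), `"none"`, or a numeric cutoff in
#'   weight units.
#' @return Object of class `"eigenalign"`: the thresholding report
#'   (`cst`), thresholded `weights`, `embedding`, `positions`, `angles`,
#'   `ec`, ranked `partition`, `sizes` ([community_size_profile()]) and
#'   accumulated warning flags.
#' @examples
#' fit <- eigenalign(random_uniform_matrix(12, seed = 1))
#' fit
#' coef(fit)[1:3]
#' @export
eigenalign <- function(matrix, k = 3L,
                       scaling = c("cdi", "unit"), multiplier = 1,
                       ordering = c("algebraic", "magnitude"),
                       threshold = "cst") {
  scaling <- match.arg(scaling)
  ordering <- match.arg(ordering)
  m <- if (inherits(matrix, "fc_matrix")) matrix else fc_matrix(matrix)
  cst <- NULL
  if (identical(threshold, "cst")) {
    cst <- cluster_span_threshold(m)
    t_use <- cst$threshold
  } else if (identical(threshold, "none")) {
    t_use <- -Inf
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    t_use <- threshold
  } else stop("threshold must be \"cst\", \"none\" or a number",
              call. = FALSE)
  Wt <- if (is.finite(t_use)) apply_threshold(m, t_use)
        else as_weight_matrix(m)
  warn <- character(0)
  emb <- withCallingHandlers(
    dominant_eigenpairs(Wt, k = k, ordering = ordering),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  ec <- eigenvector_centrality(emb)
  emb <- scale_embedding(emb, mode = scaling, multiplier = multiplier)
  pos <- position_vectors(emb)
  angles <- alignment_matrix(pos)
  part <- withCallingHandlers(
    cdi_partition(pos, Wt, ec),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  structure(list(subject_id = attr(m, "subject_id"),
                 n = nrow(m), k = emb$k,
                 raw = m, cst = cst, threshold = t_use,
                 weights = Wt, embedding = emb, positions = pos,
                 angles = angles, ec = ec, partition = part,
                 sizes = community_size_profile(part),
                 scaling = scaling, multiplier = multiplier,
                 ordering = ordering, warnings = warn,
                 call = match.call()),
            class = "eigenalign")
}

#' @export
print.eigenalign <- function(x, ...) {
  cat(sprintf("Eigenvector alignment fit%s\n",
              if (!is.null(x$subject_id))
                paste0(" [", x$subject_id, "]") else ""))
  cat(sprintf("  %d ROIs, k = %d (%s ordering, %s scaling)\n",
              x$n, x$k, x$ordering, x$scaling))
  if (!is.null(x$cst))
    cat(sprintf("  CST threshold: %.4g (imbalance %d)\n",
                x$cst$threshold, x$cst$imbalance))
  cat(sprintf("  eigenvalues: %s\n",
              paste(formatC(x$embedding$values, digits = 4),
                    collapse = ", ")))
  cat(sprintf("  CDI: %d communities (most influential holds %d ROIs)\n",
              x$sizes$n_communities, x$sizes$most))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.eigenalign <- function(object, ...) {
  print(object)
  off <- object$angles[upper.tri(object$angles)]
  cat(sprintf("  angles: mean %.3f rad, range [%.3f, %.3f]\n",
              mean(off), min(off), max(off)))
  top <- order(-object$ec)[1:min(3L, object$n)]
  cat("  top-EC ROIs:",
      paste(sprintf("%d (%.3f)", top, object$ec[top]),
            collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.eigenalign <- function(object, ...) {
  stats::setNames(object$ec, seq_len(object$n))
}

#' Plot a fitted subject in the v2-v3 eigenvector plane
#'
#' Scatter of ROI positions along the 2nd and 3rd dominant eigenvectors,
#' coloured by CDI community (rank order), leaders emphasised.  This is
#' the standard view for inspecting community structure and alignment
#' geometry.
#'
#' @param x An [eigenalign()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.eigenalign <- function(x, ...) {
  P <- x$positions
  if (ncol(P) < 3L) stop("needs k >= 3 to plot the v2-v3 plane",
                         call. = FALSE)
  ranks <- x$partition$ranks[x$partition$membership]
  cols <- grDevices::hcl.colors(max(ranks), "Dark 3")[ranks]
  graphics::plot(P[, 2L], P[, 3L], col = cols, pch = 16,
                 xlab = expression(v[2]), ylab = expression(v[3]),
                 main = x$subject_id, ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 2)
  lead <- x$partition$leaders
  graphics::points(P[lead, 2L], P[lead, 3L], pch = 1, cex = 2.2,
                   lwd = 2, col = "black")
  invisible(x)
}

#' Fit every subject of a group
#'
#' Applies [eigenalign()] to each member and stacks the per-subject
#' outputs the group statistics consume.
#'
#' @param group A [subject_group()].
#' @param ... Configuration passed to [eigenalign()].
#' @return Object of class `"ea_group"`: `fits` (list), `angles`
#'   (`n x n x S` array), `ec` (`n x S`), `profiles` (community size
#'   profiles), `summary` ([group_alignment_summary()]), `label`.
#' @export
analyze_group <- function(group, ...) {
  stopifnot(inherits(group, "subject_group"))
  fits <- lapply(group$matrices, eigenalign, ...)
  n <- fits[[1L]]$n
  angles <- array(unlist(lapply(fits, `[[`, "angles"),
                         use.names = FALSE),
                  dim = c(n, n, length(fits)))
  ec <- vapply(fits, `[[`, numeric(n), "ec")
  structure(list(label = group$label, fits = fits, angles = angles,
                 ec = ec,
                 profiles = lapply(fits, `[[`, "sizes"),
                 summary = group_alignment_summary(
                   lapply(fits, `[[`, "angles"))),
            class = "ea_group")
}

#' @export
print.ea_group <- function(x, ...) {
  cat(sprintf("Analyzed group '%s': %d subjects, %d ROIs\n",
              x$label, length(x$fits), x$fits[[1L]]$n))
  ncom <- vapply(x$profiles, `[[`, numeric(1), "n_communities")
  cat(sprintf("  communities per subject: mean %.1f, range [%d, %d]\n",
              mean(ncom), min(ncom), max(ncom)))
  invisible(x)
}

#' Compare two subject groups end to end
#'
#' The orchestrated group comparison: fits every subject, builds the
#' random-model eligibility filter (for alignment mode), and runs the
#' requested Welch comparison.
#'
#' @param group1,group2 [subject_group()] objects sharing the ROI set.
#' @param mode `"alignment"` (random-model filtered EA test, the
#'   default), `"centrality"`, `"connectivity"` or `"communities"`.
#' @param alpha Significance level for the group test and the
#'   eligibility screen (default 0.05).
#' @param n_sets,null_size Random-model filter shape (default 3 sets of
#'   1000; 200 is the reduced fast mode).
#' @param seed Seed for the null-model streams.
#' @param k,scaling,multiplier,ordering,threshold Pipeline configuration,
#'   as in [eigenalign()].
#' @param null_raw If `TRUE` the null matrices skip CST.
#' @param filter Set `FALSE` to skip the random-model filter in
#'   alignment mode.
#' @return An `"ea_comparison"` (or the [compare_community_sizes()] data
#'   frame for `mode = "communities"`).
#' @export
compare_groups <- function(group1, group2,
                           mode = c("alignment", "centrality",
                                    "connectivity", "communities"),
                           alpha = 0.05, n_sets = 3L, null_size = 1000L,
                           seed = 1L, k = 3L, scaling = "cdi",
                           multiplier = 1, ordering = "algebraic",
                           threshold = "cst", null_raw = FALSE,
                           filter = TRUE) {
  mode <- match.arg(mode)
  if (mode == "connectivity")
    return(compare_connectivity(group1, group2, alpha = alpha))
  a1 <- analyze_group(group1, k = k, scaling = scaling,
                      multiplier = multiplier, ordering = ordering,
                      threshold = threshold)
  a2 <- analyze_group(group2, k = k, scaling = scaling,
                      multiplier = multiplier, ordering = ordering,
                      threshold = threshold)
  labels <- c(group1$label, group2$label)
  switch(mode,
    alignment = {
      mask <- NULL
      if (filter) {
        nulls <- random_model_null(
          n = dim(a1$angles)[1L], R = null_size, n_sets = n_sets,
          seed = seed, k = k, ordering = ordering, scaling = scaling,
          multiplier = multiplier, raw = null_raw)
        mask <- eligible_pairs(a1$angles, a2$angles, nulls,
                               alpha = alpha)
      }
      compare_alignment(a1$angles, a2$angles, mask = mask,
                        alpha = alpha, labels = labels)
    },
    centrality = compare_centrality(a1$ec, a2$ec, alpha = alpha,
                                    labels = labels),
    communities = compare_community_sizes(a1$profiles, a2$profiles))
}
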