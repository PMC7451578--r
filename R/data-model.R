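#' Validate and construct a functional-connectivity matrix
#'
#' A connectivity matrix holds one subject's ROI-to-ROI weighted functional
#' network: Fisher z-transformed correlation coefficients, which may be
#' negative before thresholding.  Validation enforces the structural
#' contract every downstream stage relies on: the matrix is square with at
#' least 3 ROIs, contains no `NA`/`NaN`/`Inf`, is symmetric (asymmetries up
#' to `1e-8` -- numerical noise from serialization -- are repaired by
#' averaging the matrix with its transpose; anything larger is treated as a
#' wrong file, not noise), and has an exactly zero diagonal
#' (self-correlation is uninformative and would distort triple counts and
#' eigenvectors).
#'
#' @param weights Square numeric matrix of edge weights.
#' @param subject_id Optional subject identifier, kept as an attribute.
#' @param roi_ids Optional integer vector of 1-based ROI ids matching the
#'   rows/columns; defaults to `1:n`.
#' @return A validated numeric matrix of class `"fc_matrix"` with
#'   attributes `subject_id` and `roi_ids`.
#' @examples
#' w <- matrix(c(0, .5, .2, .5, 0, .4, .2, .4, 0), 3, 3)
#' m <- fc_matrix(w, subject_id = "s1")
#' attr(m, "subject_id")
#' @export
fc_matrix <- function(weights, subject_id = NULL, roi_ids = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop(sprintf("connectivity matrix must be square, got %d x %d",
                 n, ncol(weights)), call. = FALSE)
  if (n < 3L)
    stop("connectivity matrix needs at least 3 ROIs", call. = FALSE)
  if (any(!is.finite(weights)))
    stop("connectivity matrix contains NA/NaN/Inf entries", call. = FALSE)
  asym <- abs(weights - t(weights))
  worst <- max(asym)
  if (worst > 1e-8) {
    idx <- which(asym == worst, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "matrix is not symmetric: |A[%d,%d] - A[%d,%d]| = %.3g exceeds 1e-8",
      idx[1L], idx[2L], idx[2L], idx[1L], worst), call. = FALSE)
  }
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  if (is.null(roi_ids)) roi_ids <- seq_len(n)
  roi_ids <- as.integer(roi_ids)
  if (length(roi_ids) != n)
    stop("`roi_ids` length must match matrix dimension", call. = FALSE)
  dimnames(w) <- NULL
  structure(w, class = c("fc_matrix", "matrix"),
            subject_id = subject_id, roi_ids = roi_ids)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("Functional connectivity matrix%s: %d x %d ROIs\n",
              if (!is.null(attr(x, "subject_id")))
                paste0(" [", attr(x, "subject_id"), "]") else "",
              nrow(x), ncol(x)))
  w <- x[upper.tri(x)]
  cat(sprintf("  weights: min %.3f, median %.3f, max %.3f\n",
              min(w), stats::median(w), max(w)))
  invisible(x)
}

# strip class/attributes, keeping a plain numeric matrix
as_weight_matrix <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Bundle subjects into a named group
#'
#' A subject group is an ordered list of validated connectivity matrices
#' sharing one ROI ordering, labelled e.g. `"HC"`, `"aMCI"` or `"AD"`.
#'
#' @param label Group label.
#' @param matrices List of matrices (each is passed through [fc_matrix()]
#'   if not already validated).
#' @return A list of class `"subject_group"` with elements `label` and
#'   `matrices`.
#' @export
subject_group <- function(label, matrices) {
  if (length(matrices) < 1L)
    stop("a subject group needs at least one member", call. = FALSE)
  matrices <- lapply(matrices, function(m)
    if (inherits(m, "fc_matrix")) m else fc_matrix(m))
  ns <- vapply(matrices, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all group members must share the same ROI set", call. = FALSE)
  ids <- lapply(matrices, attr, "roi_ids")
  if (length(unique(ids)) != 1L)
    stop("all group members must share the same ROI ordering", call. = FALSE)
  structure(list(label = label, matrices = matrices),
            class = "subject_group")
}

#' @export
print.subject_group <- function(x, ...) {
  cat(sprintf("Subject group '%s': %d subjects, %d ROIs\n",
              x$label, length(x$matrices), nrow(x$matrices[[1L]])))
  invisible(x)
}

#' @export
length.subject_group <- function(x) length(x$matrices)
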