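#' Read a connectivity matrix from a delimited text file
#'
#' Reads a dense square matrix of edge weights from whitespace-, comma- or
#' tab-delimited text (an optional header row of column names is detected
#' and skipped).  The parsed matrix is validated by [fc_matrix()]:
#' symmetrized by averaging when the asymmetry is at most `1e-8`, rejected
#' otherwise, diagonal forced to zero.
#'
#' @param path Path to the matrix file.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param format `"delimited"` (the canonical plain-text format).  A
#'   `"mat"` binary-container dialect is not supported: convert such files
#'   to delimited text first (e.g. one `writematrix`/`numpy.savetxt` call).
#' @return An [fc_matrix()].
#' @export
read_fc_matrix <- function(path, subject_id = NULL,
                           format = c("delimited", "mat")) {
  format <- match.arg(format)
  if (format == "mat")
    stop("MAT-container input is not supported; export the array to ",
         "delimited text and use format = \"delimited\"", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("matrix file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  dat <- utils::read.table(path, header = FALSE, sep = sep,
                           comment.char = "#", strip.white = TRUE,
                           colClasses = NA)
  # a non-numeric first row is a header; a non-numeric first column, names
  if (!all(vapply(dat, is.numeric, logical(1)))) {
    dat2 <- utils::read.table(path, header = TRUE, sep = sep,
                              comment.char = "#", strip.white = TRUE)
    if (!is.numeric(dat2[[1L]])) dat2[[1L]] <- NULL
    dat <- dat2
  }
  if (!all(vapply(dat, is.numeric, logical(1))))
    stop(sprintf("non-numeric entries in matrix file: %s", path),
         call. = FALSE)
  w <- as.matrix(dat)
  if (nrow(w) != ncol(w))
    stop(sprintf("matrix file %s is not square (%d x %d)",
                 path, nrow(w), ncol(w)), call. = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  fc_matrix(w, subject_id = subject_id)
}

#' Write a connectivity matrix as delimited text
#'
#' Inverse of [read_fc_matrix()]: writes the weights as a dense
#' tab-separated matrix at 12 significant digits, so a read/write/read
#' cycle is the identity on the decimal text.
#'
#' @param m Matrix (validated or plain numeric).
#' @param path Output path.
#' @export
write_fc_matrix <- function(m, path) {
  m <- if (inherits(m, "fc_matrix")) as_weight_matrix(m) else m
  txt <- apply(m, 1L, function(r)
    paste(formatC(r, digits = 12L, format = "g"), collapse = "\t"))
  writeLines(txt, path)
}

#' Read an ROI label table
#'
#' The table maps the 1-based ROI ids used in all user-facing output to
#' anatomical names (e.g. the 132 CONN-atlas regions).  Ids must be unique
#' and contiguous from 1 to n; names must be unique.
#'
#' @param path CSV/TSV file with columns id, name and optionally
#'   hemisphere.
#' @return A data frame with columns `roi_id`, `roi_name` and, when
#'   present in the file, `hemisphere`.
#' @export
read_roi_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("ROI table not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  has_header <- !grepl("^[0-9]", first)
  dat <- utils::read.table(path, header = has_header, sep = sep,
                           strip.white = TRUE, quote = "\"")
  if (ncol(dat) < 2L)
    stop("ROI table needs at least id and name columns", call. = FALSE)
  out <- data.frame(roi_id = as.integer(dat[[1L]]),
                    roi_name = as.character(dat[[2L]]),
                    stringsAsFactors = FALSE)
  if (ncol(dat) >= 3L) out$hemisphere <- as.character(dat[[3L]])
  if (anyDuplicated(out$roi_id))
    stop("duplicate ROI ids in table", call. = FALSE)
  if (anyDuplicated(out$roi_name))
    stop("duplicate ROI names in table", call. = FALSE)
  if (!identical(sort(out$roi_id), seq_len(nrow(out))))
    stop("ROI ids must be contiguous from 1 to n (gap or offset found)",
         call. = FALSE)
  out[order(out$roi_id), , drop = FALSE]
}

#' Read a group manifest and load its subjects
#'
#' The manifest is a CSV with columns `subject_id`, `group`, `path`
#' (matrix file locations, relative paths resolved against the manifest's
#' directory).  Returns one [subject_group()] per distinct group label, in
#' order of first appearance.
#'
#' @param path Manifest CSV.
#' @return Named list of [subject_group()] objects.
#' @export
read_group_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  dat <- utils::read.csv(path, strip.white = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(dat)))
    stop("manifest must have columns subject_id, group, path",
         call. = FALSE)
  base <- dirname(path)
  labels <- unique(dat$group)
  out <- lapply(labels, function(g) {
    rows <- dat[dat$group == g, , drop = FALSE]
    mats <- lapply(seq_len(nrow(rows)), function(i) {
      p <- rows$path[i]
      if (!file.exists(p)) p <- file.path(base, rows$path[i])
      read_fc_matrix(p, subject_id = rows$subject_id[i])
    })
    subject_group(g, mats)
  })
  names(out) <- labels
  out
}

#' Write pairwise comparison results as a long-format table
#'
#' Serializes a pairwise [compare_groups()] result to a tab-separated
#' table with one row per tested ROI pair (`i < j`, ascending), columns
#' `roi_i, roi_j, mean_angle_group1, mean_angle_group2, delta, t, df, p,
#' direction, passed_filter`.  Numeric values are written at 12
#' significant digits so a read-back reproduces them exactly at that
#' precision.
#'
#' @param result An object of class `"ea_comparison"` from
#'   [compare_alignment()] / [compare_connectivity()] (pairwise modes).
#' @param path Output TSV path.
#' @export
write_pair_results <- function(result, path) {
  df <- pair_results_table(result)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (cn in names(df)[num])
    df[[cn]] <- formatC(df[[cn]], digits = 12L, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Long-format table of per-pair test results
#'
#' @param result A pairwise `"ea_comparison"` object.
#' @return Data frame with one row per tested pair, `i < j` ascending.
#' @export
pair_results_table <- function(result) {
  stopifnot(inherits(result, "ea_comparison"))
  if (is.null(result$p) || !is.matrix(result$p))
    stop("result does not hold a pairwise grid", call. = FALSE)
  n <- nrow(result$p)
  idx <- which(upper.tri(result$p) & result$tested, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(
    roi_i = as.integer(idx[, 1L]),
    roi_j = as.integer(idx[, 2L]),
    mean_angle_group1 = result$mean1[idx],
    mean_angle_group2 = result$mean2[idx],
    delta = result$delta[idx],
    t = result$t[idx],
    df = result$df[idx],
    p = result$p[idx],
    direction = result$direction[idx],
    passed_filter = result$significant[idx],
    stringsAsFactors = FALSE)
}

#' Read back a pair-results table
#'
#' @param path TSV written by [write_pair_results()].
#' @return Data frame in the same column layout.
#' @export
read_pair_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
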