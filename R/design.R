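#' Remove all-zero samples and taxa from a count table
#'
#' Restricts a samples x taxa count table to rows with positive row sums and
#' columns with positive column sums, preserving order.
#'
#' @param counts Nonnegative integer matrix with unique row and column names.
#' @return The filtered count matrix.
#' @export
filter_zero <- function(counts) {
  check_count_table(counts)
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  out <- counts[keep_r, keep_c, drop = FALSE]
  if (nrow(out) == 0L || ncol(out) == 0L)
    stop("filtering removed every row or column")
  out
}

check_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("counts is empty")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("sample and taxon labels must be unique")
  invisible(counts)
}

#' Smoothed relative abundances
#'
#' Converts counts to proportions with a smoothing constant of 1:
#' `phi_ij = (t_ij + 1) / sum_j (t_ij + 1)`, so every row sums to exactly 1
#' and every entry lies strictly inside (0, 1).
#'
#' @param counts Filtered count matrix (see [filter_zero()]).
#' @return Real matrix of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  check_count_table(counts)
  sm <- counts + 1
  sm / rowSums(sm)
}

#' Select the reference taxon
#'
#' The reference is the taxon with the greatest total count across all
#' samples; ties are broken toward the smallest column index.
#'
#' @param counts Filtered count matrix.
#' @return The column label of the reference taxon (or its index when the
#'   matrix has no column names).
#' @export
select_reference <- function(counts) {
  check_count_table(counts)
  j <- which.max(colSums(counts))
  if (is.null(colnames(counts))) j else colnames(counts)[j]
}

#' Build the regression design matrix from a count table
#'
#' Composes [relative_abundance()], an optional elementwise natural log, and
#' removal of the reference taxon's column. The compositional sum-to-one
#' constraint makes one column redundant; dropping the most abundant taxon
#' (or a caller-specified reference) removes that redundancy.
#'
#' @param counts Filtered count matrix.
#' @param log_transform Apply the natural log to the relative abundances
#'   (default `TRUE`).
#' @param reference Optional column label (or index) to drop instead of the
#'   most abundant taxon.
#' @return An object of class `design_matrix`: a list with `x` (n x p real
#'   matrix, p = `ncol(counts) - 1`), `reference_id`, and `log_transformed`.
#' @examples
#' tab <- generate_counts(preset_profile("fungal-like"))
#' d <- build_design(filter_zero(tab))
#' dim(d$x)
#' @export
build_design <- function(counts, log_transform = TRUE, reference = NULL) {
  check_count_table(counts)
  phi <- relative_abundance(counts)
  ref <- if (is.null(reference)) select_reference(counts) else reference
  if (is.character(ref)) {
    if (!ref %in% colnames(counts)) stop("reference taxon not found: ", ref)
    ref_j <- match(ref, colnames(counts))
  } else {
    ref_j <- as.integer(ref)
    ref <- if (is.null(colnames(counts))) ref_j else colnames(counts)[ref_j]
  }
  x <- phi[, -ref_j, drop = FALSE]
  if (log_transform) x <- log(x)
  structure(list(x = x, reference_id = ref,
                 log_transformed = isTRUE(log_transform)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design matrix:", nrow(x$x), "samples x", ncol(x$x), "taxa",
      if (x$log_transformed) "(log relative abundances)" else
        "(relative abundances)",
      "\n  reference taxon dropped:", x$reference_id, "\n")
  invisible(x)
}

#' Write or read a design matrix with its reference metadata
#'
#' The matrix is stored tab-delimited (samples as rows) next to a JSON
#' sidecar `<file>.json` recording the reference taxon and transform flag.
#'
#' @param design A `design_matrix` from [build_design()].
#' @param file Path of the matrix file.
#' @return `read_design()` returns the `design_matrix`; `write_design()`
#'   returns `file` invisibly.
#' @export
write_design <- function(design, file) {
  df <- data.frame(sample_id = rownames(design$x), design$x,
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(reference_id = design$reference_id,
                            log_transformed = design$log_transformed),
                       paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_design
#' @export
read_design <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  structure(list(x = x, reference_id = meta$reference_id,
                 log_transformed = meta$log_transformed),
            class = "design_matrix")
}
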