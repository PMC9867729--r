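#' Construct a feature-by-cell count matrix
#'
#' The basic container for all single-table operations: a non-negative
#' feature-by-cell matrix together with unique feature and cell identifiers
#' and an optional per-cell batch label. Values need not be integers --
#' correspondence analysis is well defined for any non-negative table, so
#' e.g. logcounts are accepted.
#'
#' @param values Numeric matrix (features in rows, cells in columns) or a
#'   sparse \code{Matrix}; all entries must be finite and \eqn{\ge 0}.
#' @param feature_ids Character vector of unique row identifiers; defaults to
#'   \code{rownames(values)}.
#' @param cell_ids Character vector of unique column identifiers; defaults to
#'   \code{colnames(values)}.
#' @param batch Optional per-cell batch label (length \code{ncol(values)}).
#'
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{values} (dense base matrix with dimnames), and \code{batch}
#'   (factor or \code{NULL}).
#' @export
count_matrix <- function(values, feature_ids = NULL, cell_ids = NULL,
                         batch = NULL) {
  if (methods::is(values, "Matrix")) {
    values <- as.matrix(values)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(feature_ids)) feature_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- colnames(values)
  if (is.null(feature_ids)) {
    feature_ids <- paste0("feature", seq_len(nrow(values)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- paste0("cell", seq_len(ncol(values)))
  }
  feature_ids <- as.character(feature_ids)
  cell_ids <- as.character(cell_ids)
  if (length(feature_ids) != nrow(values)) {
    stop("length of `feature_ids` must equal nrow(values)")
  }
  if (length(cell_ids) != ncol(values)) {
    stop("length of `cell_ids` must equal ncol(values)")
  }
  if (anyDuplicated(feature_ids)) stop("`feature_ids` must be unique")
  if (anyDuplicated(cell_ids)) stop("`cell_ids` must be unique")
  if (any(!is.finite(values))) stop("all values must be finite")
  if (any(values < 0)) stop("all values must be non-negative")
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("count matrix must have at least 2 features and 2 cells")
  }
  if (!is.null(batch)) {
    if (length(batch) != ncol(values)) {
      stop("`batch` must have one entry per cell")
    }
    batch <- factor(batch, levels = unique(as.character(batch)))
  }
  dimnames(values) <- list(feature_ids, cell_ids)
  structure(list(values = values, batch = batch), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d cells\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$batch)) {
    cat("batches:", paste(levels(x$batch), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
cell_ids <- function(x) colnames(x$values)

#' Drop all-zero rows and columns
#'
#' Rows (features) and columns (cells) whose sums are zero carry no weight
#' and make the residual transformations undefined (they divide by the
#' marginal proportions), so they are removed before weighting. A message
#' reports how many of each were dropped.
#'
#' @param counts A [count_matrix].
#' @return A [count_matrix] restricted to rows and columns with positive sum.
#' @export
drop_empty <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  rs <- rowSums(counts$values)
  cs <- colSums(counts$values)
  keep_r <- rs > 0
  keep_c <- cs > 0
  n_dropped_r <- sum(!keep_r)
  n_dropped_c <- sum(!keep_c)
  if (n_dropped_r == 0L && n_dropped_c == 0L) {
    return(counts)
  }
  message(sprintf("drop_empty: removed %d zero-sum feature(s) and %d zero-sum cell(s)",
                  n_dropped_r, n_dropped_c))
  if (sum(keep_r) < 2L || sum(keep_c) < 2L) {
    stop("degenerate table after filtering")
  }
  count_matrix(counts$values[keep_r, keep_c, drop = FALSE],
               batch = if (is.null(counts$batch)) NULL else
                 counts$batch[keep_c])
}

#' Select the most variable features
#'
#' Ranks features by the variance of \code{log1p}-scaled counts and keeps the
#' top \code{k}. Used to bound the size of the dense residual matrix before
#' decomposition; mirrors the common practice of selecting on the order of
#' 1000--2000 highly variable genes.
#'
#' @param counts A [count_matrix].
#' @param k Number of features to keep; clipped to the number available.
#' @return A [count_matrix] with at most \code{k} features, original row
#'   order preserved.
#' @export
select_features <- function(counts, k) {
  stopifnot(inherits(counts, "count_matrix"), k >= 2)
  m <- nrow(counts$values)
  if (k >= m) return(counts)
  v <- apply(log1p(counts$values), 1L, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(k)])
  count_matrix(counts$values[keep, , drop = FALSE], batch = counts$batch)
}
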