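# atomic write: write to a temp file in the destination directory, then rename
with_atomic_file <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("failed to move temporary file to ", path)
  invisible(path)
}

#' Read a sparse count matrix in Matrix Market / 10x triplet layout
#'
#' Reads a MatrixMarket coordinate file (1-based indices on disk) together
#' with one-identifier-per-line features and barcodes files (first column
#' used if tab-delimited). Features are matrix rows by convention; use
#' \code{transpose = TRUE} for dialects storing cells as rows.
#'
#' @param matrix_path Path to the .mtx file.
#' @param features_path,barcodes_path Paths to the row / column identifier
#'   files.
#' @param transpose If TRUE, the on-disk matrix is cells-by-features and is
#'   transposed after reading (identifier files still refer to features and
#'   cells respectively).
#' @return A [count_matrix].
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path,
                            transpose = FALSE) {
  M <- Matrix::readMM(matrix_path)
  M <- methods::as(methods::as(M, "dMatrix"), "TsparseMatrix")
  if (length(M@i) > 0) {
    key <- paste(M@i, M@j)
    if (anyDuplicated(key)) {
      dup <- which(duplicated(key))[1L]
      stop(sprintf("duplicate coordinate in %s at entry %d (data line %d): (%d, %d)",
                   matrix_path, dup, dup + 2L, M@i[dup] + 1L, M@j[dup] + 1L))
    }
    if (any(M@x < 0)) {
      neg <- which(M@x < 0)[1L]
      stop(sprintf("negative value in %s at entry %d (data line %d)",
                   matrix_path, neg, neg + 2L))
    }
  }
  if (transpose) M <- Matrix::t(M)
  feats <- read_id_column(features_path)
  cells <- read_id_column(barcodes_path)
  if (length(feats) != nrow(M)) {
    stop(sprintf("features file has %d line(s) but matrix has %d row(s)",
                 length(feats), nrow(M)))
  }
  if (length(cells) != ncol(M)) {
    stop(sprintf("barcodes file has %d line(s) but matrix has %d column(s)",
                 length(cells), ncol(M)))
  }
  count_matrix(as.matrix(M), feature_ids = feats, cell_ids = cells)
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a count matrix in Matrix Market / 10x triplet layout
#'
#' Writes \code{matrix.mtx}, \code{features.tsv}, and \code{barcodes.tsv}
#' into \code{dir} (atomically: each file appears only once fully written).
#'
#' @param counts A [count_matrix].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths.
#' @export
write_counts_mtx <- function(counts, dir) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mpath <- file.path(dir, "matrix.mtx")
  fpath <- file.path(dir, "features.tsv")
  bpath <- file.path(dir, "barcodes.tsv")
  M <- methods::as(Matrix::Matrix(counts$values, sparse = TRUE),
                   "generalMatrix")
  with_atomic_file(mpath, function(tmp) Matrix::writeMM(M, tmp))
  with_atomic_file(fpath, function(tmp)
    writeLines(rownames(counts$values), tmp))
  with_atomic_file(bpath, function(tmp)
    writeLines(colnames(counts$values), tmp))
  invisible(c(matrix = mpath, features = fpath, barcodes = bpath))
}

#' Read a dense delimited count matrix
#'
#' Expects a header row of cell identifiers and a first column of feature
#' identifiers; the body must be numeric and non-negative. The delimiter is
#' inferred from the extension (.csv comma, otherwise tab) unless given.
#'
#' @param path Input file.
#' @param sep Field delimiter; default inferred.
#' @return A [count_matrix].
#' @export
read_counts_csv <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty count table in ", path)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("non-numeric values in count table ", path)
  if (any(M < 0)) stop("negative values in count table ", path)
  count_matrix(M)
}

#' Write a dense delimited count matrix
#'
#' @param counts A [count_matrix].
#' @param path Output file; delimiter inferred from extension as in
#'   [read_counts_csv()].
#' @param sep Field delimiter; default inferred.
#' @return Invisibly, \code{path}.
#' @export
write_counts_csv <- function(counts, path, sep = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  with_atomic_file(path, function(tmp) {
    df <- data.frame(feature_id = rownames(counts$values),
                     counts$values, check.names = FALSE)
    utils::write.table(df, tmp, sep = sep, quote = FALSE, row.names = FALSE)
  })
}

#' Write a cell embedding as delimited text
#'
#' First column \code{cell_id}, then \code{PC1..PCk}, plus a \code{batch}
#' column when batch labels are supplied.
#'
#' @param emb Numeric matrix, cells by components, rownames = cell ids.
#' @param path Output TSV path.
#' @param batch Optional per-cell batch labels.
#' @return Invisibly, \code{path}.
#' @export
write_embedding <- function(emb, path, batch = NULL) {
  emb <- as.matrix(emb)
  colnames(emb) <- paste0("PC", seq_len(ncol(emb)))
  df <- data.frame(cell_id = rownames(emb), emb, check.names = FALSE)
  if (!is.null(batch)) {
    stopifnot(length(batch) == nrow(emb))
    df$batch <- as.character(batch)
  }
  with_atomic_file(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path TSV file with a \code{cell_id} column, PC columns, and an
#'   optional \code{batch} column.
#' @return List with \code{emb} (matrix) and \code{batch} (or NULL).
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(df)) stop("embedding file lacks a cell_id column")
  batch <- if ("batch" %in% names(df)) df$batch else NULL
  pcs <- grep("^PC[0-9]+$", names(df), value = TRUE)
  emb <- as.matrix(df[, pcs, drop = FALSE])
  rownames(emb) <- df$cell_id
  list(emb = emb, batch = batch)
}

#' Write a scree table (component, singular value, percent inertia)
#'
#' @param result A \code{ca_result} or \code{corralm_result}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_scree <- function(result, path) {
  df <- data.frame(component = seq_along(result$d),
                   singular_value = result$d,
                   pct_inertia = result$pct_inertia)
  with_atomic_file(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}
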