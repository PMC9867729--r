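#' Subset a list of count tables to their shared features
#'
#' Takes the intersection of feature ids across all tables and restricts
#' each table to those features, reordered to one canonical (lexicographic)
#' shared order. A message reports the shared feature count and how many
#' features each table lost.
#'
#' @param tables List of [count_matrix] objects.
#' @return List of [count_matrix] objects over identical, identically
#'   ordered features.
#' @export
match_features <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  lapply(tables, function(t) stopifnot(inherits(t, "count_matrix")))
  shared <- Reduce(intersect, lapply(tables, function(t) rownames(t$values)))
  if (length(shared) < 2L) {
    stop("fewer than 2 features shared across tables; cannot integrate")
  }
  shared <- sort(shared)
  dropped <- vapply(tables, function(t) nrow(t$values) - length(shared),
                    integer(1))
  message(sprintf("match_features: %d shared feature(s); dropped per table: %s",
                  length(shared), paste(dropped, collapse = ", ")))
  lapply(tables, function(t) {
    count_matrix(t$values[shared, , drop = FALSE], batch = t$batch)
  })
}

#' Joint multi-table embedding across batches
#'
#' Embeds the cells of k count tables (e.g. sequencing batches) in one
#' shared latent space: each table is independently transformed to residuals
#' (indexed by default, tempering per-table library-depth effects), the
#' residual matrices are concatenated along the shared features, and a
#' single truncated SVD of the concatenated matrix yields the joint
#' embedding. Because every table is scaled by its own weights, the
#' embedding is invariant to per-batch rescaling of sequencing depth; no
#' explicit batch-correction step is applied.
#'
#' @param tables List of [count_matrix] objects sharing a feature namespace,
#'   optionally named (names become batch labels; otherwise
#'   \code{batch1, batch2, ...}).
#' @param residual_kind \code{"indexed"} (default) or \code{"freeman_tukey"}.
#' @param n_components Number of joint components (default 30, capped).
#' @return Object of class \code{corralm_result}: \code{embedding} (cells x
#'   components, rows in input concatenation order), \code{batch_index},
#'   \code{shared_features}, \code{d}, \code{feature_coords},
#'   \code{pct_inertia}.
#' @export
corralm_fit <- function(tables, residual_kind = c("indexed", "freeman_tukey"),
                        n_components = 30) {
  residual_kind <- match.arg(residual_kind)
  stopifnot(is.list(tables), length(tables) >= 1L)
  batch_names <- names(tables)
  if (is.null(batch_names) || any(batch_names == "")) {
    batch_names <- paste0("batch", seq_along(tables))
  }
  if (anyDuplicated(batch_names)) stop("batch names must be unique")
  tables <- match_features(tables)
  res_fun <- switch(residual_kind,
    indexed = indexed_residuals,
    freeman_tukey = freeman_tukey_residuals
  )
  blocks <- vector("list", length(tables))
  for (b in seq_along(tables)) {
    tab <- tables[[b]]
    # prefix cell ids with the batch label to guarantee uniqueness
    colnames(tab$values) <- paste(batch_names[b], colnames(tab$values),
                                  sep = ".")
    blocks[[b]] <- tryCatch(res_fun(tab)$values, error = function(e) {
      stop("batch '", batch_names[b], "': ", conditionMessage(e))
    })
  }
  M_C <- do.call(cbind, blocks)
  res <- new_residual_matrix(M_C, residual_kind, "none", 1)
  k <- min(as.integer(n_components), nrow(M_C), ncol(M_C))
  fit <- svd_decompose(res, k)
  batch_index <- factor(rep(batch_names,
                            vapply(blocks, ncol, integer(1))),
                        levels = batch_names)
  structure(list(embedding = fit$V, batch_index = batch_index,
                 shared_features = rownames(M_C), d = fit$d,
                 feature_coords = fit$U, pct_inertia = fit$pct_inertia,
                 residual_kind = residual_kind),
            class = "corralm_result")
}

#' @export
print.corralm_result <- function(x, ...) {
  cat(sprintf(
    "corralm_result: %d cells in %d batch(es), %d shared features, %d component(s)\n",
    nrow(x$embedding), nlevels(x$batch_index), length(x$shared_features),
    length(x$d)))
  cat("residuals:", x$residual_kind, "\n")
  print(table(x$batch_index))
  invisible(x)
}
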