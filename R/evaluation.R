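#' Scaled variance of embedding components by batch
#'
#' For each batch b and component d, the scaled variance is
#' \deqn{SV_{b,d} = Var(E_{b,d}) / Var(E_d),}
#' the sample variance of the batch's coordinates on that component divided
#' by the sample variance of all cells on it (both with the n-1
#' denominator). Values near 1 for every batch indicate that each batch is
#' dispersed like the whole embedding -- a heuristic for batch integration.
#' The metric assumes batches share a similar composition of cell types; it
#' cannot flag compositional differences.
#'
#' @param emb Numeric matrix, cells by components.
#' @param batch Per-cell batch labels (length \code{nrow(emb)}); every batch
#'   must contain at least 2 cells.
#' @param components Component indices to evaluate (default: the first three
#'   available components).
#' @return Object of class \code{scaled_variance}: list with \code{SV}
#'   (batches x components matrix), \code{batches}, \code{components}.
#' @export
scaled_variance <- function(emb, batch, components = NULL) {
  emb <- as.matrix(emb)
  if (is.null(components)) components <- seq_len(min(3L, ncol(emb)))
  if (any(!is.finite(emb))) stop("embedding contains missing or non-finite values")
  if (length(batch) != nrow(emb)) stop("`batch` must have one label per cell")
  batch <- factor(batch)
  components <- as.integer(components)
  if (any(components < 1L) || any(components > ncol(emb))) {
    stop("`components` out of range")
  }
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    stop("batch(es) with fewer than 2 cells: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  SV <- matrix(NA_real_, nlevels(batch), length(components),
               dimnames = list(levels(batch), paste0("PC", components)))
  for (d in seq_along(components)) {
    v_all <- stats::var(emb[, components[d]])
    for (b in seq_len(nlevels(batch))) {
      SV[b, d] <- stats::var(emb[batch == levels(batch)[b], components[d]]) /
        v_all
    }
  }
  structure(list(SV = SV, batches = levels(batch), components = components),
            class = "scaled_variance")
}

#' @export
print.scaled_variance <- function(x, ...) {
  cat("scaled variance by batch and component:\n")
  print(round(x$SV, 4))
  invisible(x)
}

#' Long-format table of scaled variances
#'
#' @param x A \code{scaled_variance} object.
#' @param ... Unused.
#' @return data.frame with columns batch, component, SV.
#' @export
as.data.frame.scaled_variance <- function(x, ...) {
  data.frame(
    batch = rep(x$batches, times = length(x$components)),
    component = rep(x$components, each = length(x$batches)),
    SV = as.vector(x$SV),
    stringsAsFactors = FALSE
  )
}

#' Dot plot of scaled variances (requires ggplot2)
#'
#' @param x A \code{scaled_variance} object.
#' @return A ggplot object.
#' @export
plot_scaled_variance <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_scaled_variance requires ggplot2")
  }
  df <- as.data.frame(x)
  df$component <- factor(df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = component, y = SV, colour = batch)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "component", y = "scaled variance") +
    ggplot2::theme_minimal()
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie): 1 for identical
#' partitions up to relabeling, about 0 for random agreement, negative for
#' worse-than-chance. In the degenerate case where the maximum index equals
#' its expected value (e.g. both partitions are single clusters or both are
#' all singletons), the value returned is 1 when the partitions are
#' identical up to relabeling and 0 otherwise.
#'
#' @param labels_a,labels_b Two label vectors of equal length (>= 2).
#' @return A single number in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("partitions must have equal length")
  }
  if (length(labels_a) < 2L) stop("need at least 2 observations")
  a <- as.integer(factor(labels_a))
  b <- as.integer(factor(labels_b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps * max(1, max_index)) {
    # identical up to relabeling <=> contingency table is a permutation pattern
    identical_part <- nrow(tab) == ncol(tab) &&
      all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
    return(if (identical_part) 1 else 0)
  }
  mclust::adjustedRandIndex(a, b)
}

#' Deterministic k-means reference clustering of an embedding
#'
#' A seeded centroid-based clusterer used to evaluate embeddings in a
#' self-contained way (cluster recovery against known labels via
#' [adjusted_rand_index()]). Identical seed and input give identical
#' partitions.
#'
#' @param emb Numeric matrix, cells by components.
#' @param k Number of clusters (2 to n).
#' @param seed Integer RNG seed.
#' @return Integer vector of cluster assignments, length \code{nrow(emb)}.
#' @export
reference_cluster <- function(emb, k, seed = 1L) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  k <- as.integer(k)
  if (k > n) stop("k must not exceed the number of cells (", n, ")")
  if (k < 2L) stop("k must be at least 2")
  if (k == n) return(seq_len(n))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fit <- stats::kmeans(emb, centers = k, nstart = 10L, iter.max = 100L)
  as.integer(fit$cluster)
}
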