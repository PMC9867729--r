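#' Truncated SVD of a residual matrix
#'
#' Decomposes the residual matrix M as \eqn{M = U D V^T} with orthonormal
#' U, V and non-increasing singular values, keeping the leading
#' \code{n_components}. Exact dense SVD (LAPACK) is used when
#' \code{min(m, n) <= 100} or when most components are requested; otherwise
#' a deterministic randomized subspace-iteration solver computes the
#' truncated factorization and is checked against a relative tolerance of
#' 1e-10 on the singular values between sweeps.
#'
#' Sign ambiguity is resolved per component: each (U_k, V_k) pair is flipped
#' so that the entry of largest absolute value in U_k is positive (ties
#' broken by smallest row index), making repeated runs bit-identical.
#'
#' @param residuals A \code{ca_residuals} object (or plain numeric matrix).
#' @param n_components Number of components to keep (1 to \code{min(m, n)}).
#' @param method \code{"auto"} (default), \code{"dense"}, or
#'   \code{"truncated"} to force a solver.
#' @return An object of class \code{ca_result} with \code{U}, \code{d},
#'   \code{V}, \code{pct_inertia}, and provenance; coordinate scores are
#'   populated by [coordinate_scores()] or [ca_fit()].
#' @export
svd_decompose <- function(residuals, n_components,
                          method = c("auto", "dense", "truncated")) {
  method <- match.arg(method)
  if (inherits(residuals, "ca_residuals")) {
    M <- residuals$values
    prov <- list(residual_kind = residuals$residual_kind,
                 vst = residuals$vst, alpha = residuals$alpha)
  } else {
    M <- as.matrix(residuals)
    prov <- list(residual_kind = NA_character_, vst = "none", alpha = 1)
  }
  m <- nrow(M); n <- ncol(M)
  k <- as.integer(n_components)
  if (is.na(k) || k < 1L || k > min(m, n)) {
    stop("`n_components` must be between 1 and min(m, n) = ", min(m, n))
  }
  if (method == "auto") {
    method <- if (min(m, n) <= 100L || k > min(m, n) / 2) "dense" else "truncated"
  }
  if (method == "dense") {
    s <- svd(M, nu = k, nv = k)
    U <- s$u; V <- s$v; d <- s$d[seq_len(k)]
  } else {
    s <- .svd_subspace(M, k)
    U <- s$u; V <- s$v; d <- s$d
  }
  # percent inertia is relative to the computed components
  total_sq <- sum(d^2)
  # deterministic sign convention
  for (j in seq_len(k)) {
    i_max <- which.max(abs(U[, j]))[1L]
    if (U[i_max, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  rownames(U) <- rownames(M)
  rownames(V) <- colnames(M)
  colnames(U) <- colnames(V) <- paste0("PC", seq_len(k))
  pct <- if (total_sq > 0) 100 * d^2 / total_sq else rep(0, k)
  prov$n_components <- k
  structure(list(U = U, d = d, V = V,
                 row_sc = NULL, col_sc = NULL,
                 row_pc = NULL, col_pc = NULL,
                 pct_inertia = pct, weights = NULL,
                 provenance = prov),
            class = "ca_result")
}

# randomized subspace iteration with a deterministic start block;
# converges fast because residual spectra decay quickly
.svd_subspace <- function(M, k, tol = 1e-10, max_iter = 1000L, oversample = 20L) {
  m <- nrow(M); n <- ncol(M)
  p <- min(n, k + oversample)
  # deterministic Gaussian start: local RNG state, restored on exit
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(20240101L)
  Omega <- matrix(stats::rnorm(n * p), n, p)
  Q <- qr.Q(qr(M %*% Omega))
  d_prev <- NULL
  for (iter in seq_len(max_iter)) {
    Q <- qr.Q(qr(crossprod(M, Q)))    # n x p
    Q <- qr.Q(qr(M %*% Q))            # m x p
    B <- crossprod(Q, M)              # p x n
    sb <- svd(B, nu = k, nv = k)
    d <- sb$d[seq_len(k)]
    if (!is.null(d_prev)) {
      delta <- abs(d - d_prev)
      if (all(delta / pmax(abs(d_prev), 1e-12) < tol) || all(delta < tol)) {
        return(list(u = Q %*% sb$u, d = d, v = sb$v))
      }
    }
    d_prev <- d
  }
  stop("truncated SVD did not converge to relative tolerance 1e-10 in ",
       max_iter, " subspace iterations")
}

#' Standard and principal coordinate scores
#'
#' Standard coordinates divide the singular vectors row-wise by the square
#' roots of the corresponding weights: \code{row_sc[i, k] = U[i, k] /
#' sqrt(row_w[i])} and \code{col_sc[j, k] = V[j, k] / sqrt(col_w[j])}.
#' Principal coordinates additionally scale each component by its singular
#' value. With the square-root-weight convention the standard coordinates
#' have unit weighted variance per component, consistent with the
#' orthonormality of U and V.
#'
#' @param result A \code{ca_result} from [svd_decompose()].
#' @param weights The [compute_weights()] model of the same table.
#' @return The \code{ca_result} with \code{row_sc}, \code{col_sc},
#'   \code{row_pc}, \code{col_pc} populated.
#' @export
coordinate_scores <- function(result, weights) {
  stopifnot(inherits(result, "ca_result"), inherits(weights, "weight_model"))
  if (length(weights$row_w) != nrow(result$U) ||
      length(weights$col_w) != nrow(result$V)) {
    stop("weight vectors do not match the dimensions of the singular vectors")
  }
  result$row_sc <- result$U / sqrt(weights$row_w)
  result$col_sc <- result$V / sqrt(weights$col_w)
  result$row_pc <- sweep(result$row_sc, 2L, result$d, `*`)
  result$col_pc <- sweep(result$col_sc, 2L, result$d, `*`)
  result$weights <- weights
  result
}

#' Fit correspondence analysis on a single count table
#'
#' The full single-table pipeline: drop zero-margin rows/columns, optionally
#' variance-stabilize the counts, compute the chosen chi-squared residuals,
#' optionally apply power deflation, decompose by truncated SVD, and attach
#' coordinate scores. The variants are selected by \code{method}, \code{vst},
#' and \code{alpha}:
#' \itemize{
#'   \item standard CA: \code{method = "pearson"}, \code{vst = "none"},
#'     \code{alpha = 1}
#'   \item CA-FT: \code{method = "freeman_tukey"} (recommended default for
#'     overdispersed single-cell counts)
#'   \item VST variants: \code{method = "pearson"} with \code{vst} one of
#'     \code{"sqrt"}, \code{"anscombe"}, \code{"freeman_tukey_counts"}
#'   \item power deflation: \code{method = "pearson"}, \code{alpha = 0.9}
#' }
#'
#' @param counts A [count_matrix].
#' @param method Residual family: \code{"pearson"} or \code{"freeman_tukey"}.
#' @param vst Count transform applied before residuals (default none).
#' @param alpha Power-deflation exponent in (0, 1]; 1 disables it.
#' @param n_components Number of components (default 30, capped at
#'   \code{min(m, n)}).
#' @return A \code{ca_result} with singular vectors/values, coordinate
#'   scores, percent inertia, and the configuration in \code{$provenance}.
#' @export
ca_fit <- function(counts, method = c("pearson", "freeman_tukey"),
                   vst = c("none", "sqrt", "anscombe", "freeman_tukey_counts"),
                   alpha = 1, n_components = 30) {
  stopifnot(inherits(counts, "count_matrix"))
  method <- match.arg(method)
  vst <- match.arg(vst)
  counts <- drop_empty(counts)
  transformed <- if (vst == "none") counts else vst_transform(counts, vst)
  res <- switch(method,
    pearson = pearson_residuals(transformed, vst = vst),
    freeman_tukey = freeman_tukey_residuals(transformed, vst = vst)
  )
  res <- power_deflate(res, alpha)
  k <- min(as.integer(n_components), nrow(res$values), ncol(res$values))
  fit <- svd_decompose(res, k)
  fit <- coordinate_scores(fit, compute_weights(transformed))
  fit$batch <- counts$batch
  fit
}

#' @export
print.ca_result <- function(x, ...) {
  k <- length(x$d)
  cat(sprintf("ca_result: %d features x %d cells, %d component(s)\n",
              nrow(x$U), nrow(x$V), k))
  cat(sprintf("residuals: %s (vst=%s, alpha=%g)\n",
              x$provenance$residual_kind, x$provenance$vst,
              x$provenance$alpha))
  kk <- min(k, 5L)
  cat("singular values:", paste(signif(x$d[seq_len(kk)], 4), collapse = " "),
      if (k > kk) "...\n" else "\n")
  invisible(x)
}

#' Extract the cell embedding from a CA fit
#'
#' Returns the cell-side coordinates used for downstream clustering or
#' visualization: either the right singular vectors V (default) or the
#' principal coordinates.
#'
#' @param result A \code{ca_result}.
#' @param type \code{"singular_vectors"} or \code{"principal_coords"}.
#' @return Numeric matrix, cells by components, rownames = cell ids.
#' @export
ca_embedding <- function(result,
                         type = c("singular_vectors", "principal_coords")) {
  stopifnot(inherits(result, "ca_result"))
  type <- match.arg(type)
  if (type == "singular_vectors") result$V else {
    if (is.null(result$col_pc)) stop("principal coordinates not computed")
    result$col_pc
  }
}

#' Elbow-based component selection from a scree of singular values
#'
#' Finds the scree point with the largest perpendicular distance to the
#' straight line joining the first and last points of the scree plot
#' (component index against singular value). Endpoints are excluded; ties
#' go to the smallest index.
#'
#' @param d Non-increasing vector of singular values, length at least 3.
#' @return Integer index (1-based) of the elbow component.
#' @export
select_components_elbow <- function(d) {
  if (length(d) < 3L) stop("need at least 3 singular values for the elbow method")
  if (any(diff(d) > 1e-12)) stop("`d` must be non-increasing")
  n <- length(d)
  x1 <- 1; y1 <- d[1]; x2 <- n; y2 <- d[n]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  idx <- 2:(n - 1L)
  # perpendicular distance of (i, d_i) to the chord
  dist <- abs((y2 - y1) * idx - (x2 - x1) * d[idx] + x2 * y1 - y2 * x1) / len
  idx[which.max(dist)]
}

#' Prepare paired coordinates for a CA biplot
#'
#' Returns all cell coordinates in the first two components together with
#' the \code{k_features} features lying furthest from the origin (largest
#' L2 norm over components 1-2), so that genes driving the separation can
#' be plotted in the same space as the cells. Ties in norm are broken by
#' feature id (lexicographic).
#'
#' @param result A \code{ca_result} with at least 2 components.
#' @param k_features How many top features to return (clipped to m with a
#'   warning).
#' @param type \code{"principal_coords"} (default) or
#'   \code{"singular_vectors"}; recorded in the output.
#' @return List with \code{cells} (n x 2), \code{features} (k x 2, sorted by
#'   descending norm), and \code{coord_type}.
#' @export
biplot_prepare <- function(result, k_features = 20,
                           type = c("principal_coords", "singular_vectors")) {
  stopifnot(inherits(result, "ca_result"))
  type <- match.arg(type)
  if (length(result$d) < 2L) stop("biplot needs at least 2 components")
  if (type == "principal_coords") {
    if (is.null(result$row_pc)) stop("principal coordinates not computed")
    Fmat <- result$row_pc[, 1:2, drop = FALSE]
    Cmat <- result$col_pc[, 1:2, drop = FALSE]
  } else {
    Fmat <- result$U[, 1:2, drop = FALSE]
    Cmat <- result$V[, 1:2, drop = FALSE]
  }
  m <- nrow(Fmat)
  if (k_features > m) {
    warning("k_features exceeds number of features; returning all ", m)
    k_features <- m
  }
  norms <- sqrt(rowSums(Fmat^2))
  ord <- order(-norms, rownames(Fmat))
  top <- ord[seq_len(k_features)]
  list(cells = Cmat, features = Fmat[top, , drop = FALSE], coord_type = type)
}
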