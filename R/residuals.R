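#' Row, column, and cell weights of a count table
#'
#' Converts a count table X into the proportion table P = X/N (N the grand
#' total) and its marginals: row weights \eqn{p_{i.}} and column weights
#' \eqn{p_{.j}}. The product \eqn{p_{i.} p_{.j}} is the expected proportion
#' of cell (i, j) under row-column independence, the reference point for all
#' residual transformations.
#'
#' @param counts A [count_matrix] with no all-zero rows or columns (use
#'   [drop_empty()] first).
#' @return An object of class \code{weight_model}: list with \code{N},
#'   \code{P}, \code{row_w}, \code{col_w}.
#' @export
compute_weights <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  X <- counts$values
  rs <- rowSums(X)
  cs <- colSums(X)
  if (any(rs == 0)) {
    stop("all-zero rows: ", paste(rownames(X)[rs == 0], collapse = ", "),
         " (filter with drop_empty first)")
  }
  if (any(cs == 0)) {
    stop("all-zero columns: ", paste(colnames(X)[cs == 0], collapse = ", "),
         " (filter with drop_empty first)")
  }
  N <- sum(X)
  structure(list(N = N, P = X / N, row_w = rs / N, col_w = cs / N),
            class = "weight_model")
}

#' Variance-stabilizing count transformations
#'
#' Element-wise square-root family transforms applied to the counts before
#' the residual step, to temper overdispersion in Poisson-like data:
#' \describe{
#'   \item{sqrt}{\eqn{x^* = \sqrt{x}}}
#'   \item{anscombe}{\eqn{x^* = 2\sqrt{x + 3/8}}}
#'   \item{freeman_tukey_counts}{\eqn{x^* = \sqrt{x} + \sqrt{x + 1}}}
#' }
#'
#' @param counts A [count_matrix]; non-integer values are accepted.
#' @param mode One of \code{"sqrt"}, \code{"anscombe"},
#'   \code{"freeman_tukey_counts"}.
#' @return A [count_matrix] of transformed values with identifiers preserved.
#' @export
vst_transform <- function(counts,
                          mode = c("sqrt", "anscombe", "freeman_tukey_counts")) {
  stopifnot(inherits(counts, "count_matrix"))
  mode <- match.arg(mode)
  X <- counts$values
  Xs <- switch(mode,
    sqrt = sqrt(X),
    anscombe = 2 * sqrt(X + 3 / 8),
    freeman_tukey_counts = sqrt(X) + sqrt(X + 1)
  )
  count_matrix(Xs, batch = counts$batch)
}

new_residual_matrix <- function(values, residual_kind, vst, alpha) {
  stopifnot(is.matrix(values))
  if (any(!is.finite(values))) stop("residual matrix contains non-finite values")
  structure(list(values = values, residual_kind = residual_kind,
                 vst = vst, alpha = alpha),
            class = "ca_residuals")
}

#' @export
print.ca_residuals <- function(x, ...) {
  cat(sprintf("ca_residuals: %d x %d, kind=%s, vst=%s, alpha=%g\n",
              nrow(x$values), ncol(x$values), x$residual_kind, x$vst, x$alpha))
  invisible(x)
}

# guard against vanishing expected proportions before dividing by them
check_expected <- function(E) {
  if (any(E < 1e-300)) {
    stop("expected proportions below 1e-300; table too extreme for residual scaling")
  }
  E
}

#' Pearson residuals of a count table
#'
#' The standardized residual \eqn{r_{p;ij} = (p_{ij} - p_{i.}p_{.j}) /
#' \sqrt{p_{i.}p_{.j}}}: the observed-minus-expected proportion scaled by the
#' square root of the expected proportion. The matrix of Pearson residuals
#' is exactly independence-centered, and its total inertia times N is the
#' Pearson chi-squared statistic of the table.
#'
#' @param counts A [count_matrix] with no zero margins.
#' @param vst Record of any count transform already applied (provenance only;
#'   no transform is applied here).
#' @return A \code{ca_residuals} object with \code{residual_kind = "pearson"}.
#' @export
pearson_residuals <- function(counts, vst = "none") {
  w <- compute_weights(counts)
  E <- check_expected(outer(w$row_w, w$col_w))
  R <- (w$P - E) / sqrt(E)
  dimnames(R) <- dimnames(counts$values)
  new_residual_matrix(R, "pearson", vst, 1)
}

#' Freeman-Tukey residuals of a count table
#'
#' The residual \eqn{r_{f;ij} = \sqrt{p_{ij}} + \sqrt{p_{ij} + 1/N} -
#' \sqrt{4 p_{i.}p_{.j} + 1/N}}, an alternative member of the chi-squared
#' family with variance-stabilizing behaviour for sparse, overdispersed
#' counts. As \eqn{N \to \infty} at fixed proportions each residual tends to
#' the Hellinger-type limit \eqn{2(\sqrt{p_{ij}} - \sqrt{p_{i.}p_{.j}})};
#' at finite N the matrix is not exactly independence-centered.
#'
#' @inheritParams pearson_residuals
#' @return A \code{ca_residuals} object with
#'   \code{residual_kind = "freeman_tukey"}.
#' @export
freeman_tukey_residuals <- function(counts, vst = "none") {
  w <- compute_weights(counts)
  E <- check_expected(outer(w$row_w, w$col_w))
  R <- sqrt(w$P) + sqrt(w$P + 1 / w$N) - sqrt(4 * E + 1 / w$N)
  dimnames(R) <- dimnames(counts$values)
  new_residual_matrix(R, "freeman_tukey", vst, 1)
}

#' Indexed residuals of a count table
#'
#' The residual \eqn{r_{ij} = (p_{ij} - p_{i.}p_{.j}) / (p_{i.}p_{.j})},
#' i.e. the Pearson residual divided by a further square root of the
#' expectation. It reads directly as a relative excess: r = 0.5 means the
#' observed value is 50% higher than expected. Down-weighting by the full
#' expectation tempers the influence of high-mass columns (deeply sequenced
#' cells), which is why this residual is the default for multi-batch joint
#' embedding.
#'
#' @inheritParams pearson_residuals
#' @return A \code{ca_residuals} object with \code{residual_kind = "indexed"}.
#' @export
indexed_residuals <- function(counts, vst = "none") {
  w <- compute_weights(counts)
  E <- check_expected(outer(w$row_w, w$col_w))
  R <- (w$P - E) / E
  dimnames(R) <- dimnames(counts$values)
  new_residual_matrix(R, "indexed", vst, 1)
}

#' Power deflation of a residual matrix
#'
#' Sign-preserving element-wise power \eqn{r^* = \mathrm{sgn}(r) |r|^\alpha}
#' with \eqn{\alpha \in (0, 1]}. Values of alpha slightly below 1 (the
#' recommended range is 0.9 to 0.99; the default elsewhere in this package
#' is 0.9) softly shrink outlying residuals while preserving sign, zeros,
#' and the ordering of magnitudes; alpha = 1 is the identity.
#'
#' @param residuals A \code{ca_residuals} object.
#' @param alpha Exponent in (0, 1].
#' @return A \code{ca_residuals} object with \code{alpha} recorded.
#' @export
power_deflate <- function(residuals, alpha) {
  stopifnot(inherits(residuals, "ca_residuals"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be a single value in (0, 1]")
  }
  if (alpha == 1) {
    residuals$alpha <- 1
    return(residuals)
  }
  R <- sign(residuals$values) * abs(residuals$values)^alpha
  out <- new_residual_matrix(R, residuals$residual_kind, residuals$vst, alpha)
  dimnames(out$values) <- dimnames(residuals$values)
  out
}
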