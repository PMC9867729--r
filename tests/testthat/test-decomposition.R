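test_that("svd_decompose handles null and hand-solvable cases", {
  z <- svd_decompose(matrix(0, 4, 3), 3)
  expect_equal(z$d, rep(0, 3))

  # the 2x2 Pearson residual of the diagonal table has spectrum (1, 0)
  r <- pearson_residuals(count_matrix(matrix(c(2, 0, 0, 2), 2)))
  s <- svd_decompose(r, 2)
  expect_equal(s$d, c(1, 0), tolerance = 1e-12)
  # the two cells separate with opposite signs on component 1
  expect_equal(sign(s$V[1, 1]) * sign(s$V[2, 1]), -1)

  expect_error(svd_decompose(matrix(1, 3, 3), 0), "n_components")
  expect_error(svd_decompose(matrix(1, 3, 3), 4), "n_components")
})

test_that("truncated and dense SVD agree with the full-SVD oracle", {
  set.seed(31)
  for (rep in 1:10) {
    m <- sample(8:12, 1); n <- sample(8:12, 1)
    M <- matrix(rnorm(m * n), m, n)
    k <- min(m, n)
    oracle <- svd(M)
    dense <- svd_decompose(M, k, method = "dense")
    expect_equal(dense$d, oracle$d[1:k], tolerance = 1e-10)
    # full-rank reconstruction
    recon <- dense$U %*% diag(dense$d) %*% t(dense$V)
    expect_equal(unname(recon), M, tolerance = 1e-10)
    # forced truncated solver matches the oracle on leading components
    k2 <- 3L
    trunc <- svd_decompose(M, k2, method = "truncated")
    expect_equal(trunc$d, oracle$d[1:k2], tolerance = 1e-8)
    expect_equal(unname(abs(trunc$U)), abs(oracle$u[, 1:k2]),
                 tolerance = 1e-6)
  }
})

test_that("sign convention makes repeated decompositions bit-identical", {
  set.seed(37)
  M <- matrix(rnorm(200), 10, 20)
  a <- svd_decompose(M, 5)
  b <- svd_decompose(M, 5)
  expect_identical(a$U, b$U)
  expect_identical(a$V, b$V)
  # the largest-magnitude entry of each U column is positive
  for (j in 1:5) expect_gt(a$U[which.max(abs(a$U[, j])), j], 0)
  # the truncated solver obeys the same convention
  tr1 <- svd_decompose(M, 4, method = "truncated")
  tr2 <- svd_decompose(M, 4, method = "truncated")
  expect_identical(tr1$U, tr2$U)
  for (j in 1:4) expect_gt(tr1$U[which.max(abs(tr1$U[, j])), j], 0)
})

test_that("Pearson spectra are canonical correlations and conserve inertia", {
  set.seed(41)
  for (rep in 1:5) {
    X <- random_table(6, 8)
    r <- pearson_residuals(count_matrix(X))
    s <- svd_decompose(r, 6)
    expect_true(all(s$d <= 1 + 1e-8))
    expect_true(all(diff(s$d) <= 1e-12))
    expect_equal(sum(s$d^2) * sum(X), chisq_oracle(X), tolerance = 1e-8)
    expect_lt(max(abs(crossprod(s$U) - diag(6))), 1e-8)
    expect_lt(max(abs(crossprod(s$V) - diag(6))), 1e-8)
  }
})

test_that("coordinate scores follow the (square-root) weight convention", {
  set.seed(43)
  cm <- random_count_matrix(6, 8)
  w <- compute_weights(cm)
  fit <- coordinate_scores(svd_decompose(pearson_residuals(cm), 5), w)
  expect_equal(fit$row_sc, fit$U / sqrt(w$row_w))
  expect_equal(fit$col_sc, fit$V / sqrt(w$col_w))
  expect_equal(fit$row_pc, sweep(fit$row_sc, 2, fit$d, `*`))
  expect_equal(fit$col_pc, sweep(fit$col_sc, 2, fit$d, `*`))
  # principal/standard ratio equals d_k wherever d_k > 0
  for (k in which(fit$d > 1e-10)) {
    expect_equal(fit$col_pc[, k] / fit$col_sc[, k],
                 rep(fit$d[k], nrow(fit$V)), ignore_attr = TRUE)
  }

  # uniform column weights 1/n: col_sc = sqrt(n) V
  u <- count_matrix(outer(runif(5, 1, 2), rep(1, 4)))
  wu <- compute_weights(u)
  fu <- coordinate_scores(svd_decompose(pearson_residuals(u), 3), wu)
  expect_equal(fu$col_sc, sqrt(4) * fu$V)

  # zero singular value -> zero principal coordinates
  r <- pearson_residuals(count_matrix(matrix(c(2, 0, 0, 2), 2)))
  f2 <- coordinate_scores(svd_decompose(r, 2),
                          compute_weights(count_matrix(matrix(c(2, 0, 0, 2), 2))))
  expect_equal(unname(f2$col_pc[, 2]), c(0, 0))

  expect_error(coordinate_scores(svd_decompose(matrix(rnorm(12), 3), 2), wu),
               "dimension|match")
})

test_that("ca_fit composes the pipeline exactly", {
  set.seed(47)
  cm <- random_count_matrix(8, 10)
  fit <- ca_fit(cm, method = "pearson", vst = "none", alpha = 1,
                n_components = 5)
  direct <- svd_decompose(pearson_residuals(cm), 5)
  expect_identical(fit$U, direct$U)
  expect_identical(fit$d, direct$d)
  expect_identical(fit$V, direct$V)
  expect_equal(fit$provenance,
               list(residual_kind = "pearson", vst = "none", alpha = 1,
                    n_components = 5L))

  # uniform table: no structure, all singular values 0
  fu <- ca_fit(count_matrix(matrix(1, 4, 4)), n_components = 3)
  expect_equal(fu$d, rep(0, 3), tolerance = 1e-12)

  # diagonal 2x2: leading singular value exactly 1, opposite cell signs
  f2 <- ca_fit(count_matrix(matrix(c(2, 0, 0, 2), 2)), n_components = 2)
  expect_equal(f2$d[1], 1, tolerance = 1e-12)
  expect_equal(sign(f2$V[1, 1]) * sign(f2$V[2, 1]), -1)

  # provenance records non-default configurations
  f3 <- ca_fit(cm, method = "freeman_tukey", alpha = 0.9, n_components = 4)
  expect_equal(f3$provenance$residual_kind, "freeman_tukey")
  expect_equal(f3$provenance$alpha, 0.9)
})

test_that("permuting cells permutes V and coordinates, leaving d unchanged", {
  set.seed(53)
  X <- random_table(6, 9)
  pc <- sample(9)
  f1 <- ca_fit(count_matrix(X), n_components = 5)
  f2 <- ca_fit(count_matrix(X[, pc]), n_components = 5)
  expect_equal(f1$d, f2$d, tolerance = 1e-10)
  expect_equal(unname(f2$V), unname(f1$V[pc, ]), tolerance = 1e-8)
  expect_equal(unname(f2$col_sc), unname(f1$col_sc[pc, ]), tolerance = 1e-8)
})

test_that("elbow selection maximizes perpendicular distance to the chord", {
  # brute-force oracle over interior points
  elbow_oracle <- function(d) {
    n <- length(d)
    p1 <- c(1, d[1]); p2 <- c(n, d[n])
    v <- p2 - p1
    dist <- sapply(2:(n - 1), function(i) {
      w <- c(i, d[i]) - p1
      abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
    })
    (2:(n - 1))[which.max(dist)]
  }
  d1 <- c(10, 2, 1.5, 1.4, 1.3)
  expect_equal(select_components_elbow(d1), 2)
  expect_equal(select_components_elbow(d1), elbow_oracle(d1))
  set.seed(59)
  for (rep in 1:10) {
    d <- sort(rexp(8, 0.5), decreasing = TRUE)
    expect_equal(select_components_elbow(d), elbow_oracle(d))
  }
  # documented tie-breaks
  expect_equal(select_components_elbow(c(4, 3, 2, 1)), 2)
  expect_equal(select_components_elbow(c(5, 5, 5)), 2)
  expect_error(select_components_elbow(c(2, 1)), "at least 3")
  expect_error(select_components_elbow(c(1, 2, 3)), "non-increasing")
})

test_that("biplot_prepare ranks features by distance from the origin", {
  fit <- list(
    d = c(2, 1),
    U = matrix(c(3, 1, 4, 0), 2, 2, dimnames = list(c("gB", "gA"), NULL)),
    V = matrix(rnorm(6), 3, 2, dimnames = list(paste0("c", 1:3), NULL)),
    row_pc = matrix(c(3, 1, 4, 0), 2, 2, dimnames = list(c("gB", "gA"), NULL)),
    col_pc = matrix(rnorm(6), 3, 2, dimnames = list(paste0("c", 1:3), NULL)),
    provenance = list()
  )
  class(fit) <- "ca_result"
  # norms: gB = 5, gA = 1
  bp <- biplot_prepare(fit, 1)
  expect_equal(rownames(bp$features), "gB")
  expect_equal(nrow(bp$cells), 3)
  expect_equal(bp$coord_type, "principal_coords")
  # k = m returns all features sorted by descending norm
  bp2 <- biplot_prepare(fit, 2)
  expect_equal(rownames(bp2$features), c("gB", "gA"))
  # ties broken lexicographically by feature id
  fit$row_pc <- matrix(c(0, 3, 5, 4), 2, 2,
                       dimnames = list(c("gZ", "gA"), NULL)) # both norm 5
  bp3 <- biplot_prepare(fit, 1)
  expect_equal(rownames(bp3$features), "gA")
  expect_warning(bp4 <- biplot_prepare(fit, 10), "exceeds")
  expect_equal(nrow(bp4$features), 2)
})

test_that("ca_embedding returns the requested cell coordinates", {
  set.seed(61)
  cm <- random_count_matrix(6, 8)
  fit <- ca_fit(cm, n_components = 4)
  expect_equal(ca_embedding(fit), fit$V)
  expect_equal(ca_embedding(fit, "principal_coords"), fit$col_pc)
})
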