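#' Configuration for the synthetic count generator
#'
#' Describes a multinomial / gamma-Poisson count model with cluster
#' structure, log-normal library sizes, optional overdispersion, and
#' multiplicative batch effects. The defaults describe a well-separated
#' three-population dataset of moderate size: 300 genes, 200 cells per
#' cluster, 10% of genes up-regulated 4-fold per cluster, mildly
#' overdispersed (gamma-Poisson dispersion 0.3) counts with log-normal
#' library sizes around 2500.
#'
#' @param m Number of genes.
#' @param n_per_cluster Cells per cluster (per batch).
#' @param k_clusters Number of cell clusters.
#' @param de_frac Fraction of genes differentially expressed per cluster.
#' @param de_fold Fold-change applied to a cluster's DE gene block.
#' @param libsize_log_mean,libsize_log_sd Parameters of the log-normal
#'   library-size distribution (natural-log scale).
#' @param dispersion Gamma-Poisson overdispersion; 0 gives pure multinomial
#'   sampling.
#' @param batches data.frame with columns \code{name},
#'   \code{libsize_multiplier}, \code{effect_fold}, \code{effect_frac}
#'   (multiplicative batch effect applied to a random gene subset); default
#'   a single neutral batch.
#' @param seed Integer seed; all draws are reproducible from it.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(m = 300, n_per_cluster = 200, k_clusters = 3,
                       de_frac = 0.1, de_fold = 4,
                       libsize_log_mean = log(2500), libsize_log_sd = 0.35,
                       dispersion = 0.3,
                       batches = data.frame(name = "batch1",
                                            libsize_multiplier = 1,
                                            effect_fold = 1,
                                            effect_frac = 0),
                       seed = 1L) {
  stopifnot(m >= 2, n_per_cluster >= 1, k_clusters >= 1,
            de_frac >= 0, de_frac <= 1, de_fold > 0,
            libsize_log_sd >= 0, dispersion >= 0,
            is.data.frame(batches), nrow(batches) >= 1)
  required <- c("name", "libsize_multiplier", "effect_fold", "effect_frac")
  if (!all(required %in% names(batches))) {
    stop("`batches` must have columns: ", paste(required, collapse = ", "))
  }
  structure(list(m = as.integer(m), n_per_cluster = as.integer(n_per_cluster),
                 k_clusters = as.integer(k_clusters), de_frac = de_frac,
                 de_fold = de_fold, libsize_log_mean = libsize_log_mean,
                 libsize_log_sd = libsize_log_sd, dispersion = dispersion,
                 batches = batches, seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-cluster gene expression profiles
#'
#' Draws a base gene-proportion vector from a log-normal and, for each
#' cluster, up-regulates a disjoint block of \code{de_frac * m} genes by
#' \code{de_fold}, renormalizing to a probability vector. When
#' \code{k_clusters * de_frac > 1} the blocks wrap around and overlap (with
#' a warning).
#'
#' @param config A [sim_config].
#' @return List with \code{profiles} (m x k matrix of column-stochastic
#'   proportions), \code{base} (the shared base proportions), and
#'   \code{de_genes} (list of DE gene index blocks per cluster).
#' @export
make_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  .make_profiles_impl(config)
}

.make_profiles_impl <- function(config) {
  m <- config$m
  base <- stats::rlnorm(m, meanlog = 0, sdlog = 1)
  base <- base / sum(base)
  n_de <- round(config$de_frac * m)
  if (config$k_clusters * n_de > m && n_de > 0) {
    warning("k_clusters * de_frac > 1; DE gene blocks overlap")
  }
  profiles <- matrix(base, m, config$k_clusters)
  de_genes <- vector("list", config$k_clusters)
  for (cl in seq_len(config$k_clusters)) {
    if (n_de == 0) { de_genes[[cl]] <- integer(0); next }
    idx <- (((cl - 1L) * n_de):((cl * n_de) - 1L)) %% m + 1L
    de_genes[[cl]] <- idx
    prof <- base
    prof[idx] <- prof[idx] * config$de_fold
    profiles[, cl] <- prof / sum(prof)
  }
  colnames(profiles) <- paste0("cluster", seq_len(config$k_clusters))
  rownames(profiles) <- paste0("gene", seq_len(m))
  list(profiles = profiles, base = base, de_genes = de_genes)
}

#' Sample a synthetic count matrix with known structure
#'
#' For every batch and cluster, draws \code{n_per_cluster} cells. Each
#' cell's library size is log-normal times the batch's library-size
#' multiplier; given dispersion 0 its counts are multinomial over the
#' cluster profile, otherwise gamma-Poisson: counts ~ Poisson(L * pi_g *
#' gamma) with per-gene, per-cell gamma multipliers of mean 1 and variance
#' \code{dispersion} (a negative-binomial marginal). A batch can also apply
#' a multiplicative \code{effect_fold} to a random \code{effect_frac}
#' fraction of genes (renormalized), emulating batch-specific capture
#' biases. All draws derive from \code{config$seed}; identical seeds give
#' byte-identical output.
#'
#' @param config A [sim_config].
#' @return List with \code{counts} (a [count_matrix] with batch labels),
#'   \code{cluster} (true cluster label per cell), \code{batch} (batch label
#'   per cell), and \code{profiles}.
#' @export
sample_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  prof <- .make_profiles_impl(config)
  m <- config$m
  n_b <- nrow(config$batches)
  n_cells <- config$n_per_cluster * config$k_clusters * n_b
  counts <- matrix(0, m, n_cells)
  cluster <- character(n_cells)
  batch <- character(n_cells)
  col <- 0L
  for (b in seq_len(n_b)) {
    brow <- config$batches[b, ]
    # batch effect: multiplicative fold on a random gene subset
    batch_mult <- rep(1, m)
    n_eff <- round(brow$effect_frac * m)
    if (n_eff > 0 && brow$effect_fold != 1) {
      batch_mult[sample.int(m, n_eff)] <- brow$effect_fold
    }
    for (cl in seq_len(config$k_clusters)) {
      pi_g <- prof$profiles[, cl] * batch_mult
      pi_g <- pi_g / sum(pi_g)
      for (cell in seq_len(config$n_per_cluster)) {
        col <- col + 1L
        L <- round(stats::rlnorm(1, config$libsize_log_mean,
                                 config$libsize_log_sd) *
                     brow$libsize_multiplier)
        L <- max(L, 1)
        if (config$dispersion == 0) {
          counts[, col] <- stats::rmultinom(1, size = L, prob = pi_g)
        } else {
          shape <- 1 / config$dispersion
          gam <- stats::rgamma(m, shape = shape, rate = shape)
          counts[, col] <- stats::rpois(m, lambda = L * pi_g * gam)
        }
        cluster[col] <- paste0("cluster", cl)
        batch[col] <- as.character(brow$name)
      }
    }
  }
  rownames(counts) <- paste0("gene", seq_len(m))
  colnames(counts) <- paste0("cell", seq_len(n_cells))
  cm <- count_matrix(counts, batch = batch)
  list(counts = cm, cluster = cluster, batch = batch,
       profiles = prof$profiles)
}
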