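#' Parameters for the zero-inflated expression simulator
#'
#' Defines the generating conditions for a synthetic log-scale expression
#' matrix with block cell-type structure and Bernoulli dropouts. Per-gene
#' means are drawn from Normal(\code{mean_loc}, \code{mean_scale}) and
#' per-gene standard deviations from Normal(\code{sd_loc}, \code{sd_scale});
#' each cell type gets \code{de_genes_per_type} differentially expressed
#' genes (disjoint across types) whose expression in their own type's cells
#' is scaled by a Uniform(\code{fold_low}, \code{fold_high}) fold change.
#' The fold acts on the count scale, so on the log scale (where the matrix
#' lives) the type-specific mean is \code{mu_g + log(u_g)}. Dropouts zero
#' each entry
#' of gene g independently with probability exp(-lambda * meanExp_g^2),
#' where meanExp_g is the gene's mean over all cells before dropout, so
#' lowly expressed genes drop out more often.
#'
#' @param n_genes number of genes (rows).
#' @param n_cells number of cells (columns).
#' @param n_types number of cell types; cells are split into equal blocks
#'   (remainder assigned to the last type).
#' @param de_genes_per_type differentially expressed genes per cell type,
#'   sampled without replacement across types (so exactly
#'   \code{n_types * de_genes_per_type} DE genes exist).
#' @param mean_loc,mean_scale location and scale of the Normal generating
#'   per-gene mean expression (log scale).
#' @param sd_loc,sd_scale location and scale of the Normal generating
#'   per-gene standard deviations; draws are clamped to >= 0.01.
#' @param fold_low,fold_high range of the uniform (count-scale) fold change
#'   applied to a DE gene's expression in its own cell type.
#' @param dropout_lambda non-negative decay rate lambda of the
#'   double-exponential dropout probability exp(-lambda * meanExp^2).
#' @param seed integer seed; every random draw flows from it in a fixed
#'   stream order (means, sds, DE selection, folds, entries, dropout mask).
#'
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_genes = 20000L, n_cells = 150L, n_types = 3L,
                              de_genes_per_type = 270L,
                              mean_loc = 1.8, mean_scale = 0.5,
                              sd_loc = 0.6, sd_scale = 0.1,
                              fold_low = 2, fold_high = 10,
                              dropout_lambda = 0.1, seed = 1L) {
  chk_count <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != as.integer(x)) {
      stop_config("invalid '", name, "': must be a positive integer")
    }
    as.integer(x)
  }
  chk_real <- function(x, name, positive = FALSE, nonneg = FALSE) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
      stop_config("invalid '", name, "': must be a finite number")
    }
    if (positive && x <= 0) stop_config("invalid '", name, "': must be > 0")
    if (nonneg && x < 0) stop_config("invalid '", name, "': must be >= 0")
    as.numeric(x)
  }
  cfg <- list(
    n_genes = chk_count(n_genes, "n_genes"),
    n_cells = chk_count(n_cells, "n_cells"),
    n_types = chk_count(n_types, "n_types"),
    de_genes_per_type = chk_count(de_genes_per_type, "de_genes_per_type"),
    mean_loc = chk_real(mean_loc, "mean_loc"),
    mean_scale = chk_real(mean_scale, "mean_scale", positive = TRUE),
    sd_loc = chk_real(sd_loc, "sd_loc"),
    sd_scale = chk_real(sd_scale, "sd_scale", positive = TRUE),
    fold_low = chk_real(fold_low, "fold_low", positive = TRUE),
    fold_high = chk_real(fold_high, "fold_high", positive = TRUE),
    dropout_lambda = chk_real(dropout_lambda, "dropout_lambda", nonneg = TRUE)
  )
  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed) ||
      seed != as.integer(seed)) {
    stop_config("invalid 'seed': must be an integer")
  }
  cfg$seed <- as.integer(seed)
  if (cfg$n_types * cfg$de_genes_per_type > cfg$n_genes) {
    stop_config("invalid 'de_genes_per_type': n_types * de_genes_per_type ",
                "exceeds n_genes")
  }
  if (cfg$fold_low > cfg$fold_high) {
    stop_config("invalid 'fold_low': must be <= fold_high")
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", x$n_genes, "genes x", x$n_cells, "cells,",
      x$n_types, "types,", x$de_genes_per_type, "DE genes/type, lambda =",
      x$dropout_lambda, ", seed =", x$seed, "\n")
  invisible(x)
}

# cell-type labels: equal blocks, remainder to the last type
type_labels <- function(n_cells, n_types) {
  block <- n_cells %/% n_types
  sizes <- rep(block, n_types)
  sizes[n_types] <- n_cells - block * (n_types - 1L)
  rep(seq_len(n_types), times = sizes)
}

#' Generate the "original" (pre-dropout) simulated dataset
#'
#' Draws a log-scale expression matrix with cell-type structure. Values are
#' already on log scale: each entry is Normal(type-specific mean, sd_g)
#' clamped at 0, no further log transform is applied downstream by the
#' simulator.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a list of class \code{simulated_dataset} with elements
#'   \code{original} (genes x cells matrix), \code{raw} (NULL here; see
#'   \code{\link{simulate_dataset}}), \code{labels} (integer cell-type
#'   vector named by cell), \code{de_gene_sets} (list of disjoint gene-ID
#'   character vectors, one per type) and \code{config}.
#' @export
simulate_original <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_config("'config' must be a simulation_config object")
  }
  set.seed(config$seed)
  ds <- simulate_original_impl(config)
  ds
}

# draws from the current RNG state, in the documented stream order
simulate_original_impl <- function(config) {
  m <- config$n_genes
  n <- config$n_cells
  t <- config$n_types
  d <- config$de_genes_per_type

  mu <- rnorm(m, config$mean_loc, config$mean_scale)          # 1. means
  sds <- pmax(rnorm(m, config$sd_loc, config$sd_scale), 0.01) # 2. sds
  de_idx <- sample.int(m, t * d)                              # 3. DE genes
  folds <- runif(t * d, config$fold_low, config$fold_high)    # 4. folds

  labels <- type_labels(n, t)
  gene_ids <- paste0("gene", seq_len(m))
  cell_ids <- paste0("cell", seq_len(n))

  # type-specific mean matrix: base mu everywhere; DE genes boosted in
  # their own type's cells by log(fold) (the fold multiplies count-scale
  # expression, the matrix is log scale)
  mean_mat <- matrix(mu, nrow = m, ncol = n)
  de_sets <- vector("list", t)
  for (ty in seq_len(t)) {
    g <- de_idx[((ty - 1L) * d + 1L):(ty * d)]
    f <- folds[((ty - 1L) * d + 1L):(ty * d)]
    mean_mat[g, labels == ty] <- mu[g] + log(f)
    de_sets[[ty]] <- gene_ids[sort(g)]
  }

  ent <- rnorm(m * n, mean = as.vector(mean_mat), sd = rep(sds, n)) # 5. entries
  original <- matrix(pmax(ent, 0), nrow = m, ncol = n,
                     dimnames = list(gene_ids, cell_ids))
  original <- set_scale(original, "lognormalized")

  names(labels) <- cell_ids
  structure(list(original = original, raw = NULL, labels = labels,
                 de_gene_sets = de_sets, config = config),
            class = "simulated_dataset")
}

#' Inject Bernoulli dropouts into an expression matrix
#'
#' Each entry of gene g is zeroed independently with probability
#' exp(-lambda * meanExp_g^2), where meanExp_g is the mean of gene g across
#' all cells of the input (pre-dropout) matrix. Dropout only zeroes values,
#' it never alters surviving entries.
#'
#' @param original non-negative genes x cells matrix.
#' @param dropout_lambda non-negative decay rate lambda.
#' @param seed optional integer seed; if NULL the current RNG state is used.
#' @return a matrix of the same shape with extra zeros.
#' @export
inject_dropouts <- function(original, dropout_lambda, seed = NULL) {
  original <- check_expression(original)
  if (length(dropout_lambda) != 1L || !is.finite(dropout_lambda) ||
      dropout_lambda < 0) {
    stop_config("invalid 'dropout_lambda': must be a non-negative number")
  }
  if (!is.null(seed)) set.seed(seed)
  p_drop <- exp(-dropout_lambda * rowMeans(original)^2)       # 6. dropout mask
  keep <- matrix(runif(length(original)) >= rep(p_drop, ncol(original)),
                 nrow = nrow(original))
  raw <- original * keep
  dimnames(raw) <- dimnames(original)
  raw
}

#' Generate a full simulated dataset (original + zero-inflated raw)
#'
#' Runs \code{\link{simulate_original}} and then injects dropouts with the
#' config's \code{dropout_lambda}, continuing the same random stream (the
#' dropout mask is the last block of draws from the seed).
#'
#' @inheritParams simulate_original
#' @return a \code{simulated_dataset} with the \code{raw} element filled.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_config("'config' must be a simulation_config object")
  }
  set.seed(config$seed)
  ds <- simulate_original_impl(config)
  ds$raw <- inject_dropouts(ds$original, config$dropout_lambda, seed = NULL)
  ds
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", nrow(x$original), "genes x", ncol(x$original),
      "cells,", x$config$n_types, "types;",
      if (is.null(x$raw)) "no dropouts injected" else
        sprintf("raw zero fraction %.3f", dropout_rate(x$raw)), "\n")
  invisible(x)
}

#' Fraction of zero entries in an expression matrix
#'
#' @param E a non-empty matrix.
#' @return the proportion of entries equal to zero, in [0, 1].
#' @export
dropout_rate <- function(E) {
  if (!is.matrix(E) || length(E) == 0L) {
    stop_data("dropout_rate requires a non-empty matrix")
  }
  mean(E == 0)
}
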