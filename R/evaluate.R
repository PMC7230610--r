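#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a true and a predicted partition of
#' the same objects, computed from the contingency table n_ij:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} -
#'   [\sum_i \binom{n_{i.}}{2} \sum_j \binom{n_{.j}}{2}] / \binom{n}{2}}
#'   {\frac{1}{2}[\sum_i \binom{n_{i.}}{2} + \sum_j \binom{n_{.j}}{2}] -
#'   [\sum_i \binom{n_{i.}}{2} \sum_j \binom{n_{.j}}{2}] / \binom{n}{2}}}
#' It equals 1 for identical partitions (up to label renaming), is about 0
#' for random agreement, and penalizes both false merges and false splits.
#' When the denominator is 0 (both partitions trivially agree with chance,
#' e.g. all objects in one block), 1 is returned if the partitions are
#' identical up to relabeling and 0 otherwise.
#'
#' @param truth,predicted equal-length label vectors (any categorical
#'   values; label names are irrelevant).
#' @return the ARI, a number <= 1.
#' @export
adjusted_rand_index <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_data("partitions have different lengths (", length(truth), " vs ",
              length(predicted), ")")
  }
  if (length(truth) == 0L) stop_data("empty partitions")
  n <- length(truth)
  tab <- table(truth, predicted)
  comb2 <- function(x) x * (x - 1) / 2
  index <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(colSums(tab)))
  expected <- a * b / comb2(n)
  maximum <- (a + b) / 2
  if (abs(maximum - expected) < .Machine$double.eps * max(1, maximum)) {
    # degenerate: agreement indistinguishable from chance by the formula
    return(as.numeric(index == maximum && a == b))
  }
  (index - expected) / (maximum - expected)
}

#' Cluster cells by PCA followed by k-means
#'
#' Projects cells (columns, treated as observations over gene features)
#' onto the top principal components, then runs k-means with many random
#' restarts. The same fixed number of components is used for every dataset
#' so clustering accuracy is comparable across imputation settings.
#'
#' @param E genes x cells matrix (typically log-normalized or imputed).
#' @param n_clusters number of clusters (given a priori).
#' @param n_components number of principal components (capped at
#'   min(genes, cells) - 1).
#' @param n_init number of k-means restarts with different centroid seeds.
#' @param max_iter maximum k-means iterations per restart.
#' @param seed integer seed making the k-means restarts reproducible.
#' @return an integer vector of cluster labels named by cell ID.
#' @export
pca_kmeans <- function(E, n_clusters, n_components = 20L, n_init = 100L,
                       max_iter = 1000L, seed = 1L) {
  E <- check_expression(E, allow_negative = TRUE)
  n <- ncol(E)
  if (length(n_clusters) != 1L || !is.finite(n_clusters) || n_clusters < 1) {
    stop_config("invalid 'n_clusters': must be a positive integer")
  }
  if (n_clusters > n) {
    stop_data("n_clusters (", n_clusters, ") exceeds the number of cells (",
              n, ")")
  }
  ncomp <- min(n_components, min(dim(E)) - 1L)
  ncomp <- max(ncomp, 1L)
  pcs <- prcomp(t(E), center = TRUE, scale. = FALSE, rank. = ncomp)$x
  set.seed(seed)
  if (n_clusters == 1L) {
    labels <- rep(1L, n)
  } else {
    km <- kmeans(pcs, centers = n_clusters, nstart = n_init,
                 iter.max = max_iter)
    labels <- km$cluster
  }
  names(labels) <- colnames(E)
  labels
}

#' Sweep restart probability and neighborhood size
#'
#' Runs the full imputation pipeline over a grid of (alpha, k), clusters
#' each imputed matrix with PCA+k-means, and scores it against the true
#' partition with the ARI. The default grids are alpha in 0.1..0.9 by 0.1
#' and k in powers of two from 8 up to 2^floor(log2(m/4)), m the
#' post-filter gene count. The raw-data baseline (same preprocessing and
#' clustering, no imputation) is computed once for reference.
#'
#' @param E_raw genes x cells matrix of non-negative values.
#' @param truth true cell partition (length = cells).
#' @param network \code{"gene"} or \code{"cell"}.
#' @param alphas,ks numeric grids; NULL uses the defaults above.
#' @param n_clusters number of clusters; default the number of distinct
#'   true labels.
#' @param input_scale \code{"counts"} or \code{"lognormalized"}; see
#'   \code{\link{netimpute}}. Also controls how the raw baseline matrix is
#'   prepared for clustering.
#' @param seed seed for the clustering restarts.
#' @param ... further arguments passed to \code{\link{netimpute}}.
#' @return a list with \code{sweep} (data.frame alpha, k, network, ari) and
#'   \code{baseline_ari}.
#' @export
parameter_sweep <- function(E_raw, truth, network = c("gene", "cell"),
                            alphas = NULL, ks = NULL, n_clusters = NULL,
                            input_scale = c("counts", "lognormalized"),
                            seed = 1L, ...) {
  network <- match.arg(network)
  input_scale <- match.arg(input_scale)
  E_raw <- check_expression(E_raw)
  if (length(truth) != ncol(E_raw)) {
    stop_data("'truth' must label every cell")
  }
  if (is.null(n_clusters)) n_clusters <- length(unique(truth))
  E_pre <- prepare_expression(E_raw, input_scale)
  m <- if (network == "gene") nrow(E_pre) else ncol(E_pre)
  if (is.null(alphas)) alphas <- seq(0.1, 0.9, by = 0.1)
  if (is.null(ks)) ks <- 2^(3:max(3L, floor(log2(m / 4))))
  ks <- ks[ks <= m - 1L]
  if (length(alphas) == 0L || length(ks) == 0L) {
    stop_config("invalid sweep grid: 'alphas' and 'ks' must be non-empty")
  }
  baseline <- adjusted_rand_index(
    truth, pca_kmeans(E_pre, n_clusters, seed = seed))
  grid <- expand.grid(alpha = alphas, k = ks)
  ari <- vapply(seq_len(nrow(grid)), function(r) {
    X <- netimpute(E_raw, network = network, k = grid$k[r],
                   alpha = grid$alpha[r], input_scale = input_scale, ...)
    adjusted_rand_index(truth, pca_kmeans(X, n_clusters, seed = seed))
  }, numeric(1))
  list(sweep = data.frame(alpha = grid$alpha, k = grid$k, network = network,
                          ari = ari),
       baseline_ari = baseline)
}

#' Degree versus mean imputed value ("hub effect") diagnostic
#'
#' For each gene, pairs its degree in the co-expression graph with its mean
#' imputed value across cells, and reports the Pearson correlation between
#' the two. Smoothing with incoming probabilities inflates high-degree
#' (hub) genes, showing up as a high correlation; outgoing-probability
#' smoothing keeps each gene's magnitude near its observed one, so the
#' correlation stays low. If the degrees (or the mean values) are constant
#' the correlation is reported as 0 by convention.
#'
#' @param A adjacency matrix whose node set equals the genes of
#'   \code{E_imputed}.
#' @param E_imputed imputed genes x cells matrix.
#' @return a list with \code{table} (data.frame gene, degree,
#'   mean_imputed) and \code{correlation}.
#' @export
hub_effect <- function(A, E_imputed) {
  E_imputed <- check_expression(E_imputed, allow_negative = TRUE)
  if (is.null(rownames(A)) || !identical(rownames(A), rownames(E_imputed))) {
    stop_data("graph node set does not match the genes of the imputed matrix")
  }
  degree <- Matrix::rowSums(A != 0)
  mean_imputed <- rowMeans(E_imputed)
  # constant degree or (numerically) constant values: no bias to report
  flat <- sd(degree) == 0 ||
    sd(mean_imputed) <= 1e-12 * max(1, mean(abs(mean_imputed)))
  correlation <- if (flat) 0 else cor(degree, mean_imputed)
  list(table = data.frame(gene = rownames(E_imputed),
                          degree = as.integer(degree),
                          mean_imputed = mean_imputed,
                          row.names = NULL),
       correlation = correlation)
}
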