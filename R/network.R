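#' Pairwise Pearson similarity between genes or cells
#'
#' Computes the p x p Pearson correlation matrix between rows (genes) or
#' columns (cells) of a log-normalized expression matrix. Zero-variance
#' vectors cannot be correlated; the corresponding nodes are flagged
#' isolated (attribute \code{"isolated"}, a logical vector) and their rows
#' and columns are set to NA. KNN graph construction excludes them from
#' neighborhoods, so they end up with no edges.
#'
#' @param E genes x cells matrix (log-normalized).
#' @param axis \code{"gene"} for gene-gene similarity (rows), \code{"cell"}
#'   for cell-cell similarity (columns).
#' @return a symmetric p x p matrix with unit diagonal for all non-isolated
#'   nodes, dimnames set to the node IDs, and attribute \code{"isolated"}.
#' @export
expression_similarity <- function(E, axis = c("gene", "cell")) {
  axis <- match.arg(axis)
  E <- check_expression(E, allow_negative = TRUE)
  X <- if (axis == "gene") t(E) else E          # observations in columns
  isolated <- apply(X, 2L, sd) == 0
  S <- suppressWarnings(cor(X))
  diag(S)[!isolated] <- 1
  S[isolated, ] <- NA_real_
  S[, isolated] <- NA_real_
  ids <- if (axis == "gene") rownames(E) else colnames(E)
  dimnames(S) <- list(ids, ids)
  names(isolated) <- ids
  attr(S, "isolated") <- isolated
  attr(S, "axis") <- axis
  S
}

# top-k neighbor indices per node from a similarity matrix.
# Self is always excluded; isolated nodes (flagged or NA similarity) are
# excluded as candidates and get empty neighborhoods. Ties are broken by
# ascending node index (order() is stable).
# Returns a p x k integer matrix padded with NA.
neighbors_from_similarity <- function(S, k) {
  p <- nrow(S)
  if (length(k) != 1L || !is.finite(k) || k < 1 || k > p - 1L) {
    stop_config("invalid 'k': must be in [1, ", p - 1L, "]")
  }
  k <- as.integer(k)
  isolated <- attr(S, "isolated")
  if (is.null(isolated)) isolated <- rep(FALSE, p)
  nn <- matrix(NA_integer_, nrow = p, ncol = k)
  for (i in seq_len(p)) {
    if (isolated[i]) next
    s <- S[i, ]
    s[i] <- NA_real_
    s[isolated] <- NA_real_
    cand <- which(!is.na(s))
    if (length(cand) == 0L) next
    ord <- cand[order(s[cand], decreasing = TRUE)]
    take <- head(ord, k)
    nn[i, seq_along(take)] <- take
  }
  nn
}

# build an undirected binary adjacency from a p x k neighbor-index matrix
graph_from_neighbors <- function(nn, node_ids, mutual = TRUE) {
  p <- nrow(nn)
  i <- rep(seq_len(p), times = ncol(nn))
  j <- as.vector(nn)
  ok <- !is.na(j)
  D <- Matrix::sparseMatrix(i = i[ok], j = j[ok], x = 1, dims = c(p, p),
                            dimnames = list(node_ids, node_ids))
  A <- if (mutual) Matrix::drop0(D * Matrix::t(D)) else D + Matrix::t(D)
  A@x[] <- 1
  Matrix::diag(A) <- 0
  Matrix::drop0(A)
}

#' Mutual k-nearest-neighbor co-expression graph
#'
#' Connects nodes i and j iff each is among the other's k most similar
#' nodes (excluding self). The AND condition keeps only high-confidence
#' links, giving a sparser, less noisy network than asymmetric KNN; every
#' node's degree is at most k.
#'
#' @param S similarity matrix from \code{\link{expression_similarity}}.
#' @param k neighborhood size, 1 <= k <= p - 1.
#' @return a symmetric binary sparse adjacency matrix (zero diagonal) with
#'   attributes \code{"k"} and \code{"flavor"}.
#' @export
mutual_knn <- function(S, k) {
  A <- graph_from_neighbors(neighbors_from_similarity(S, k), rownames(S),
                            mutual = TRUE)
  attr(A, "k") <- as.integer(k)
  attr(A, "flavor") <- "mutual_knn"
  A
}

#' Asymmetric k-nearest-neighbor co-expression graph
#'
#' Connects nodes i and j iff at least one is among the other's k most
#' similar nodes (OR condition); the mutual-KNN edge set is always a subset
#' of this one.
#'
#' @inheritParams mutual_knn
#' @return a symmetric binary sparse adjacency matrix (zero diagonal).
#' @export
asymmetric_knn <- function(S, k) {
  A <- graph_from_neighbors(neighbors_from_similarity(S, k), rownames(S),
                            mutual = FALSE)
  attr(A, "k") <- as.integer(k)
  attr(A, "flavor") <- "asymmetric_knn"
  A
}

# block-wise top-k neighbors straight from the expression matrix, never
# materializing the full p x p similarity. Output is identical to
# neighbors_from_similarity(expression_similarity(E, axis), k).
knn_neighbors_blockwise <- function(E, k, axis = c("gene", "cell"),
                                    block_size = 1024L) {
  axis <- match.arg(axis)
  X <- if (axis == "gene") t(E) else E          # n_obs x p
  p <- ncol(X)
  if (length(k) != 1L || !is.finite(k) || k < 1 || k > p - 1L) {
    stop_config("invalid 'k': must be in [1, ", p - 1L, "]")
  }
  k <- as.integer(k)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  ss <- sqrt(colSums(Xc^2))
  isolated <- ss == 0
  ss_safe <- ss
  ss_safe[isolated] <- 1
  Z <- sweep(Xc, 2L, ss_safe, "/")
  Z[, isolated] <- 0
  nn <- matrix(NA_integer_, nrow = p, ncol = k)
  valid <- which(!isolated)
  for (start in seq(1L, p, by = block_size)) {
    idx <- start:min(start + block_size - 1L, p)
    Sb <- crossprod(Z[, idx, drop = FALSE], Z)   # block x p correlations
    for (r in seq_along(idx)) {
      i <- idx[r]
      if (isolated[i]) next
      s <- Sb[r, ]
      s[i] <- -Inf
      s[isolated] <- -Inf
      cand <- valid[valid != i]
      if (length(cand) == 0L) next
      ord <- cand[order(s[cand], decreasing = TRUE)]
      take <- head(ord, k)
      nn[i, seq_along(take)] <- take
    }
  }
  attr(nn, "isolated") <- isolated
  nn
}

#' Build a KNN co-expression graph directly from an expression matrix
#'
#' Computes top-k neighborhoods block-wise so the full p x p similarity
#' matrix is never materialized; the result is identical to
#' \code{mutual_knn(expression_similarity(E, axis), k)} (or the asymmetric
#' variant).
#'
#' @param E log-normalized genes x cells matrix.
#' @param k neighborhood size.
#' @param axis \code{"gene"} or \code{"cell"}.
#' @param flavor \code{"mutual"} or \code{"asymmetric"}.
#' @param block_size rows of the similarity computed per block.
#' @return a symmetric binary sparse adjacency matrix.
#' @export
knn_graph <- function(E, k, axis = c("gene", "cell"),
                      flavor = c("mutual", "asymmetric"),
                      block_size = 1024L) {
  axis <- match.arg(axis)
  flavor <- match.arg(flavor)
  E <- check_expression(E, allow_negative = TRUE)
  nn <- knn_neighbors_blockwise(E, k, axis, block_size)
  ids <- if (axis == "gene") rownames(E) else colnames(E)
  A <- graph_from_neighbors(nn, ids, mutual = flavor == "mutual")
  attr(A, "k") <- as.integer(k)
  attr(A, "flavor") <- paste0(flavor, "_knn")
  A
}

#' Load and filter a protein-protein interaction network
#'
#' Takes a STRING-style scored edge table (geneA, geneB, combined_score),
#' keeps only the most confident interactions (score at or above the
#' \code{confidence_quantile} quantile of all scores, i.e. the top 10\% by
#' default), drops edges touching genes absent from the expression matrix,
#' symmetrizes and removes self-loops. Expressed genes with no surviving
#' interaction remain as isolated nodes, so imputation leaves them
#' unchanged. Gene IDs are matched case-insensitively.
#'
#' @param edges data.frame with three columns (geneA, geneB, score) or a
#'   path to a whitespace/tab-delimited file with those columns (header
#'   optional).
#' @param expressed_genes character vector of gene IDs defining the node
#'   set (typically \code{rownames} of the filtered expression matrix).
#' @param confidence_quantile quantile of the score distribution below
#'   which edges are discarded (default 0.90, keeping the top 10 percent).
#' @return a symmetric binary sparse adjacency matrix over
#'   \code{expressed_genes}.
#' @export
load_ppi <- function(edges, expressed_genes, confidence_quantile = 0.90) {
  if (is.character(edges) && length(edges) == 1L) {
    if (!file.exists(edges)) stop_usage("PPI edge file not found: ", edges)
    edges <- data.table::fread(edges, header = "auto", data.table = FALSE)
  }
  if (!is.data.frame(edges) || ncol(edges) < 3L) {
    stop_data("PPI edges must have three columns: geneA, geneB, score")
  }
  if (length(confidence_quantile) != 1L || !is.finite(confidence_quantile) ||
      confidence_quantile < 0 || confidence_quantile > 1) {
    stop_config("invalid 'confidence_quantile': must be in [0, 1]")
  }
  score <- as.numeric(edges[[3L]])
  if (any(is.na(score))) stop_data("non-numeric PPI scores")
  thr <- quantile(score, confidence_quantile, names = FALSE)
  keep <- score >= thr
  key <- toupper(expressed_genes)
  a <- match(toupper(as.character(edges[[1L]])), key)
  b <- match(toupper(as.character(edges[[2L]])), key)
  ok <- keep & !is.na(a) & !is.na(b) & a != b
  p <- length(expressed_genes)
  if (!any(ok)) {
    warning("no PPI edges survive filtering; graph is fully isolated ",
            "and imputation will return the input unchanged")
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(p, p),
                              dimnames = list(expressed_genes, expressed_genes))
  } else {
    A <- Matrix::sparseMatrix(i = c(a[ok], b[ok]), j = c(b[ok], a[ok]), x = 1,
                              dims = c(p, p),
                              dimnames = list(expressed_genes, expressed_genes))
    A@x[] <- 1
    Matrix::diag(A) <- 0
    A <- Matrix::drop0(A)
  }
  attr(A, "flavor") <- "ppi"
  A
}
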