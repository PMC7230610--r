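#' Row-normalize an adjacency matrix into a transition matrix
#'
#' Divides each row of the binary adjacency by its degree, giving the
#' transition probabilities of a simple random walk. Isolated (zero-degree)
#' nodes receive a self-loop row (P[v,v] = 1) so the matrix stays
#' row-stochastic and isolated genes keep their own value under diffusion.
#'
#' @param A symmetric binary sparse adjacency matrix with zero diagonal.
#' @return a row-stochastic sparse matrix P with the same dimnames.
#' @export
row_normalize <- function(A) {
  A <- as(as(Matrix::Matrix(A), "CsparseMatrix"), "generalMatrix")
  d <- Matrix::rowSums(A)
  inv <- ifelse(d > 0, 1 / d, 0)
  P <- Matrix::Diagonal(x = inv) %*% A
  if (any(d == 0)) {
    P <- P + Matrix::Diagonal(x = as.numeric(d == 0))
  }
  P <- as(as(P, "CsparseMatrix"), "generalMatrix")
  dimnames(P) <- dimnames(A)
  P
}

#' Stationary matrix of a random walk with restart
#'
#' Iterates F <- (1 - alpha) F P + alpha I from F = I until the largest
#' absolute entry change drops below \code{tol}. The fixed point is
#' F = alpha (I - (1 - alpha) P)^{-1}; row v holds the outgoing
#' probabilities f_vj, the equilibrium probability that a walker started at
#' v (restarting to v with probability alpha at each step) sits at j. Every
#' row sums to 1 and f_vv >= alpha, so under outgoing-probability
#' imputation every gene keeps at least an alpha share of its own value.
#'
#' The p x p result is dense; this explicit form is intended for moderate p
#' (diagnostics and testing). Imputation itself uses the implicit iteration
#' in \code{\link{diffuse_expression}}, which never materializes F.
#'
#' @param P row-stochastic sparse transition matrix.
#' @param alpha restart probability in (0, 1].
#' @param tol convergence tolerance on the max absolute entry change.
#' @param max_iter maximum number of iterations.
#' @return a dense p x p matrix with attribute \code{"alpha"}.
#' @export
rwr_stationary <- function(P, alpha, tol = 1e-6, max_iter = 1000L) {
  check_alpha(alpha)
  check_stochastic(P)
  p <- nrow(P)
  I <- diag(p)
  F_cur <- I
  for (it in seq_len(max_iter)) {
    F_new <- (1 - alpha) * as.matrix(F_cur %*% P) + alpha * I
    delta <- max(abs(F_new - F_cur))
    F_cur <- F_new
    if (delta < tol) {
      dimnames(F_cur) <- dimnames(P)
      attr(F_cur, "alpha") <- alpha
      return(F_cur)
    }
  }
  stop_data("random walk did not converge in ", max_iter,
            " iterations (residual ", format(delta), ")")
}

#' Diffuse an expression matrix over a transition matrix
#'
#' Computes the RWR-smoothed matrix without materializing the stationary
#' matrix F: outgoing mode iterates X <- (1 - alpha) P X + alpha E to the
#' fixed point F E (imputed e_vc = sum_j f_vj e_jc, a probability-weighted
#' average of cell c's values, so each gene's imputed value keeps magnitude
#' comparable to its observed one); incoming mode iterates with t(P),
#' giving t(F) E (imputed values weighted by the probabilities flowing
#' *into* each gene, which inflates hub genes — provided for comparison).
#'
#' @param P row-stochastic sparse transition matrix over the genes of E.
#' @param E genes x cells matrix (log-normalized); rownames must equal P's
#'   node IDs.
#' @param alpha restart probability in (0, 1].
#' @param mode \code{"outgoing"} (weighted average, the default) or
#'   \code{"incoming"}.
#' @param tol,max_iter iteration control as in \code{\link{rwr_stationary}}.
#' @return the smoothed matrix, same shape and dimnames as E.
#' @export
diffuse_expression <- function(P, E, alpha, mode = c("outgoing", "incoming"),
                               tol = 1e-6, max_iter = 1000L) {
  mode <- match.arg(mode)
  check_alpha(alpha)
  check_stochastic(P)
  if (!is.matrix(E)) E <- as.matrix(E)
  if (is.null(rownames(E)) || is.null(rownames(P)) ||
      !identical(rownames(P), rownames(E))) {
    missing <- setdiff(rownames(P), rownames(E))
    stop_data("node set of the transition matrix does not match the rows ",
              "of the expression matrix",
              if (length(missing)) paste0(" (missing: ",
                paste(head(missing, 5L), collapse = ", "), ")") else "")
  }
  M <- if (mode == "outgoing") P else Matrix::t(P)
  X <- E
  for (it in seq_len(max_iter)) {
    X_new <- (1 - alpha) * as.matrix(M %*% X) + alpha * E
    delta <- max(abs(X_new - X))
    X <- X_new
    if (delta < tol) {
      dimnames(X) <- dimnames(E)
      return(set_scale(X, "imputed"))
    }
  }
  stop_data("diffusion did not converge in ", max_iter,
            " iterations (residual ", format(delta), ")")
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop_config("invalid 'alpha': restart probability must be in (0, 1]")
  }
}

check_stochastic <- function(P, tol = 1e-8) {
  if (nrow(P) != ncol(P)) stop_data("transition matrix must be square")
  rs <- Matrix::rowSums(P)
  if (any(abs(rs - 1) > tol) || min(P) < 0) {
    stop_data("transition matrix is not row-stochastic")
  }
}

#' Network-based dropout imputation
#'
#' End-to-end pipeline: filter unexpressed genes, library-size normalize,
#' log transform, build the network (mutual KNN on Pearson similarity over
#' genes or cells, or a confidence-filtered PPI), row-normalize it, and
#' diffuse the log-normalized matrix by random walk with restart. For the
#' gene and PPI networks the smoothing is across each cell's genes
#' (imputed e_vc = sum_j f_vj e_jc); for the cell network each gene's
#' profile is smoothed across cells (imputed e_gc = sum_d f_cd e_gd).
#'
#' @param E_raw genes x cells matrix of non-negative values (counts or any
#'   non-negative expression measure).
#' @param input_scale \code{"counts"} (default) runs the full preprocessing
#'   chain; \code{"lognormalized"} declares that the input already is
#'   library-size normalized and log transformed (as simulated data is), so
#'   only the unexpressed-gene filter is applied before network
#'   construction and diffusion.
#' @param network \code{"gene"} (default), \code{"cell"}, or \code{"ppi"}.
#' @param k mutual-KNN neighborhood size (gene/cell networks).
#' @param alpha restart probability in (0, 1]; alpha = 1 disables smoothing.
#' @param mode \code{"outgoing"} (default) or \code{"incoming"} diffusion.
#' @param ppi_edges scored edge table or file path (required for
#'   \code{network = "ppi"}), see \code{\link{load_ppi}}.
#' @param confidence_quantile PPI score quantile cutoff.
#' @param pseudo pseudo count of the log transform.
#' @param tol,max_iter diffusion iteration control.
#' @param back_transform if TRUE, return expm1 of the smoothed matrix
#'   (normalized-count scale) instead of the log scale.
#' @param block_size block size for block-wise KNN search.
#' @return the imputed matrix (log-normalized scale unless
#'   \code{back_transform}), restricted to the expressed genes.
#' @export
netimpute <- function(E_raw, network = c("gene", "cell", "ppi"),
                      k = 128L, alpha = 0.5,
                      mode = c("outgoing", "incoming"),
                      input_scale = c("counts", "lognormalized"),
                      ppi_edges = NULL, confidence_quantile = 0.90,
                      pseudo = 1, tol = 1e-6, max_iter = 1000L,
                      back_transform = FALSE, block_size = 1024L) {
  network <- match.arg(network)
  mode <- match.arg(mode)
  check_alpha(alpha)
  E <- prepare_expression(E_raw, input_scale, pseudo)
  if (network == "ppi") {
    if (is.null(ppi_edges)) {
      stop_config("network = \"ppi\" requires 'ppi_edges'")
    }
    A <- load_ppi(ppi_edges, rownames(E), confidence_quantile)
  } else {
    axis <- network
    A <- knn_graph(E, k = k, axis = axis, flavor = "mutual",
                   block_size = block_size)
  }
  P <- row_normalize(A)
  if (network == "cell") {
    X <- t(diffuse_expression(P, t(E), alpha, mode, tol, max_iter))
  } else {
    X <- diffuse_expression(P, E, alpha, mode, tol, max_iter)
  }
  dimnames(X) <- dimnames(E)
  X <- set_scale(X, "imputed")
  if (back_transform) X <- set_scale(expm1(X), "imputed")
  X
}
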