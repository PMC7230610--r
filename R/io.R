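#' Read an expression matrix
#'
#' Dense TSV/CSV (genes as rows, first column gene IDs, header row of cell
#' IDs) or MatrixMarket (\code{.mtx}) with sidecar one-ID-per-line gene and
#' cell files. The dense round-trip through \code{\link{write_expression}}
#' is loss-free.
#'
#' @param path input file; format chosen by extension (.tsv/.txt, .csv,
#'   .mtx).
#' @param gene_file,cell_file sidecar ID files for MatrixMarket input;
#'   default \code{<path minus .mtx>_genes.txt} / \code{_cells.txt}.
#' @return a dense numeric genes x cells matrix with dimnames.
#' @export
read_expression <- function(path, gene_file = NULL, cell_file = NULL) {
  if (!file.exists(path)) stop_usage("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(gene_file)) gene_file <- paste0(stem, "_genes.txt")
    if (is.null(cell_file)) cell_file <- paste0(stem, "_cells.txt")
    if (!file.exists(gene_file)) stop_usage("gene ID file not found: ", gene_file)
    if (!file.exists(cell_file)) stop_usage("cell ID file not found: ", cell_file)
    M <- as.matrix(Matrix::readMM(path))
    rownames(M) <- readLines(gene_file)
    colnames(M) <- readLines(cell_file)
    return(check_expression(M))
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  genes <- as.character(dt[[1L]])
  M <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- genes
  check_expression(M, allow_negative = TRUE)
}

#' Write an expression matrix
#'
#' @param E genes x cells matrix with dimnames.
#' @param path output file; \code{.csv} writes comma-separated, \code{.mtx}
#'   writes MatrixMarket plus sidecar ID files, anything else tab-separated
#'   with gene IDs in the first column and cell IDs in the header.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(E, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    Matrix::writeMM(as(as(Matrix::Matrix(E), "CsparseMatrix"), "generalMatrix"),
                    path)
    writeLines(rownames(E), paste0(stem, "_genes.txt"))
    writeLines(colnames(E), paste0(stem, "_cells.txt"))
    return(invisible(path))
  }
  dt <- data.table::data.table(gene = rownames(E))
  dt <- cbind(dt, data.table::as.data.table(E))
  data.table::fwrite(dt, path, sep = if (ext == "csv") "," else "\t")
  invisible(path)
}

#' Read cell-type labels
#'
#' Two-column TSV (cell_id, type), with or without a header.
#'
#' @param path input file.
#' @return a vector of labels named by cell ID.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_usage("label file not found: ", path)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) < 2L) stop_data("label file must have two columns (cell_id, type)")
  labels <- dt[[2L]]
  names(labels) <- as.character(dt[[1L]])
  labels
}

#' Write cell-type labels
#'
#' @param labels vector of labels named by cell ID.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(
    data.table::data.table(cell_id = names(labels), type = unname(labels)),
    path, sep = "\t")
  invisible(path)
}

#' Export a graph as an edge-list TSV
#'
#' Writes each undirected edge once (node_a < node_b by index).
#'
#' @param A symmetric binary sparse adjacency matrix with dimnames.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_graph_edges <- function(A, path) {
  TT <- as(as(A, "CsparseMatrix"), "TsparseMatrix")
  i <- TT@i + 1L
  j <- TT@j + 1L
  up <- i < j
  data.table::fwrite(
    data.table::data.table(node_a = rownames(A)[i[up]],
                           node_b = colnames(A)[j[up]]),
    path, sep = "\t")
  invisible(path)
}

#' Read a graph from an edge-list TSV
#'
#' @param path two-column edge list (node_a, node_b), with or without
#'   header.
#' @param node_ids the full node set (isolated nodes allowed).
#' @return a symmetric binary sparse adjacency matrix over \code{node_ids}.
#' @export
read_graph_edges <- function(path, node_ids) {
  if (!file.exists(path)) stop_usage("graph file not found: ", path)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  a <- match(as.character(dt[[1L]]), node_ids)
  b <- match(as.character(dt[[2L]]), node_ids)
  ok <- !is.na(a) & !is.na(b) & a != b
  p <- length(node_ids)
  A <- Matrix::sparseMatrix(i = c(a[ok], b[ok]), j = c(b[ok], a[ok]),
                            x = 1, dims = c(p, p),
                            dimnames = list(node_ids, node_ids))
  A@x[] <- 1
  A
}
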