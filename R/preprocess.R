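#' Remove genes that are not expressed in any cell
#'
#' Low-quality genes are defined as all-zero rows; they carry no signal and
#' would be zero-variance (hence isolated) in the co-expression network
#' anyway. Gene order is preserved.
#'
#' @param E genes x cells matrix of non-negative values.
#' @return the matrix restricted to genes with at least one non-zero entry.
#' @export
filter_unexpressed_genes <- function(E) {
  E <- check_expression(E)
  keep <- rowSums(E != 0) > 0L
  if (!any(keep)) stop_data("all genes are unexpressed; nothing to keep")
  scale <- attr(E, "scale")
  out <- E[keep, , drop = FALSE]
  set_scale(out, scale)
}

#' Library-size normalization
#'
#' Divides each entry by the total of its cell (column) and multiplies by
#' the median of all cell totals, so that every cell ends up with the same
#' total, the median library size. Within-cell proportions are untouched.
#'
#' @param E genes x cells matrix; every column must have a positive total.
#' @return the normalized matrix (every column sums to median(colSums(E))).
#' @export
normalize_library_size <- function(E) {
  E <- check_expression(E)
  lib <- colSums(E)
  if (any(lib <= 0)) {
    stop_data("cells with zero total counts: ",
              paste(head(colnames(E)[lib <= 0], 5L), collapse = ", "),
              "; filter empty cells before normalizing")
  }
  out <- sweep(E, 2L, lib, "/") * median(lib)
  set_scale(out, "normalized")
}

#' Log transform with a pseudo count
#'
#' Applies \code{log(x + pseudo)} entrywise (natural log). With the default
#' pseudo count of 1, zeros map to zero, so the zero pattern is preserved.
#'
#' @param E genes x cells matrix of non-negative values.
#' @param pseudo positive pseudo count added before taking the log.
#' @return the transformed matrix.
#' @export
log_transform <- function(E, pseudo = 1) {
  E <- check_expression(E)
  if (length(pseudo) != 1L || !is.finite(pseudo) || pseudo <= 0) {
    stop_config("invalid 'pseudo': must be a positive number")
  }
  out <- log(E + pseudo)
  dimnames(out) <- dimnames(E)
  set_scale(out, "lognormalized")
}

#' Standard preprocessing pipeline
#'
#' Convenience wrapper running, in order: unexpressed-gene filtering,
#' library-size normalization, and log transform with pseudo count 1.
#' This is the matrix on which similarity and imputation operate.
#'
#' @inheritParams filter_unexpressed_genes
#' @param pseudo pseudo count for the log transform.
#' @return the log-normalized matrix.
#' @export
preprocess <- function(E, pseudo = 1) {
  log_transform(normalize_library_size(filter_unexpressed_genes(E)), pseudo)
}

# bring an input matrix to the log-normalized stage the network and the
# diffusion operate on: counts go through the full chain, data that is
# already log-normalized (e.g. the simulator's output) only gets the
# unexpressed-gene filter.
prepare_expression <- function(E, input_scale = c("counts", "lognormalized"),
                               pseudo = 1) {
  input_scale <- match.arg(input_scale)
  if (input_scale == "counts") {
    preprocess(E, pseudo)
  } else {
    set_scale(filter_unexpressed_genes(E), "lognormalized")
  }
}
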