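# independent oracles used to check the package's own implementations

# all set partitions of n objects into at most max_blocks blocks, as
# canonical label vectors (restricted growth strings)
enumerate_partitions <- function(n, max_blocks) {
  out <- list()
  recurse <- function(prefix, top) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(min(top + 1L, max_blocks))) {
      recurse(c(prefix, lab), max(top, lab))
    }
  }
  recurse(integer(), 0L)
  out
}

# ARI built directly from pair counting: walk all C(n,2) object pairs,
# count co-membership agreements, and chance-correct.
pair_counting_ari <- function(x, y) {
  n <- length(x)
  together <- 0; in_x <- 0; in_y <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sx <- x[i] == x[j]
      sy <- y[i] == y[j]
      if (sx && sy) together <- together + 1
      if (sx) in_x <- in_x + 1
      if (sy) in_y <- in_y + 1
    }
  }
  npairs <- n * (n - 1) / 2
  expected <- in_x * in_y / npairs
  maximum <- (in_x + in_y) / 2
  if (abs(maximum - expected) < 1e-12) {
    return(as.numeric(together == maximum && in_x == in_y))
  }
  (together - expected) / (maximum - expected)
}

# brute-force mutual / asymmetric KNN straight from the definition
brute_knn_graph <- function(S, k, mutual = TRUE) {
  p <- nrow(S)
  isolated <- attr(S, "isolated")
  if (is.null(isolated)) isolated <- rep(FALSE, p)
  topk <- lapply(seq_len(p), function(i) {
    if (isolated[i]) return(integer())
    s <- S[i, ]
    s[i] <- NA
    s[isolated] <- NA
    cand <- which(!is.na(s))
    cand[order(s[cand], decreasing = TRUE)][seq_len(min(k, length(cand)))]
  })
  A <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      a <- j %in% topk[[i]]
      b <- i %in% topk[[j]]
      if ((mutual && a && b) || (!mutual && (a || b))) A[i, j] <- 1
    }
  }
  dimnames(A) <- dimnames(S)
  A
}

# textbook Pearson correlation, written out
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# direct dense solve of the RWR fixed point F = alpha (I - (1-alpha) P)^-1
rwr_solve_oracle <- function(P, alpha) {
  p <- nrow(P)
  alpha * solve(diag(p) - (1 - alpha) * as.matrix(P))
}

# random connected-ish undirected graph adjacency with dimnames
random_graph <- function(p, edge_prob = 0.15) {
  A <- matrix(0, p, p)
  A[upper.tri(A)] <- as.numeric(runif(p * (p - 1) / 2) < edge_prob)
  A <- A + t(A)
  ids <- paste0("g", seq_len(p))
  dimnames(A) <- list(ids, ids)
  A
}
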