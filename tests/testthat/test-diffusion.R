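path3 <- function() {
  ids <- c("a", "b", "c")
  A <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, 3, dimnames = list(ids, ids))
  A
}

two_node_P <- function() {
  ids <- c("u", "v")
  Matrix::Matrix(matrix(c(0, 1, 1, 0), 2, dimnames = list(ids, ids)),
                 sparse = TRUE)
}

test_that("row normalization splits by degree and self-loops isolated nodes", {
  P <- as.matrix(row_normalize(path3()))
  expect_equal(P["b", ], c(a = 0.5, b = 0, c = 0.5), tolerance = 1e-12)
  expect_equal(rowSums(P), c(a = 1, b = 1, c = 1), tolerance = 1e-12)
  # isolated node gets a unit self-loop row
  A <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A[1, 2] <- A[2, 1] <- 1
  P2 <- as.matrix(row_normalize(A))
  expect_equal(P2["c", ], c(a = 0, b = 0, c = 1), tolerance = 0)
  # complete graph K3: all off-diagonal 0.5
  K3 <- matrix(1, 3, 3) - diag(3)
  dimnames(K3) <- list(letters[1:3], letters[1:3])
  P3 <- as.matrix(row_normalize(K3))
  expect_equal(unname(P3), (matrix(1, 3, 3) - diag(3)) / 2, tolerance = 1e-12)
})

test_that("RWR stationary matrix matches closed forms", {
  P <- two_node_P()
  # full restart: never leaves the start node
  expect_equal(unname(rwr_stationary(P, alpha = 1)), diag(2), tolerance = 0,
               ignore_attr = TRUE)
  # worked 2-node solution of alpha (I - (1-alpha)P)^-1 at alpha = 0.5
  F2 <- rwr_stationary(P, alpha = 0.5, tol = 1e-10)
  expect_equal(unname(F2), matrix(c(2, 1, 1, 2) / 3, 2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("iterative RWR equals the direct linear solve and honors its invariants", {
  set.seed(77)
  for (rep in 1:20) {
    p <- sample(5:100, 1)
    alpha <- sample(c(0.1, 0.5, 0.9), 1)
    P <- row_normalize(random_graph(p))
    F_iter <- rwr_stationary(P, alpha, tol = 1e-10)
    F_direct <- rwr_solve_oracle(P, alpha)
    expect_lt(max(abs(F_iter - F_direct)), 1e-8)
    expect_true(all(abs(rowSums(F_iter) - 1) < 1e-6))
    expect_true(all(diag(F_iter) >= alpha - 1e-12))
    expect_true(all(F_iter >= 0))
  }
})

test_that("implicit diffusion equals multiplying by the explicit stationary matrix", {
  set.seed(88)
  for (rep in 1:5) {
    p <- sample(20:200, 1)
    n <- sample(2:10, 1)
    alpha <- runif(1, 0.2, 0.9)
    P <- row_normalize(random_graph(p))
    E <- matrix(rexp(p * n), p, n,
                dimnames = list(rownames(P), paste0("c", 1:n)))
    F_exp <- rwr_solve_oracle(P, alpha)
    out <- diffuse_expression(P, E, alpha, "outgoing", tol = 1e-10)
    inc <- diffuse_expression(P, E, alpha, "incoming", tol = 1e-10)
    expect_lt(max(abs(out - F_exp %*% E)), 1e-8)
    expect_lt(max(abs(inc - t(F_exp) %*% E)), 1e-8)
    # convexity: outgoing values stay inside each cell's observed range
    for (j in seq_len(n)) {
      expect_true(all(out[, j] >= min(E[, j]) - 1e-10))
      expect_true(all(out[, j] <= max(E[, j]) + 1e-10))
    }
  }
})

test_that("constant-per-cell input is a fixed point of outgoing diffusion", {
  P <- row_normalize(path3())
  E <- matrix(rep(c(2, 5), each = 3), 3, 2,
              dimnames = list(rownames(P), c("c1", "c2")))
  out <- diffuse_expression(P, E, alpha = 0.4)
  expect_equal(unclass(out)[, ], unclass(E)[, ], tolerance = 1e-12)
})

test_that("diffusion validates alpha and the node set", {
  P <- row_normalize(path3())
  E <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "x"), c("c1", "c2")))
  expect_error(diffuse_expression(P, E, 0.5), "node set")
  E2 <- matrix(1:6, 3, 2, dimnames = list(rownames(P), c("c1", "c2")))
  expect_error(diffuse_expression(P, E2, 0), "alpha")
  expect_error(diffuse_expression(P, E2, 1.5), "alpha")
})

test_that("netimpute at alpha = 1 and on an isolated graph returns its input", {
  ds <- simulate_dataset(simulation_config(n_genes = 150L, n_cells = 40L,
                                           de_genes_per_type = 10L,
                                           dropout_lambda = 0.08, seed = 14))
  prepared <- netimpute:::prepare_expression(ds$raw, "lognormalized")
  # full restart: no smoothing at all
  X1 <- netimpute(ds$raw, network = "gene", k = 16, alpha = 1,
                  input_scale = "lognormalized")
  expect_equal(unclass(X1)[, ], unclass(prepared)[, ], tolerance = 0)
  # a PPI with no matching genes gives identity rows
  edges <- data.frame(a = "zz1", b = "zz2", score = 1)
  expect_warning(
    X2 <- netimpute(ds$raw, network = "ppi", alpha = 0.5, ppi_edges = edges,
                    input_scale = "lognormalized"),
    "isolated")
  expect_equal(unclass(X2)[, ], unclass(prepared)[, ], tolerance = 0)
  # counts pipeline at alpha = 1 reproduces the log-normalized input
  X3 <- netimpute(ds$raw, network = "gene", k = 16, alpha = 1)
  expect_equal(unclass(X3)[, ], unclass(preprocess(ds$raw))[, ],
               tolerance = 0)
})

test_that("cell-network imputation smooths each gene's profile across cells", {
  ds <- simulate_dataset(simulation_config(n_genes = 120L, n_cells = 36L,
                                           de_genes_per_type = 10L,
                                           dropout_lambda = 0.08, seed = 15))
  E <- netimpute:::prepare_expression(ds$raw, "lognormalized")
  X <- netimpute(ds$raw, network = "cell", k = 8, alpha = 0.6,
                 input_scale = "lognormalized", tol = 1e-10)
  # oracle: explicit F over the cell graph, imputed e_gc = sum_d f_cd e_gd
  A <- knn_graph(E, 8, axis = "cell", flavor = "mutual")
  F_exp <- rwr_solve_oracle(row_normalize(A), 0.6)
  expect_lt(max(abs(X - E %*% t(F_exp))), 1e-8)
  expect_identical(dim(X), dim(E))
})
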