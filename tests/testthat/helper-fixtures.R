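# shared fixtures built in code

# the reduced simulation used by the heavier evaluation tests: 2000 genes,
# 150 cells, 3 types, 81 DE genes per type; lambda = 0.04 yields ~87% zeros
reduced_config <- function(seed, dropout_lambda = 0.04) {
  simulation_config(n_genes = 2000L, n_cells = 150L, n_types = 3L,
                    de_genes_per_type = 81L,
                    dropout_lambda = dropout_lambda, seed = seed)
}

# small labeled matrix
toy_matrix <- function(values, nrow) {
  m <- matrix(values, nrow = nrow)
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0("c", seq_len(ncol(m))))
  m
}
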