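# netimpute

Network-based dropout imputation for single-cell RNA-seq expression
matrices, with a zero-inflation simulator and a clustering evaluation
harness.

## The problem and the method

scRNA-seq count matrices are riddled with technical zeros ("dropouts")
because only a small fraction of each cell's transcripts is captured. The
excess zeros blur cell-to-cell similarity and break cell-type
identification. netimpute smooths the matrix over a co-expression network:

1. **Network.** Pearson similarity `S` between genes; genes `i, j` are
   linked iff each is in the other's top-`k` neighborhood (*mutual* KNN).
   Cell-cell networks and confidence-filtered protein-protein interaction
   tables (top 10% by combined score) are supported alternatives.
2. **Random walk with restart.** `P` is the row-normalized adjacency; the
   walk `F <- (1 - alpha) F P + alpha I` converges to
   `F = alpha (I - (1 - alpha) P)^(-1)`, whose row `v` holds the outgoing
   probabilities `f_vj` (each row sums to 1, `f_vv >= alpha`).
3. **Imputation.** `e_vc' = sum_j f_vj e_jc` — a convex,
   outgoing-probability-weighted average of the cell's values, so each gene
   keeps at least an `alpha` share of its own measurement and hub genes are
   not inflated (the *incoming*-probability orientation, provided for
   comparison as `mode = "incoming"`, does inflate them; see
   `hub_effect()`).

The diffusion runs implicitly (`X <- (1 - alpha) P X + alpha E`), so the
dense `m x m` stationary matrix is never built.

## A worked example

```r
library(netimpute)

cfg <- simulation_config(n_genes = 2000, n_cells = 150, n_types = 3,
                         de_genes_per_type = 81, dropout_lambda = 0.06,
                         seed = 1)
ds <- simulate_dataset(cfg)          # original + zero-inflated raw + labels
dropout_rate(ds$raw)
#> [1] 0.804

raw <- filter_unexpressed_genes(ds$raw)
adjusted_rand_index(ds$labels, pca_kmeans(raw, 3, seed = 1))
#> [1] 0.701

imp <- netimpute(ds$raw, network = "gene", k = 128, alpha = 0.5,
                 input_scale = "lognormalized")
adjusted_rand_index(ds$labels, pca_kmeans(imp, 3, seed = 1))
#> [1] 0.736
```

At 80% zeros, PCA+k-means recovers the three simulated cell types with
adjusted Rand index 0.70 from the raw matrix and 0.74 after imputation
(1 = perfect recovery of the generating labels, ~0 = chance). The
`input_scale = "lognormalized"` flag tells the pipeline that simulated data
is already on the log scale; real count matrices use the default
`"counts"`, which filters, library-size normalizes and log-transforms
first.

## Command line

A thin wrapper over the package functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "netimpute.R", package = "netimpute"))') \
    simulate --n-genes 2000 --n-cells 150 --de-per-type 81 \
    --dropout-lambda 0.06 --seed 1 --out-prefix sim/
# then: impute --input sim/raw.tsv --k 128 --alpha 0.5 --output imputed.tsv
#       evaluate --imputed imputed.tsv --labels sim/labels.tsv --n-clusters 3
#       sweep / hub-report for the parameter grid and the degree-bias table
```

Every run writes a JSON record of its effective parameters next to its
outputs; exit codes are 0 (success), 1 (data/configuration error), 2
(usage error).

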