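# scLSTM

Cell-type detection for single-cell RNA-seq by pairwise similarity
learning. The package is for computational biologists who have a cells ×
genes expression matrix (counts, CPM, TPM, FPKM or RPKM), may or may not
know the number of cell types, and want cluster assignments plus external
validation metrics — in particular on small, platform-heterogeneous data
sets (50–800 cells) with up to 10:1 cell-type imbalance, where rare types
are easily absorbed by common ones.

## Method

Three stages:

1. **Improved sigmoid-kernel embedding.** From the expression matrix $A$:
   $L = \log(A+1)$; $I = LL^\top$ (inner products of log profiles);
   $I' = (I - I_{\min})/(I_{\max} - I_{\min})$ globally; $S = \tanh(I')$.
   All similarities lie in $[0, \tanh 1]$.
2. **Siamese LSTM.** Two weight-sharing LSTM branches read the kernel rows
   $S_i, S_j$ of a cell pair as sequences; a head (concatenate → dense →
   sigmoid → dense → sigmoid) scores the pair in $(0,1)$, trained with
   binary cross-entropy on same/different pairs built from pseudo-labels
   (an initial clustering of $S$) or, optionally, user labels. All pairs
   are then scored and symmetrised into a learned similarity $M$ with unit
   diagonal.
3. **Agglomerative clustering.** Average-linkage hierarchical clustering on
   $D = 1 - M$, cut at $k$ clusters; $k$ can be estimated by a silhouette
   sweep. K-means and spectral variants, and a single-branch ("sigLSTM")
   ablation, are included.

Validation metrics: adjusted Rand index (ARI), normalised mutual
information $\mathrm{NMI}(T,P) = 2I(T,P)/(H(T)+H(P))$, clustering accuracy
after the Hungarian-optimal label mapping, and balanced accuracy
(macro-averaged recall). A negative-binomial synthetic generator with
marker-gene blocks and dropout provides ground-truth benchmarks without any
download.

The twin LSTM (backpropagation through time + Adam) is implemented in
Rcpp/RcppArmadillo; no deep-learning framework is needed.

## Worked example

```r
library(scLSTM)

sim <- simulate_counts(synthetic_spec(n_cells = 120, n_genes = 2000, k = 3,
                                      proportions = c(0.6, 0.3, 0.1),
                                      seed = 42))
table(sim$labels)
#>  0  1  2
#> 72 36 12

run <- run_pipeline(sim$expr, labels = sim$labels, k = 3, seed = 42)
run
#> <pipeline_run> variant=sclstm method=AG k=3 (given) seed=42 [2.3s]
#>   ARI 1.0000  NMI 1.0000  ACC 1.0000  BAS 1.0000

run$model
#> <sclstm_model> n = 120, hidden = 32, 25 epochs (loss 0.6584 -> 0.0199)

estimate_num_clusters(run$S)
#> [1] 3
```

The simulated set has three types at 6:3:1 abundance; the pipeline recovers
the planted partition exactly (all four metrics 1), training converged from
a binary cross-entropy of 0.66 to 0.02 in 25 epochs, and the silhouette
sweep over the kernel similarity recovers the true number of clusters. With
real data, replace `sim$expr` with
`read_expression_matrix("expr.csv")` (dense CSV/TSV) or a Matrix Market
triplet (`matrix.mtx` + `genes.tsv`/`barcodes.tsv`, 10x layout); for
droplet data apply the prevalence filter
`filter_low_prevalence_genes(x, min_cells = 3)` or pass `min_cells = 3`.

A command-line front end with `run`, `simulate`, `kernel`, `cluster` and
`evaluate` subcommands is installed at `inst/cli/sclstm.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sclstm.R", package="scLSTM"))')" \
  run --input expr.csv --k 4 --variant sclstm --method AG --seed 0 --out run1/
```

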