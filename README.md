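# hnetpath

Uniform multilabel prediction of metabolic pathway types for chemicals and
enzymes from a weighted heterogeneous interaction network.

## The problem

Curated pathway catalogues such as KEGG group metabolism into eleven
top-level pathway types (carbohydrate metabolism, lipid metabolism, ...),
and a chemical or enzyme frequently belongs to more than one of them, so
assigning compounds and enzymes to pathway types is a multilabel
classification problem. Interaction databases (STITCH for chemical-chemical
and chemical-protein associations, STRING for protein-protein associations)
score each pair with an integer confidence in [1, 999] that integrates
structure, activity, reaction and literature evidence. `hnetpath` turns
those association scores into predictive features and classifies chemicals
and enzymes *in one shared model*, letting chemical neighbourhoods inform
enzyme predictions and vice versa.

## The method

1. **Network assembly.** The three link sets are parsed from the
   STITCH/STRING links-file dialect, scores are refined to weights
   `w = score / 1000 ∈ (0, 1)`, duplicate pairs keep the maximum weight, and
   the chemical, chemical-protein and protein subnetworks are combined into
   one undirected weighted heterogeneous network. Isolated nodes are
   discarded.
2. **Diffusion.** For each node *i* a random walk with restart
   `p ← (1 − r) P p + r e_i` (column-stochastic transition matrix `P`,
   restart probability `r = 0.5`) is run to its fixed point, giving a
   diffusion state `V_i`: a proximity distribution over all *n* nodes.
3. **Embedding.** Mashup-style dimensionality reduction finds feature
   vectors `X_i` and context vectors `W_k` of dimension *d* minimizing the
   average KL divergence `(1/n) Σ_i D_KL(V_i ‖ softmax(W X_i))`. The default
   route is an exact truncated SVD of `log V`; a full-batch gradient descent
   on the KL objective itself is also provided. `X` is the feature matrix.
4. **Classification.** A RAKEL (random k-labelsets) ensemble draws `M`
   random size-`k` subsets of the `m` labels, trains one label-powerset
   multiclass classifier per subset (SMO-trained SVM with polynomial or RBF
   kernel, or a random forest), and assigns a label when its average binary
   vote across covering members strictly exceeds 0.5. Binary relevance
   (one-vs-all) is the `k = 1` special case.
5. **Evaluation.** Ten-fold cross-validation pooled over out-of-fold
   predictions, measured by accuracy (mean per-sample Jaccard), exact match,
   hamming loss, and the integrated score
   `accuracy × exact match × (1 − hamming loss)`.

A seeded synthetic-network generator with planted label-correlated
connectivity (`make_benchmark()`) makes every stage testable without any
database download.

## Worked example

```r
library(hnetpath)

bench <- make_benchmark("easy", seed = 7)   # 120 chemicals, 60 enzymes, 5 labels
bench$network
#> Heterogeneous network: 120 chemicals, 60 enzymes, 1852 edges
#>   subnetwork edges: cci = 785 , cpi = 856 , ppi = 211

V <- diffusion_states(bench$network)            # n x n RWR states
emb <- mashup_embed(V, d = 32)                  # 32-dimensional features
labels <- bench$labels[bench$network$nodes$id, ]

cfg <- ml_config("rakel", k = 5, M = 5,
                 base = base_config("svm_poly", C = 2, E = 1), seed = 1)
cross_validate(emb$X, labels, cfg, make_cv_plan(nrow(labels), seed = 1))
#> Multilabel metrics (n = 180, m = 5):
#>   accuracy         0.810
#>   exact match      0.628
#>   hamming loss     0.079
#>   integrated score 0.468
```

The classifier recovers most planted label sets exactly (exact match 0.628)
while the all-empty baseline scores 0, and permuting which node gets which
feature vector collapses the integrated score to below 0.01 — the network
neighbourhood, not the feature distribution, carries the signal.

The same pipeline is available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hnetpath.R", package = "hnetpath"))')
Rscript $CLI simulate --difficulty easy --seed 7 --out sim
Rscript $CLI build-net --cci sim/cci.tsv --cpi sim/cpi.tsv --ppi sim/ppi.tsv \
        --chemicals sim/chemicals.txt --enzymes sim/enzymes.txt --out net
Rscript $CLI embed --net net --dim 32 --seed 1 --out emb.tsv
Rscript $CLI cv --features emb.tsv --labels sim/labels.tsv \
        --k 11 --M 5 --base svm_poly --C 2 --E 1 --seed 1 --out cvout
```

Subcommands `train`, `predict`, `permute-test`, `grid` and `pipeline`
cover model persistence, the permutation control, parameter grids and the
YAML-configured end-to-end run (`run_pipeline()` in R).

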