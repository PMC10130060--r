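# fatesimplex

Trilineage fate mapping for single-cell data. `fatesimplex` places
every cell of a transcriptomic (or chromatin-accessibility) dataset on
a three-fate barycentric simplex — vertices defined by three terminal
"apex" clusters such as osteoblasts, chondrocytes and
pre-adipocyte-like reticular cells — and overlays a future
differentiation potential derived from an RNA-velocity graph, drawn as
binned arrow fields pointing at the three vertices. It is aimed at
analysts studying branching differentiation (e.g. bone marrow stromal
lineages) who want a quantitative, reproducible alternative to reading
fate bias off a UMAP.

## The score

For cell $i$ and fate $f$ with apex cluster $C_f$:

$$D_{if} = \frac{1}{|C_f|} \sum_{j \in C_f} \lVert x_i - x_j \rVert_2
\qquad
S = \text{minmax}_f\!\left(-\log_{10} D\right)
\qquad
w_i = S_i \Big/ \sum_f S_{if}$$

computed over the union of the top-30 one-vs-rest Wilcoxon markers of
the three apex clusters, on normalized, scaled (non-centered) values.
The rows of $w$ are barycentric coordinates (they sum to 1) and plot
directly on a ternary diagram.

The future potential uses the steady-state velocity model: per-gene
degradation ratio $\hat\gamma = \sum us / \sum s^2$ fitted on the 5%
extreme cells of KNN-smoothed spliced/unspliced layers, residual
velocity $v = u - \hat\gamma s$, a clipped-cosine velocity graph over
the K = 30 nearest neighbors, and the per-cell mean edge weight into
each apex cluster, renormalized within the cell and averaged over 40
simplex grid bins.

A negative-binomial simulator with known barycentric truth, destined
fates and degradation rates (`simulate_fate_landscape()`,
`simulate_fragments()`) makes every stage testable end to end without
external data.

## Worked example

```r
library(fatesimplex)

cfg <- pipeline_config(sim = sim_params(seed = 1), seed = 1,
                       output_dir = "fate_run")
res <- run_pipeline(cfg)   # simulate -> preprocess -> markers ->
                           # simplex -> velocity -> potential -> arrows

colMeans(res$coords$barycentric[res$labels == "osteoblast", ])
#> osteoblast chondrocyte   reticular
#> 0.87715297  0.07701671  0.04583032

tr <- res$truth
trans <- names(tr$destined_fate)[!is.na(tr$destined_fate)]
Pn <- res$potential$normalized[trans, ]
Pn[is.na(Pn)] <- -1            # flagged cells cannot win
pred <- colnames(Pn)[max.col(Pn)]
mean(pred == tr$destined_fate[trans])
#> [1] 0.984
```

The first block says simulated osteoblast apex cells carry ~88% of
their affinity on the osteoblast vertex; the second says 98.4% of
transitional cells have their largest normalized differentiation
potential on the fate their simulated kinetics are driving them
toward. `fate_run/` receives `coords.tsv` (per-cell barycentric
weights and 2-D projection), `arrows.tsv` (per-bin arrow lengths),
`markers.tsv`, `velocity_graph.tsv` and a run manifest.

Real data enters through `read_expression()` (MatrixMarket layers +
features/barcodes TSV), `read_labels()`, `read_gene_annotation()`
(BED/GTF) and `gene_activity_from_fragments()` for the ATAC path; set
`pipeline_config(sim = NULL, input_dir = ..., apex_clusters = ...)`.

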