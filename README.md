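# degsom

Cross-tissue transcriptome comparison for disease/treatment designs:
pairwise differential-expression contrasts, directional classification of
treatment effects, self-organizing-map (SOM) co-expression modules, and
gene-set over-representation — with a synthetic-data generator that
plants known ground truth for validation.

## The problem

In factorial designs of the form *control vs. disease × untreated vs.
treated*, profiled in several tissues, the interesting questions are
directional. For each tissue, genes significant in both the disease
contrast (control → disease) and the treatment contrast (disease →
treated disease) split by the product of their fold-change signs:

- **reversed** — sign product −1: treatment pushes the gene back toward
  control;
- **exacerbated** — sign product +1: treatment pushes it further.

The motivating setting is the `db/db` mouse model of type 2 diabetes
treated with pioglitazone, profiled in sciatic nerve (SCN), dorsal root
ganglia (DRG), kidney glomeruli (Glom) and kidney cortex, where the
fraction of shared DEGs reversed by treatment differs sharply between
tissues.

At the core:

- **DEG calling** — per-gene two-sided Welch t-test on log₂(FPKM+1),
  Benjamini–Hochberg FDR within each contrast, significant iff q < 0.05;
  fold change log₂((mean_alt+1)/(mean_ref+1)).
- **Enrichment** — one-sided Fisher's exact test: for universe size N,
  set size K, list size n, overlap k, p = P(X ≥ k), X ~ Hypergeom(N, K,
  n); BH across the sets tested for each list.
- **SOM** — a from-scratch batch Kohonen map on a 7 × 7 hexagonal
  lattice over centred log₂ condition-mean profiles (genes below an FPKM
  floor of 3 removed), with U-matrix edge distances and merging of
  adjacent, correlated modules into clusters.

See the methods vignette (`vignettes/cross-tissue-pipeline.Rmd`) for the
full model description, parameter meanings and limitations.

## Worked example

```r
library(degsom)

cfg <- simulation_config(tissues = c("SCN", "Glom"), n_genes = 2000, seed = 42)
ds  <- generate_dataset(cfg)
ds$matrix
#> expression_matrix: 2000 genes x 48 samples
#> tissues: SCN, Glom
#> groups:  db/+, db/db, db/+ PIO, db/db PIO

dis <- extract_deg_set(call_degs(ds$matrix, "Glom", "db/+",  "db/db"))
trt <- extract_deg_set(call_degs(ds$matrix, "Glom", "db/db", "db/db PIO"))
classify_overlap(dis, trt)
#> overlap_classification [Glom]: 216 shared (98.1% reversed, 1.9% exacerbated),
#>   79 disease-only, 117 treatment-only
```

216 glomerular genes are significant in both contrasts and nearly all are
reversed — the generator's glomeruli analog plants ~95% reversal, and the
estimate lands within binomial error of it.

```r
inp  <- preprocess_for_som(ds$matrix)        # 1317 genes pass the FPKM-3 floor
grid <- train_som(inp, seed = 1)             # 7x7 hex lattice, 50 batch epochs
asg  <- assign_modules(grid, inp)            # quantization error 0.373
clusters <- merge_modules(grid, asg, correlation_threshold = 0.8)
clusters[[1]]
#> som_cluster 'cluster_01': modules {1, 2, 8, 15, 16, 22, 23, 24, 29, 31}, 253 genes

sets <- generate_gene_sets(ds$truth, n_decoy_sets = 5, set_size = 50, seed = 2)
res  <- fisher_enrichment(clusters[[1]]$member_genes, inp$gene_ids, sets)
head(res[order(res$p_value), ], 1)
#>             set  k  K   n    N odds_ratio  p_value  q_value significant
#> 1 mito_reversed 50 50 253 1317        Inf 2.14e-38 1.71e-37        TRUE
```

The first merged cluster contains all 50 genes of the planted
"mitochondrial" archetype (overlap k = 50 of K = 50), enriched at
p ≈ 2×10⁻³⁸, while the decoy sets stay non-significant.

`run_pipeline(pipeline_config(seed = 7), "out/")` chains all stages —
simulation (or TSV ingestion), contrasts, overlap classification, SOM,
enrichment — writing per-stage TSV tables, `summary.json` and a run log;
the same config and seed give byte-identical summaries.

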