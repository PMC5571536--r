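---
title: "Methods: cross-tissue DEG contrasts, reversal classification, SOM modules and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-tissue DEG contrasts, reversal classification, SOM modules and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degsom)
```

# The analysis problem

A recurring design in studies of diabetic complications compares control
(`db/+`) and diabetic (`db/db`) mice, each with and without a drug such as
pioglitazone (PIO), across several tissues — here sciatic nerve (SCN),
dorsal root ganglia (DRG), kidney glomeruli (Glom) and kidney cortex. The
scientific questions are directional: which genes does disease perturb in
each tissue, which of those perturbations does the drug push *back*
(reversed) or push *further* (exacerbated), and which co-expression
patterns are conserved across tissues?

`degsom` implements this analysis as a reusable pipeline over a
genes-by-samples FPKM matrix:

1. **Pairwise contrasts** within each tissue (`call_degs`), FDR-gated at
   q < 0.05.
2. **Overlap classification** of genes shared between the disease
   contrast (control → diabetic) and the treatment contrast (diabetic →
   treated diabetic) into reversed vs. exacerbated (`classify_overlap`),
   with stratified sets for cross-tissue comparison
   (`stratify_deg_sets`, `cross_tissue_compare`).
3. **Co-expression module discovery** with a batch Kohonen
   self-organizing map on a 7 × 7 hexagonal lattice (`train_som` and
   friends), including U-matrix distances and merging of adjacent modules
   into clusters.
4. **Over-representation analysis** of any gene list against a GMT
   gene-set collection via one-sided Fisher's exact tests with
   Benjamini–Hochberg correction (`fisher_enrichment`,
   `enrichment_matrix`).

A synthetic-data generator (`generate_dataset`) emulates the four-tissue,
four-group design with planted ground truth and is the basis of the
package's validation.

# Differential expression

The DEG stage is deliberately simple and pluggable: a two-sided Welch
t-test on `log2(FPKM + 1)` replicate values, per gene, within one tissue.
Count-model machinery (dispersion estimation, isoform deconvolution) is
out of scope because every downstream step consumes only the triplet
(p-value, q-value, fold-change sign); a different test can be substituted
behind the same interface. The +1 pseudocount makes an FPKM of zero
representable on the log scale and is used consistently in both the test
and the fold change `log2((mean_alt + 1) / (mean_ref + 1))`.

Choices that matter:

* **FDR control.** Benjamini–Hochberg within each contrast (per tissue),
  strict inequality q < 0.05. Adjusting per contrast, rather than across
  all contrasts globally, is the most common reading of per-tissue DEG
  reporting and keeps contrasts independent of each other.
* **Degenerate genes.** A gene with zero variance in both groups gets
  p = 1 when the group means are equal (no evidence) and p = 0 when they
  differ (a deterministic difference); both cases are vanishingly rare on
  real data but keep the test total.
* **No expression floor.** Genes are tested unfiltered; the expression
  floor belongs to the SOM stage only.

# Reversal / exacerbation classification

Orientation is fixed: the disease contrast is control → disease and the
treatment contrast disease → treated disease, both "alternative minus
reference" on the log2 scale. For a gene significant in both, the product
of the two signs decides the class: −1 reversed, +1 exacerbated.
"Reversal" is thus purely directional — no requirement that the treated
mean returns within some distance of control — because the class
definition in this analysis tradition is directional. Genes significant
only under treatment are reported (`treatment_only`) but excluded from
the percentages, which are percentages *of the shared set*. No magnitude
floor is applied to fold changes anywhere, because none is part of the
method; and the intersection is of hard-thresholded sets, with no
conjunction p-value.

# The self-organizing map

The SOM is the package's own implementation (no SOM library is used):

* **Input.** Per-gene profiles over a small panel of conditions — by
  default six: `db/+`, `db/db`, `db/db PIO` in SCN and glomeruli. The SOM
  consumes *condition means*, not replicate columns, because the module
  patterns of interest are defined across groups. Genes whose maximum
  condition-mean FPKM is below 3 are removed, then profiles are
  `log2(mean + 1)`-transformed and centred to row mean zero, so the map
  clusters *shapes*, not expression levels. The floor rule "maximum
  condition mean < 3" is one documented reading of "expression below
  log₂3"; it is a single switch (`min_fpkm`) and removes roughly the
  nontrivial fraction of low-expressed genes one expects from an
  FPKM abundance spectrum.
* **Lattice.** 7 × 7 hexagonal, odd-r offset rows, modules numbered 1–49
  row-major. Hex adjacency (each interior module has six neighbours) is
  what makes "adjacent modules" well defined for merging; distances on
  the lattice are integer axial hex distances.
* **Training.** *Batch* Kohonen updates: each epoch assigns every gene to
  its best-matching unit (BMU, Euclidean distance; exact ties go to the
  lowest module index) and then sets every codebook vector to the
  Gaussian-neighbourhood-weighted mean of all profiles. Batch training is
  used instead of online updates because it is deterministic given the
  seed and independent of gene order. The neighbourhood radius decays
  linearly from `max(width, height)/2` to 0.5 over 50 epochs (defaults);
  the final value 0.5 keeps a mild neighbour pull
  (weight e^−2 ≈ 0.14 at lattice distance 1) that preserves topology
  without smearing modules. The codebook initializes by seeded sampling
  of input profiles. In the limit radius → 0 one batch epoch is exactly
  one Lloyd k-means step with k = width × height, a property the test
  suite checks against `stats::kmeans`.
* **U-matrix and clusters.** The U-matrix reports the codebook distance
  across every adjacent module pair; ridges of high distance mark borders
  between module territories. Merging has two modes: an explicit,
  lattice-connected module list (the "hand-picked cluster" workflow, e.g.
  modules 42 and 49, which are adjacent on this lattice), or automatic
  merging of adjacent modules whose codebooks correlate at ≥ 0.8
  (Pearson). Threshold merging considers only modules with at least one
  assigned gene: an empty module represents no genes, and its
  interpolating codebook could otherwise bridge two unrelated
  territories into one cluster.

Numerical identity with any particular toolbox's module numbering is not
a goal and is not claimed; the map's *properties* (BMU correctness,
quantization-error behaviour, topology preservation, archetype recovery)
are what the tests pin down.

# Enrichment

Over-representation only (upper-tail), matching how annotation tools
report enrichment: with `N` universe genes, `K` in the set, list size `n`
and overlap `k`, p = P(X ≥ k), X ~ Hypergeom(N, K, n), computed via the
exact hypergeometric tail. Set members are intersected with the universe
first; K = 0 yields p = 1. BH correction runs across all sets tested for
one list (the per-analysis family). The background universe is explicit
and configurable because published analyses rarely state theirs: the
pipeline uses all genes of the matrix for DEG strata and the
SOM-filtered genes for SOM clusters. The significance-matrix view
(`enrichment_matrix`) arranges −log10 p values with average-linkage
hierarchical clustering on Euclidean distances, inputs pre-sorted by
label so leaf order is deterministic.

# The synthetic-data generator

`generate_dataset` emulates the study design the pipeline targets; it is
a fixed experimental condition, not a tuning knob.

* **Design.** 4 tissues × 4 groups × 6 replicates (96 samples), 4,000
  genes by default.
* **Baseline.** log2(FPKM+1) ~ Exponential(mean 3), giving the
  right-skewed FPKM spectrum in which an FPKM-3 floor removes a
  substantial minority of genes.
* **Effects.** Per tissue, a fraction of genes receive a signed disease
  effect, split into reversed / exacerbated / disease-only; a further 5%
  respond to treatment alone. Effects compose additively on the log2
  scale; the disease effect applies to `db/db`-genotype groups and the
  treatment effect to PIO groups, so reversed genes return toward
  baseline in `db/db PIO`. Effect magnitudes are |N(2, 0.5)| (log2
  units, truncated below at 0.25); replicate noise is Gaussian with
  sd 0.25 on the log2 scale. The default per-tissue fractions mirror the
  qualitative pattern the pipeline is meant to resolve: a large disease
  signature in nerve and glomeruli, near-complete reversal of shared
  genes in glomeruli (~95%) versus about half in nerve, and only small
  shared sets in DRG and cortex.
* **Modules.** Three planted archetypes (50 genes each, scale 1.5 log2
  units) defined over the six focal conditions: a conserved-but-opposite
  "mitochondrial" pattern (down-and-reversed in SCN, up-and-reversed in
  Glom), an "inflammation" pattern (induced in both, reversed only in
  Glom), and a stable tissue offset. Module genes' truth roles are
  derived from their archetype profile, so the truth table accounts for
  everything planted.
* **Determinism.** One seed in the config; identical configs produce
  bit-identical matrices. The pipeline derives per-stage seeds from its
  single master seed by fixed offsets.

What the generator does **not** model — and therefore what passing tests
cannot certify about real data: count-level (negative binomial)
noise, library-size and gene-length biases, batch effects, dropout,
correlated genes outside the planted modules, and annotation noise in
gene sets. One intentional artefact of the FPKM scale is worth knowing:
values truncate at zero, so a strong *down* effect on a low baseline
saturates, which slightly lowers the detectability of exacerbated-down
genes in the treatment contrast and can push the estimated reversed
percentage a few points above the planted value in the nerve analog
(still within binomial error in the validation runs).

# Validation scales

The test suite validates each stage against independent oracles:
brute-force step-up adjustment for BH (1,000 random vectors), exhaustive
hypergeometric-tail enumeration for Fisher (instances with N ≤ 60,
tolerance 1e-12, plus the closed-form case p = 2/9), `stats::t.test` for
the vectorised Welch test, brute-force nearest-neighbour scans for BMU
assignment, and one-step `stats::kmeans` for the zero-radius limit.
Calibration and recovery use simulation at these sizes, chosen to give
tight Monte Carlo error while keeping the default test run fast:
5,000-gene global-null and 2,000-gene power simulations over 200 seeds
each (n = 6 vs 6); reversal recovery on a 4,000-gene two-tissue dataset
with ≥ 200 planted shared DEGs per tissue; SOM archetype recovery with
3 × 50 genes at noise sd 0.1 (adjusted Rand index ≥ 0.9 against
threshold-merged clusters); and 100 seeded enrichment runs with 5 decoy
sets each. End-to-end determinism is asserted by byte-comparing the JSON
summaries of two identical pipeline runs.

# Known limitations

* The Welch-on-log-FPKM test is a stand-in for count-based models; on
  real RNA-Seq data a negative-binomial test will be better calibrated at
  low counts.
* The reversed/exacerbated classes are sign-only; a gene nudged back by
  5% counts as reversed.
* SOM module numbering depends on the seed; only geometry-invariant
  quantities (cluster memberships, U-matrix structure, enrichment of
  clusters) are meaningful across runs.
* Enrichment p-values depend strongly on the chosen universe; the
  package makes the choice explicit rather than defensible-by-default.
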