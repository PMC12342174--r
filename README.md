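# mogfuse

Two-stage multi-omics cancer-subtype classification in R: supervised
per-omics feature learning with graph convolutional networks (GCNs) on
patient similarity graphs, similarity network fusion (SNF) of the per-omics
networks, and a two-head graph attention network (GAT) classifier on the
fused patient graph.

## Who this is for

Cohort studies with several molecular layers (copy number, methylation,
mRNA, protein) on the same few hundred patients, where subtype labels exist
and the question is whether integrating layers predicts subtype better than
the best single layer. Everything runs on plain delimited matrices — no
framework dependencies — and every stage is seeded and bit-reproducible.

## The method in brief

Per omics matrix $X \in \mathbb{R}^{n\times d}$, a patient affinity matrix
uses the scaled exponential kernel
$A_{ij}=\exp(-\rho_{ij}/(\mu\nu_{ij}))$ with squared Euclidean distance
$\rho$ and local scaling $\nu$ from the $k$-nearest-neighbour mean
distances ($k=20$, $\mu=0.5$). A **dynamic threshold search** keeps the
smallest top fraction $p \in \{0.01, 0.015, \dots\}$ of entries whose graph
has no isolated node, guaranteeing the row-normalised Laplacian
$L = D^{-1}A$ exists. A two-layer GCN
($H^{(1)}=\sigma(LH^{(0)}W_0+b_0)$, hidden width 100, ELU, dropout 0.5,
Adam lr 0.001, weight decay 0.01, cross-entropy masked to training rows) is
trained per view, and its **first-layer activations** become that view's
latent features. Selected views' latents are concatenated; their affinity
networks are fused by SNF cross-diffusion
($P^{(u)} \leftarrow S^{(u)}\bar P^{(-u)} S^{(u)\top}$, 20 sweeps); the
fused network is thresholded again and a two-head GAT
($\alpha_{ij} = \mathrm{softmax}_{j\in N_i}\,\mathrm{LeakyReLU}(a^\top[Wh_i\|Wh_j])$)
with a softmax head predicts subtypes. Metrics: accuracy and macro
precision/recall/F1 with a confusion matrix, computed on a stratified 25%
test partition (transductive: test samples are in the graphs, never in any
loss).

## Worked example

```r
library(mogfuse)

# Synthetic cohort: 150 samples, 3 subtypes, 2 omics views with
# complementary signal (neither view separates all subtypes alone).
sim <- simulate_multiomics(synthetic_config(seed = 7))
rec <- run_pipeline(sim$omics, sim$labels, pipeline_config(seed = 7))
print(rec)
```

```
Two-stage multi-omics run
  samples: 150, classes: C1, C3, C2
  omics1: p* = 0.010, validation accuracy = 0.818
  omics2: p* = 0.010, validation accuracy = 0.727
  selected omics: omics1, omics2
  fused network p* = 0.010
  test accuracy 1.0000 | macro P 1.0000 | macro R 1.0000 | macro F1 1.0000
```

Reading the output: each view's GCN alone reaches only ~0.7–0.8 validation
accuracy (each view was built to separate only part of the subtype
structure), while the fused pipeline classifies the held-out 38 samples
perfectly — integration recovered what no single layer carries. `p*` is the
smallest edge-retention fraction whose graph has no isolated patient.

Real data enter as one matrix per layer (samples in rows, or
`samples_in_columns = TRUE` for the transposed convention) plus a
two-column label table:

```r
rec <- run_pipeline(
  c(cna = "cna.tsv", meth = "meth.tsv", mrna = "mrna.tsv", rppa = "rppa.tsv"),
  "subtypes.tsv",
  pipeline_config(seed = 1),
  output_dir = "run1")   # metrics.json, predictions.tsv, confusion.tsv, ...
```

There is also a CLI (`inst/cli/mogfuse`):

```sh
mogfuse simulate --config sim.json --out data/
mogfuse run --config run.json
mogfuse sweep --config run.json --p-grid 0.01,0.11,0.21,0.31,0.41
mogfuse evaluate --pred run1/predictions.tsv --truth subtypes.tsv
```

## Layout

- `R/` — preprocessing/IO, affinity graphs + dynamic threshold, GCN, SNF,
  GAT + metrics, synthetic generator, pipeline, CLI.
- `tests/testthat/` — unit, property and oracle tests per module;
  `test-acceptance.R` holds the seven acceptance criteria.
- `vignettes/mogfuse-methods.Rmd` — model, assumptions, parameter meanings,
  numerical choices, and what the synthetic world does and does not
  establish.
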