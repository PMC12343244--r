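# MotifFuse

Molecular property prediction from SMILES that fuses **two structural
granularities**: a communicative message-passing encoder over the atomic
bond graph, and a **motif graph** built by chemistry-rule fragmentation,
blended through a dual-channel (global/local) masked attention stack. It is
aimed at cheminformatics practitioners and method developers who want a
fully inspectable, dependency-light R implementation of motif-aware
molecular representation learning — every stage from SMILES parsing to
attention heatmaps is a documented, tested function.

## The model

A molecule is a directed graph (two directed edges per bond) with
fixed-width atom/bond feature vectors. Two fragmentation rules produce the
motif level: (1) every acyclic bond incident to a ring system is cleaved;
(2) every acyclic atom with ≥ 3 heavy neighbors becomes a singleton motif.
The fragments partition the atoms; each motif's key is the canonical
SMILES of its induced fragment, indexed against a vocabulary with a
reserved `[UNK]`. The motif graph carries an appended `[GLOBAL]` node and
three matrices: adjacency **A**, shortest-path hop distances **D** (the
`[GLOBAL]` row/column is defined as 1), and the motif–atom association
**F**.

The atomic encoder iterates, for K rounds over directed edges e(u,v):

    m_v = SUM{h_uv} ⊙ MAX{h_uv}          (incoming edges, elementwise)
    h_v ← h_v + m_v
    h_uv ← ReLU(W_k (h_u − h_vu) + h_uv⁰)

followed by a communicate step `ReLU(W_c (h_v + m_v + x_v))` and a
bidirectional GRU readout with mean pooling → molecule embedding **M**.
Atomic features project onto motifs as `ReLU((1/m) F X W_G + b_G)`, are
added to trainable motif identity embeddings, and the fused matrix **H**
(global row reintroduced) passes through L stacked attention layers: the
feature dimension splits in half, the global channel's scores are
modulated by **D** and the local channel's by **A** —
`softmax((Q K' ⊙ D) / sqrt(d/2)) V` — with residual + LayerNorm. The final
representation is `M' = M + α·H'[GLOBAL]` with a learnable scalar α, fed
to a linear head. Ablation switches (`useDistance`, `useAdjacency`,
`useGlTransformer`) reproduce the without-distance / without-adjacency /
without-matrices / without-attention variants purely by configuration.

Training uses Adam with binary cross-entropy-with-logits (classification,
missing labels masked) or MSE (regression), scaffold-split 8:1:1
(Bemis–Murcko frameworks, largest clusters placed first), ROC-AUC / RMSE
metrics, and best-validation model selection. Gradients come from a small
reverse-mode tape engine internal to the package, verified against finite
differences in the test suite.

## Worked example

```r
library(MotifFuse)

g <- smilesToGraph("CC(C)(C)c1ccc(N)cc1")   # 4-tert-butylaniline
g
#> MolecularGraph: CC(c1ccc(cc1)N)(C)C
#>   11 atoms, 22 directed edges ( 11 bonds )

vapply(decomposeMotifs(g), `[[`, character(1), "motifKey")
#> [1] "C"        "C"        "c1ccccc1" "N"        "C"        "C"
```

Six motifs: the aromatic ring, the amino nitrogen, and four carbons — the
quaternary carbon is isolated by the branching rule, its methyls become
singletons. The motif graph's distance matrix (7th row/column is the
`[GLOBAL]` node, always at distance 1):

```r
vocab <- buildMotifVocabulary(c("CC(C)(C)c1ccc(N)cc1", "Cc1ccccc1", "CCO"))
distanceMatrix(buildMotifGraph(g, vocab = vocab))
#>      [,1] [,2] [,3] [,4] [,5] [,6] [,7]
#> [1,]    0    1    2    3    2    2    1
#> [2,]    1    0    1    2    1    1    1
#> [3,]    2    1    0    1    2    2    1
#> [4,]    3    2    1    0    3    3    1
#> [5,]    2    1    2    3    0    2    1
#> [6,]    2    1    2    3    2    0    1
#> [7,]    1    1    1    1    1    1    0
```

Train a small model on a synthetic nitrogen-detection task (200 generated
molecules, scaffold split):

```r
df <- makeFixtureDataset(200, seed = 0, recipe = "has_nitrogen")
fullVocab <- buildMotifVocabulary(df$smiles)
ds <- prepareDataset(df$smiles, df$label, vocab = fullVocab)
sp <- scaffoldSplit(ds$smiles)
cfg <- motifFuseConfig(hiddenSize = 32, taskType = "classification")
model <- motifFuseModel(fullVocab, cfg, seed = 0)
res <- trainModel(model, ds, sp$train, sp$val,
                  trainControl(lr = 1e-3, batchSize = 50, epochs = 20, seed = 0))
tail(res$log, 3)
#>    epoch  trainLoss valMetric
#> 18    18 0.14426369         1
#> 19    19 0.11413727         1
#> 20    20 0.09268657         1
```

The validation metric is ROC-AUC (1.0 = the held-out scaffolds separate
perfectly). Predictions return logits and sigmoid probabilities, with
unparseable SMILES reported rather than dropped:

```r
predictMolecules(res$model, c("Nc1ccc(Cl)cc1", "CCOC"))[, c("canonical", "prob_1")]
#>       canonical    prob_1
#> 1 Nc1ccc(cc1)Cl 0.7342293
#> 2          COCC 0.4128664
```

Attention heatmap input — the `[GLOBAL]` node's row of a global-channel
head, one weight per motif (ring, amine, carbons) plus the global node
itself:

```r
att <- exportAttention(res$model, "CC(C)(C)c1ccc(N)cc1")
round(att$global[[1]][att$globalIndex, ], 3)
#> [1] 0.165 0.148 0.094 0.115 0.165 0.165 0.148
```

A thin CLI wrapping the same functions ships in `inst/cli/motiffuse`
(`decompose`, `build-vocab`, `make-fixtures`, `train`, `predict`,
`attend`).

For tuning on real datasets, the documented search grid is learning rate
{1e-3, 5e-4, 1e-4} × batch size {64, 128, 256} × attention heads
{2, 4, 8}; no automated tuner is included.

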