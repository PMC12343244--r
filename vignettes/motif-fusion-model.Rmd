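---
title: "Dual-granularity molecular representation: model and methods"
author: "MotifFuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-granularity molecular representation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Predicting physicochemical and biological properties from a molecular
structure is a routine step in drug discovery and materials screening.
Graph neural networks operating on the atom/bond graph capture local
electronic effects well, but chemists reason equally in terms of larger
units — ring systems, functional groups, branch points — whose arrangement
drives solubility, permeability, toxicity. MotifFuse models both
granularities at once: an atomic-level message-passing encoder and a
motif-level graph, blended by a masked dual-channel attention mechanism.

## Motif graphs

A molecule parsed from SMILES (through Open Babel, via ChemmineOB) is
fragmented by two rules applied jointly:

1. every acyclic bond incident to a *ring system* (a maximal set of fused
   or spiro rings) is cleaved, separating ring systems from substituents
   and from directly bonded ring systems;
2. every acyclic atom with three or more heavy-atom neighbors becomes a
   singleton motif, all of its bonds cleaved.

The broken-bond set is computed first and connected components are taken
afterwards, so the result is independent of any rule ordering, and the
fragments always partition the atoms. Each fragment's key is the canonical
SMILES of the induced subgraph with cleaved attachment points reduced to
plain valence; a corpus of molecules yields a *motif vocabulary* of unique
keys, sorted lexicographically so indices never depend on corpus order,
with one reserved index for `[UNK]` (motifs unseen at build time).

A note on the fragmentation rules: a motif edge is drawn between two
motifs exactly when an original bond joins an atom of one to an atom of
the other. Describing motif connectivity via "shared atoms" is incompatible
with cleavage producing disjoint fragments, so the bond-crossing reading is
the only consistent one; likewise rule 1 is applied to *every* acyclic bond
touching a ring system (including biaryl-type ring-ring bonds), which is
what keeps a pendant phenyl separate from a fused core.

The motif graph of a molecule with $n$ motifs and $m$ atoms carries an
appended `[GLOBAL]` node and three matrices:

* $A \in \{0,1\}^{(n+1)\times(n+1)}$ — motif adjacency; the `[GLOBAL]`
  node is adjacent to every motif, consistent with its defined distance
  of 1;
* $D \in \mathbb{N}^{(n+1)\times(n+1)}$ — all-pairs shortest-path hop
  counts between motifs (breadth-first distances), with the `[GLOBAL]`
  row and column fixed to 1 and disconnected pairs given the finite
  sentinel $n+1$ (larger than any true path, and mask-friendly);
* $F \in \{0,1\}^{n\times m}$ — motif–atom membership, built from the
  fragments only (special nodes excluded); every column sums to 1.

## Atomic encoder

Atoms and bonds get fixed-width feature vectors: element one-hot over the
first 100 elements plus an "other" bucket, degree (0–5), formal charge
(−2..+2 plus other), hybridization, aromaticity, implicit hydrogen count
(0–4), and atomic mass scaled by 1/100; bonds carry a type one-hot
(single/double/triple/aromatic), a conjugation flag and a ring flag.
Perception beyond what the toolkit exports directly (implicit hydrogens,
hybridization, conjugation) uses a deliberately simple valence model
documented in the function help; it is deterministic and adequate for
organic SMILES, but it is not a full aromaticity/tautomer engine.

The encoder is a communicative message-passing network over the *directed*
bond graph. Writing $h_v^{(k)}$ and $h_{uv}^{(k)}$ for node and edge hidden
states at round $k$:

$$m_v^{(k)} = \mathrm{SUM}\{h_{uv}^{(k-1)}\} \odot \mathrm{MAX}\{h_{uv}^{(k-1)}\},
\qquad h_v^{(k)} = h_v^{(k-1)} + m_v^{(k)},$$

$$m_{uv}^{(k)} = h_u^{(k)} - h_{vu}^{(k-1)}, \qquad
h_{uv}^{(k)} = \sigma\!\left(W^{(k)} m_{uv}^{(k)} + h_{uv}^{(0)}\right),$$

with $\sigma$ = ReLU. The MAX is taken *elementwise* across incoming edge
features: that is the differentiable reading of "the strongest component
of the neighborhood", and the one we adopt (selecting a whole argmax edge
vector would be non-smooth and is not what comparable encoders do). After
$K$ rounds a final communicate step mixes the node state, a fresh
aggregation of the final edge states, and the input-projected atom feature
$x_v$:

$$h_v = \mathrm{ReLU}\!\left(W_c\,(h_v^{(K)} + m_v^{(K)} + x_v)\right).$$

The communicate parameterization (one linear map plus ReLU on the sum) is
our concrete choice where only the sum is specified. Input projections are
learned linear maps: atom features to width $d$, and source-atom features
concatenated with bond features to width $d$ for $h^{(0)}_{uv}$.

The molecule embedding $M$ comes from a readout: node embeddings in
canonical atom order are run through a bidirectional gated recurrent layer
(hidden width $d/2$ per direction) and the per-atom outputs are
mean-pooled. Canonicalizing the atom order before the recurrent pass makes
the readout deterministic across SMILES spellings of one molecule. A plain
mean readout is available as a config option.

Because molecules differ in atom count, batch-wise fusion pads each
molecule's atom matrix with zero rows to the batch maximum
($X^{pad}_i[j] = X_i[j]$ for $j < m_i$, else $0$). Padding is provably
inert downstream: $F$ only addresses real atom columns.

## Fusion

Atomic features are projected onto motifs through $F$:

$$H^{proj}_i = \mathrm{ReLU}\!\left(\tfrac{1}{m} F_i X_i W_G + b_G\right),$$

where $m$ is the *total* atom count of the molecule. The $1/m$ factor is
the normalization as specified in the source model; it damps scale but
does not fully remove the size bias its motivation mentions (a motif with
more atoms still aggregates more signal). A `perMotifNorm` option divides
by each motif's own atom count (row sums of $F$) instead, which is the
natural fix; the printed form remains the default for fidelity.

The structural projection is then added elementwise to each motif's
identity embedding from a trainable table (one row per vocabulary index,
`[UNK]` and `[GLOBAL]` included), and the `[GLOBAL]` node — set aside
during fusion, receiving no atomic signal — is reintroduced as the final
row. Addition (rather than concatenation or gating) keeps the two
information sources in one space, residual-style.

## Global-local attention

The fused matrix $H \in \mathbb{R}^{N\times d}$ ($N = n+1$) is split along
features into halves $H_g, H_l$. Each half runs multi-head scaled
dot-product attention, with scores modulated by a structure matrix before
the softmax:

$$\mathrm{Att}_g = \mathrm{softmax}\!\left(\frac{Q_g K_g^\top \odot D}{\sqrt{d/2}}\right) V_g,
\qquad
\mathrm{Att}_l = \mathrm{softmax}\!\left(\frac{Q_l K_l^\top \odot A}{\sqrt{d/2}}\right) V_l.$$

The layer output is $\mathrm{LayerNorm}(H + [\mathrm{Att}_g \,\|\,
\mathrm{Att}_l])$, stacked $L$ times. The distance channel sees the whole
topology (longer paths weigh scores up or down smoothly); the adjacency
channel focuses each motif on its direct chemical environment.

Numerical choices worth knowing:

* **Mask semantics.** The masks *multiply raw scores*, exactly as the
  model equations are written. A zero mask entry therefore produces a
  score of 0 — not $-\infty$ — and still receives softmax weight. This is
  a faithful but slightly unusual semantics (a motif not adjacent to
  anything in the local channel attends uniformly); an
  `additive_neg_inf` mode that excludes zero-mask pairs entirely is
  provided as a configuration alternative, as is `selfLoops` to put 1s on
  the adjacency diagonal.
* **Distance values.** $D$ enters as raw hop counts (with the $n+1$
  sentinel); no decay transform is applied because none is specified. A
  `reciprocal` transform ($1/D$ off-diagonal) is available behind
  `distanceTransform`.
* **Scaling.** Scores divide by $\sqrt{d/2}$ (the channel width), for any
  head count; per-channel projection matrices are $(d/2)\times(d/2)$ and
  their columns split evenly across heads.
* **Batching.** Training batches all molecules' motif rows into one
  block-diagonal system; cross-molecule score entries are forced to
  $-\infty$ additively, which reproduces the per-molecule softmax
  exactly. The test suite asserts bitwise-level agreement between the
  batched training path and the per-molecule inference path.

The refined matrix $H'$ is collapsed to a vector by taking the `[GLOBAL]`
row — that node exists precisely to aggregate graph-level information, and
this resolves the dimensional mismatch in combining a matrix $H'$ with the
vector $M$ (mean pooling over motif rows is the config alternative). The
final representation is

$$M' = M + \alpha\, H'[\mathrm{GLOBAL}],$$

with $\alpha$ a learnable scalar initialized at 0.1 (small enough that the
motif branch starts as a gentle residual; the initial value is our
choice). A single linear head maps $M'$ to the targets. With $\alpha = 0$,
or with the stack bypassed, $M' = M$ exactly — which is also how the
"without attention" ablation is wired.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `hiddenSize` | 256 | shared width $d$ of encoder and attention (dimensionless); even, and $d/2$ divisible by the head count |
| `depth` | 3 | message-passing rounds $K$ (each round extends the receptive field by one bond) |
| `attnLayers` | 2 | stacked attention layers $L$ |
| `headsPerChannel` | 4 | heads in each of the two channels |
| `alphaInit` | 0.1 | starting value of the residual scale $\alpha$ |
| `maskMode` | multiplicative | how $A$/$D$ enter the scores |
| `readout` | gru_mean | bidirectional recurrent readout with mean pooling |
| `lr`, `batchSize`, `epochs` | 1e-4, 256, 100 | the reference training recipe (Adam); binary cross-entropy with logits for classification, mean squared error for regression |

The hidden width of 256 matches the reference configuration; $K$ and $L$
are exposed because no single value is canonical. The documented
hyperparameter grid for tuning on real data is learning rate
{1e-3, 5e-4, 1e-4} × batch size {64, 128, 256} × heads {2, 4, 8}; this
package documents the grid but deliberately ships no automated tuner.

## Training machinery

No automatic-differentiation framework is available to R in this package's
dependency footprint, so training runs on a small reverse-mode tape engine
written here: roughly fifteen matrix operations (matmul, elementwise
arithmetic, ReLU/sigmoid/tanh, row softmax with $-\infty$ support, row
layer-norm, gather/scatter/group-max, and the two losses), each with an
analytic backward rule. The engine is validated against central finite
differences both per-operation and end-to-end through the full model, and
the tape forward is asserted equal to the independent inference-path
implementation. The optimizer is standard Adam. Missing labels in
multi-task classification are masked out of the loss; model selection
takes the epoch with the best validation metric (the reference recipe
fixes the epoch count but not a checkpoint policy, so best-validation is
our choice, and no early stopping or learning-rate schedule is applied).

## Scaffold splitting

Generalization is assessed with a scaffold split: each molecule's
Bemis–Murcko framework (terminal atoms on single non-ring bonds stripped
iteratively; acyclic molecules keep their canonical SMILES as their own
key) groups it with all molecules sharing that framework. Clusters are
sorted by size, largest first with lexicographic tie-breaks, and each is
assigned greedily to the split furthest below its 8:1:1 quota. The
procedure is fully deterministic; with all-singleton scaffolds the split
sizes are exact. When every molecule shares one scaffold the package warns
and places everything in the training split.

## The synthetic generator, and what passing tests do not show

All tests and the acceptance script run on molecules from a fixed template
grammar: benzene, pyridine and cyclohexane cores; 0–3 substituents drawn
from methyl, amino, carboxyl, halogens and tert-butyl; optionally a second
core joined by a short alkyl linker. The grammar guarantees chemical
validity without a valence-repair pass and covers both fragmentation rules
by construction (any substituted core exercises rule 1; tert-butyl's
quaternary carbon exercises rule 2, and one such molecule is always
included). Generation canonicalizes, deduplicates and refills,
deterministically for a given `(n, seed)`, up to a documented capacity of
20,000 distinct molecules.

Label recipes are structural: `ring_count` (cyclomatic number),
`has_nitrogen`, and `motif_weighted` (amino-group count minus halogen
count plus Gaussian noise of σ = 0.1) — the last designed so that the
*identity* of motifs, not molecule size, carries the signal.

These fixtures emulate smallish drug-like topology; they do not emulate
real property distributions, activity cliffs, measurement noise structure,
stereochemistry, charged/tautomeric states, or the motif diversity of a
real corpus (a large public compound collection yields a vocabulary four
orders of magnitude larger). Learnability results on fixtures demonstrate
that the machinery trains and that the motif branch contributes; they say
nothing quantitative about benchmark performance on real datasets, which
additionally requires GPU-scale training.

The checks use deliberately modest problem sizes, chosen once as this
package's reference conditions: 400 molecules (seed 0) with a 32-unit
hidden width, 30 epochs at learning rate 1e-3 and batch size 50 for the
learnability tasks; 200 molecules and 10 epochs for the ablation
comparison; oracle equivalence on molecules of up to 6 atoms at width 4.

## Known limitations

* Aromaticity, hydrogen counts and conjugation come from a simplified
  valence model on top of the toolkit's canonical SMILES; exotic
  heterocycles, organometallics and hypervalent species may featurize
  approximately (they never error — unknown elements bucket to "other").
* Stereochemistry is not featurized, and no 3D information is used; the
  directed-graph machinery is ready for such extensions but none are
  implemented.
* The multiplicative mask's zero-score behavior (see above) is kept for
  fidelity; users wanting strict exclusion should set
  `maskMode = "additive_neg_inf"`.
* Training is CPU-bound R; it is intended for method study and small
  datasets, not large-scale benchmarking.
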