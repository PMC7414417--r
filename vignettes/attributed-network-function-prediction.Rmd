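---
title: "Predicting protein function from attributed networks: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein function from attributed networks: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goembed)
```

This vignette explains the model the package implements, the assumptions
behind it, the tunable parameters and their defaults, what the synthetic data
generator does and does not emulate, and the numerical and design choices
that were genuinely open. It states no empirical number that the test suite
or `scripts/acceptance.R` does not itself compute.

## The model

The method is a two-stage, transductive architecture.

**Stage 1 — unsupervised embedding.** Two undirected graphs are built over
one shared protein index. The protein–protein interaction (PPI) graph keeps
pairs with interaction confidence strictly above 300 (STRING-style 0–1000
combined scores); the sequence similarity network (SSN) keeps pairs with
alignment e-value strictly below 1e-4, symmetrized by union of hit
directions. Adjacencies are binary — confidence values are used only for
thresholding, not as edge weights. Self-loops are enforced (`A + I`) and the
graph convolution uses the symmetrically normalized adjacency
`Ã = D^(-1/2) A D^(-1/2)`. (A row-stochastic `D^(-1) A` variant exists
behind a flag; the symmetric form is the default and the one the tests pin
down, since it is the formula of the underlying graph-convolution
literature. Its row sums are generally not 1, despite the loose "averaging
over neighbors" intuition.)

Each protein carries a feature vector `x_i`, the concatenation of:

* the conjoint-triad (CT) encoding of its sequence — residues mapped to 7
  physicochemical classes, raw counts of all `7³ = 343` ordered class
  triads. The class partition `{A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W},
  {R,K}, {D,E}, {C}` is the published conjoint-triad partition, exposed as a
  configurable table (`ct_class_map()`) because it is an adopted convention,
  not something the data pin down. Triads are linearized as
  `idx(c1,c2,c3) = (c1-1)·49 + (c2-1)·7 + c3`. Sequences containing the
  ambiguous letters B, O, J, U, X, Z cannot be CT-encoded and are dropped.
* a binary bag-of-words over subcellular locations (vocabulary = every
  observed term; proteins without annotation get all zeros), and
* a binary bag-of-words over domain terms, keeping terms that occur strictly
  more than 5 times (a strict inequality; the boundary is tested).

The SSN never receives the CT block: its edges already are sequence
similarity, and duplicating that signal as node attributes adds nothing the
decoder can check.

A variational graph auto-encoder (VGAE) is trained per graph: the two-layer
GCN encoder emits per-node Gaussian parameters, one reparameterized sample
`Z = μ + σ ⊙ ε` feeds the inner-product decoder
`p(A_ij) = sigmoid(z_i · z_j)`, and the loss is the negative evidence lower
bound: a positively re-weighted reconstruction cross-entropy over all `N²`
entries (positive weight `(N² − nnz)/nnz`, overall scale
`N²/(2(N² − nnz))` — without this the loss on a sparse graph is minimized by
predicting "no edge" everywhere) plus the closed-form Gaussian KL divergence
averaged per node. The exported embedding is the latent mean `μ`, not a
sample. Training is full batch: at the scale this package targets the dense
`N × N` decoder output fits comfortably in memory, and the underlying
formulation defines no mini-batching.

**Stage 2 — supervised classification.** The PPI and SSN embeddings are
concatenated (PPI block first) and one feed-forward network per GO namespace
maps them to per-term probabilities: hidden layers with
dense → batch-normalization → ReLU → dropout, a logistic output layer, and
mean binary cross-entropy over all (protein, term) entries. Annotations are
first filtered to the eight experimental evidence codes (EXP, IDA, IPI, IMP,
IGI, IEP, TAS, IC — case-sensitive, applied before propagation so ancestors
inherit no code), then closed upward through the GO DAG over `is_a` and
`part_of` (the true-path rule; `regulates` is not traversed, matching
standard GO practice — the traversed relation set is configurable).

The embedding stage is deliberately transductive: both VGAEs see the whole
graph, unlabeled proteins included, before any train/test split; only the
classifier respects the split. This mirrors the two-stage design of
embedding-based function predictors and is why the pipeline reports say so
prominently — performance numbers quantify label generalization, not
generalization to unseen graph nodes.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `ppi_score_threshold` | 300 | strict lower bound on interaction confidence (0–1000 scale) |
| `ssn_evalue_threshold` | 1e-4 | strict upper bound on hit e-value |
| `domain_min_occurrences` | 5 | domain vocabulary cutoff (strictly more than) |
| `vgae$hidden`, `vgae$latent` | 800, 400 | GCN layer widths; the funnel order (wide hidden, narrower latent) is the conventional reading of a "400 and 800 neuron" two-layer encoder |
| `vgae$epochs`, `vgae$learning_rate` | 200, 0.001 | full-batch Adam |
| `kl_warmup` | 50 | epochs over which the KL weight ramps 0 → 1 |
| `classifier$hidden` | 1024/512/256 | per-namespace classifier |
| `classifier$dropout`, `epochs`, `learning_rate` | 0.3, 100, 0.001 | Adam, full batch |
| `test_fraction` | 0.2 | held-out protein fraction |
| `min_term_proteins` | 11 | a term becomes a label if ≥ 11 proteins carry it after closure |
| `thresholds` | 0, 0.01, …, 1 | F-max sweep grid |

Open choices resolved here, with reasons:

* **Encoder head split.** The encoder's `[μ; log σ]` output is implemented
  as one shared first layer and two second-layer heads (`W_mu`, `W_sigma`),
  following the cited variational formulation.
* **Weight initialization** is Glorot uniform `±sqrt(6/(fan_in+fan_out))`.
* **KL warm-up.** At initialization the KL term dominates the weighted
  reconstruction term by an order of magnitude, and on small attribute sets
  the optimizer can reach `μ = 0, σ = 1` exactly by driving the shared ReLU
  layer dead — a local minimum it never leaves (posterior collapse). Ramping
  the KL weight linearly over the first 50 epochs removes the failure mode
  without changing the objective being minimized at convergence; the
  reported loss history always contains the unweighted terms.
* **Attribute standardization.** Raw CT counts scale with sequence length
  (tens), location/domain bits are 0/1. Mixed scales make the first-layer
  pre-activations — and training quality — depend on which block happens to
  dominate; the pipeline therefore z-scores every attribute column by
  default (`standardize_attributes`). The CT *encoding* itself keeps raw
  counts (an optional per-sequence normalization flag exists but is off, as
  counting occurrence numbers is the defined encoding).
* **Classifier layer order** dense → BN → dropout, hidden activation ReLU,
  output logistic. The layer-order and activation choice inside "a dropout
  layer and a batch normalization layer between dense layers" is
  underdetermined; BN-before-dropout is the common ordering and is
  configurable in principle by editing one loop.
* **Threshold convention.** A pair is predicted when `score ≥ t` (ties
  predict), so `t = 0` means "predict everything". One consequence, pinned
  by a test: all-zero scores still yield a nonzero F at `t = 0`; the
  "no prediction at any threshold" branch (F-max 0 with a warning) requires
  a grid that excludes the attainable scores.
* **Homology-transfer tie-breaks**: lowest e-value, then highest bit score,
  then lexicographically smallest subject id — any deterministic rule works,
  this one is stated and tested. Homolog removal drops training proteins
  with any hit to a test protein at strictly more than 50 % identity, in
  either hit orientation.
* **Metric edge cases.** Thresholds where nothing is predicted have
  undefined precision and are skipped in the F-max maximization. Per-term
  AUPR sweeps the distinct score values in descending order, so every sweep
  point has at least one prediction and recall is non-decreasing; the area
  is the step sum `Σ (rc_t − rc_{t−1}) pr_t` exactly (no trapezoid). Terms
  with no positive example in the evaluation split are excluded and the
  evaluated-term count reduced. The three namespace roots are excluded from
  label sets — after closure they are positive for every annotated protein.

## The synthetic data generator

`generate_fixture()` produces the statistical structure the method assumes,
fully determined by one seed: `n` proteins (default 200) in `k` balanced
communities (default 4); two planted-partition graphs over them — edges
within a community appear with probability `p_in`, between with `p_out` —
written as a scored interaction table (true edges scored 400–999, plus 10 %
sub-threshold noise rows the builder must drop) and a BLAST-style hit table
(true hits with e-values 1e-30–1e-5, noise hits above 1e-4); random
sequences of 50–500 standard residues; location/domain bits that follow a
per-community binary prototype with probability `attr_signal` (default 0.9)
and flip otherwise, plus three deliberately rare domain terms that fall
under the vocabulary cutoff; and a three-level toy GO DAG per namespace
(root, 4 mid terms, 16 leaves, some diamonds) whose leaves are attached to
communities — a protein is annotated with an on-community leaf with
probability `label_signal` (default 0.9), an off-community leaf with
probability `1 − label_signal`, 90 % of direct annotations carrying
experimental codes and 10 % IEA for the evidence filter to drop, then
ancestor-closed by construction.

Default densities (`ppi_p_in = 0.5, ppi_p_out = 0.005`; SSN 0.4/0.005) are
chosen to emulate the dense, strongly modular character of real
STRING-scale networks (where mean degree is in the hundreds) at 200 nodes:
mean within-community degree ≈ 25. Density matters for one subtle reason:
in a planted-partition model all within-community pairs are exchangeable, so
a held-out within-community edge can only be separated from a
within-community non-edge by how much probability mass the planted signal
concentrates inside communities. With sparse communities the achievable
held-out link-prediction AUC is capped well below what any competent model
should be asked to demonstrate; the dense defaults put the ceiling near
0.92, so the structure-learning tests measure the model, not the fixture.

What the generator does **not** emulate: real degree heterogeneity (hubs),
overlapping functional modules, sequence-driven similarity (e-values are
sampled, never computed from the random sequences — the package consumes hit
tables and never runs an aligner), realistic GO topology (depth 3,
regular branching), annotation incompleteness bias, and cross-namespace
correlation. Passing tests therefore show that the implementation recovers
planted community-functional structure under the model's assumptions — not
that it attains any particular accuracy on real proteomes.

## Problem sizes used by the tests and the acceptance script

The `vgae()` and `mlp_classifier()` defaults are the full-scale settings
(800/400 encoder, 1024/512/256 classifier). The test suite and
`scripts/acceptance.R` run the 200-protein fixture with proportionally
smaller models — encoder 256/128 (512/256 for the link-prediction check),
classifier 128/64, learning rate 0.01, 150/60 epochs — which recover the
planted structure just as reliably at this scale and keep the whole suite
fast on one CPU. These sizes are the package's choice of test conditions,
stated here so they are not mistaken for tuned quantities; the qualitative
claims they support (structure learned, combined ≥ single network, model >
shuffled control and > homology baseline) are stable across seeds.

## Known limitations

* Full-batch training materializes the dense `N × N` decoded matrix;
  practical up to a few thousand proteins, not proteome scale without
  mini-batching or subsampling (out of scope here).
* Per-term probabilities are not calibrated, and predictions are not forced
  to be hierarchy-consistent across the GO DAG; a child can outscore its
  parent.
* The OBO reader covers the tags the pipeline needs (`id`, `name`,
  `namespace`, `is_a`, `relationship: part_of`, `is_obsolete`), not the full
  format; obsolete-term remapping is not attempted.
* Evidence filtering keeps the standard eight experimental codes; electronic
  annotations are simply discarded, not rescued.
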