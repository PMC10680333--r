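---
title: "Methods: next-tool recommendation for scientific workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: next-tool recommendation for scientific workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Platforms such as Galaxy let scientists chain command-line tools into
*workflows*: directed acyclic graphs (DAGs) whose nodes are tools and whose
edges are data connections. With thousands of available tools, a central
usability question is: *given the tools a user has already connected, which
tool is a sensible next step?* flowrec treats this as supervised sequence
learning on a corpus of historical workflows. Because several tools can
legitimately follow the same partial workflow, the problem is **multi-label**:
the target for a tool-sequence prefix is the *set* of tools observed to follow
that prefix anywhere in the corpus.

The pipeline has four stages:

1. **Corpus mining** (`parse_workflow()`, `enumerate_linear_sequences()`):
   each workflow DAG is decomposed into its maximal linear tool sequences —
   every simple path from an in-degree-0 tool to an out-degree-0 tool, length
   at least 2. Non-tool steps (data inputs, parameter inputs) are contracted
   out of the graph, preserving tool-to-tool connectivity.
2. **Dataset construction** (`build_vocabulary()`, `derive_labeled_samples()`):
   every proper prefix of every sequence becomes a sample; its label set is
   the union, over the whole corpus, of tools that immediately follow the
   prefix. Prefixes are encoded as integer vectors of fixed length `N = 25`
   (left-padded with the reserved index 0, truncated to the most recent 25
   tools) and labels as multi-hot vectors.
3. **Model training** (`build_model()`, `train()`): a transformer encoder is
   the recommendation model; stacked-GRU, CNN and dense (DNN) comparators
   share the same input/output contract. All are trained with Adam
   (learning rate 0.001) on element-wise binary cross-entropy over sigmoid
   outputs, using frequency-balanced batches.
4. **Serving** (`save_bundle()`, `recommend_tools()`): the trained weights,
   vocabulary and configuration are saved in one bundle file; at query time
   scores are ranked, deprecated tools filtered, and the survivors re-ranked
   by recent usage.

## Model architectures

All four models map an encoded prefix (length-`N` integer vector) to a
`V + 1`-dimensional sigmoid score vector (`V` tools plus the unused padding
slot, which is excluded from the loss and from every ranking).

**Transformer encoder** (the recommender). Token embeddings and learned
positional embeddings (both `d_model`-dimensional) are summed, then one
encoder block is applied: multi-head self-attention (`n_heads = 4` heads of
dimension `head_dim`, padding keys masked with an additive −10⁹ before the
softmax), a residual connection and layer normalisation, a position-wise
feed-forward network of two dense layers, a second residual + layer norm. The
representation at the **final sequence position** (the most recently added
tool — the position whose successor we are predicting) is pooled, passed
through one ReLU dense layer, and projected to the output. Dropout 0.2 is
applied after the embedding sum, the attention block, the FFN and the hidden
dense layer during training.

**Comparators.** The RNN stacks two GRU layers (reset-after gate convention);
the CNN treats the `N × d_model` embedding matrix as a one-channel image
(16×3 valid convolution, 128 filters, 2×2 max-pool, flatten, 128-unit dense);
the DNN flattens the embedding matrix directly into two 128-unit dense
layers.

At the full published scale (vocabulary 2,354; `d_model = 128`) the builders
reproduce the reference trainable-parameter counts exactly:

| model | parameters |
|---|---|
| transformer | 922,291 |
| CNN | 5,772,723 |
| DNN | 1,031,603 |

Two conventions matter for these counts and are fixed in `model_config()`:
the transformer's input embedding has `V + 1` rows (padding only), while the
RNN/CNN/DNN embeddings have `V + 2` rows (padding plus an out-of-vocabulary
row); the output dimension is always `V + 1`. The reference RNN count
(241,063) is inconsistent with a 2,354-tool vocabulary under any standard GRU
convention (it implies a vocabulary of roughly 167), so the package
implements the described architecture and does not treat that number as a
target; the closed form under our conventions gives 803,507.

Where the source description is silent we chose: pooling at the final
sequence position (rather than flattening or averaging), because it is the
position causally adjacent to the predicted tool; and BCE computed in a
numerically stable with-logits form.

## The neural-network engine

No deep-learning framework is assumed: the package carries a compact
reverse-mode automatic-differentiation engine (`R/nn-autograd.R`) providing
exactly the operations the four architectures need — matrix product, bias
add, ReLU, inverted dropout, layer normalisation, embedding lookup,
multi-head attention with padding masks, reset-after GRU (backpropagation
through time), im2col-based 2-D convolution with max pooling, and a masked
BCE-with-logits loss — plus the Adam optimiser (β₁ = 0.9, β₂ = 0.999,
ε = 10⁻⁷). Every operation's gradient is validated against central finite
differences in the test suite (relative errors below 10⁻⁴ for all four
architectures).

## Frequency-balanced training batches

Tool usage is heavily skewed: a handful of utilities dominate real corpora.
Uniform sampling would starve rare tools of gradient signal. flowrec's
concretization (`assign_frequency_bins()`, `sample_balanced_batch()`): each
tool is assigned to one of four bins by the quartiles of its *label
frequency* (how often it appears as a true next-tool across the training
split); each batch slot first draws a bin uniformly, then a training sample
whose label set touches that bin (with replacement). Tools that never occur
as labels join the rarest bin. Empty bins are skipped with a warning, so the
scheme degrades gracefully to uniform sampling on unskewed data.

## Evaluation

`precision_at_k()` is the fraction of the `k` highest-scoring positions that
are true labels, with ties broken by ascending index so the metric is
deterministic. The default policy sets `k` to each sample's own number of
true labels; a fixed integer `k` is also supported.
`evaluate_infrequent_tools()` restricts the test set to samples whose label
set touches the lowest-frequency bin — the recommender's hardest quartile.
`measure_usage_time()` reports the median wall time to rebuild a model from
its bundle plus one forward pass: the latency a workflow editor pays per
recommendation request.

## Synthetic corpus generator

Real workflow corpora are large and external, so the package generates its
own study material with *known ground truth* (`generate_grammar()`,
`generate_workflow_corpus()`):

- Tools are arranged in `max_depth` layers; each non-terminal tool draws
  `branching_factor` successors from the next layer, so the successor graph
  is acyclic by construction and the true next-tool set of any prefix is
  exactly the successor set of its last tool (`ground_truth_labels()`).
- Per-tool popularity weights follow a Pareto law
  (`w = u^(-1/skew_exponent)`, `u ~ U(0,1)`), emulating the skewed usage
  distribution of real tool corpora.
- Workflows are weighted random walks through the grammar; with probability
  `branch_prob` a node expands *all* its successors, creating the
  multi-successor nodes that make the task multi-label. At `branch_prob = 1`
  the corpus exhausts the grammar, so observed label sets equal ground
  truth — the regime used for the recovery study below.

The generator emulates DAG structure, skewed popularity and multi-label
ambiguity. It does **not** emulate tool semantics, version churn, noisy or
abandoned workflows, or long-range dependencies beyond the layer structure —
conclusions about those require real corpora.

## The desk-scale recovery study

`scripts/acceptance.R` (and the mirrored test in
`tests/testthat/test-acceptance.R`) runs the package's own headline
experiment, sized to minutes on one CPU: a 48-tool, 8-layer grammar with
branching 2; a 60-workflow exhaustive corpus; a tiny transformer
(`d_model = 32`, 4 heads × 8, batch 64) and a matched DNN, each trained for
2,000 iterations. Because the corpus exhausts the deterministic grammar, a
sufficiently expressive model can reach precision@k = 1; the acceptance
contract is transformer ≥ 0.95 with the DNN at or below it, mirroring the
published ordering at desk scale. The published full-scale numbers
(precision ≈ 0.98 on ~798,000 real sequences, sub-second usage time on the
production vocabulary) require the real corpus and are deliberately out of
scope.

## Numerical and format choices

- **Determinism.** Every stochastic step (grammar, corpus, split, batch
  sampling, dropout, weight init) is governed by an explicit seed, and
  functions that seed internally save and restore the caller's RNG state.
  The dataset container is written with canonical JSON settings so the same
  seed produces a byte-identical file.
- **Bundles.** A bundle is one JSON file with three groups — `config`,
  `vocabulary`, `weights` — where each weight tensor is base64-encoded
  little-endian IEEE-754 doubles with its dimensions. Reloading therefore
  reproduces predictions *bitwise*. (A hierarchical HDF5 container would be
  the conventional choice; JSON was selected so the bundle is a single
  self-describing text file with no binary dependency.)
- **Stability.** The loss is computed from logits
  (`max(z,0) − zy + log1p(exp(−|z|))`); attention padding uses an additive
  −10⁹ so masked weights underflow to exactly zero while rows still sum
  to 1; layer norm uses the biased variance with ε = 10⁻⁶ inside the square
  root.

## Limitations

- Training is plain R; the full published scale (35,000 iterations at batch
  512 over ~800k sequences) is out of reach here — the package targets
  desk-scale studies and correctness, not production throughput.
- One encoder block, as described in the source architecture; deeper stacks
  would need minor extension of the builder.
- The recommender is corpus-driven: it cannot suggest tools never observed
  (or simulated) as successors, and post-processing can only filter or
  re-rank what the model surfaces.
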