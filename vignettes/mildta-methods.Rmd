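---
title: "Methods: multiple-instance affinity regression with private and public features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple-instance affinity regression with private and public features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`mildta` predicts a real-valued drug–target binding affinity from two raw
strings: a SMILES representation of the compound and the amino-acid
sequence of the protein. The pair is treated as a multiple-instance
learning bag whose label is the affinity and whose instances are feature
vectors extracted under different fusion philosophies.

**Tokenization.** Both strings are segmented by a unigram subword language
model. Training seeds a candidate vocabulary with frequent substrings (up
to 6 characters), runs EM over segmentation lattices to estimate token
probabilities, and prunes the multi-character tokens with the smallest
expected counts in batches (re-running EM after each batch) until the
requested vocabulary size remains. Single characters are never pruned, so
any string over the training alphabet stays segmentable. Encoding is the
Viterbi (maximum-likelihood) segmentation computed by dynamic programming;
ties are broken toward the longer final token, which makes encoding
deterministic. Unknown characters map to a reserved `unk` id (pad = 0,
unk = 1, fixed so serialized vocabularies are portable across machines).
Truncation keeps the head of the sequence: for SMILES this preserves the
leading scaffold atoms, for proteins the N-terminal context, which is the
common convention. An optional character-level tokenizer
(`char_tokenizer()`) provides the atom-level input view; it is off by
default because the substructure stream is the primary representation.

**Sequence encoders.** Token ids are embedded (width `d_model`, default
128) and summed with sinusoidal positional encodings; the embeddings are
not rescaled before the sum — the only scaling in the attention path is
the 1/sqrt(d) inside the attention softmax. Two independent stacks of
post-norm transformer layers (default 2 layers, 4 heads, feed-forward
width 4 x `d_model`) encode the drug and protein streams. Padding
positions are excluded from every attention softmax; together with masked
pooling downstream this guarantees that the content of pad slots can never
influence an unmasked output, a property the test suite checks by
mutating pad tokens. Dropout is not applied by default.

**Private branch.** Each context matrix passes through a stack of gated
convolution blocks (default 3 blocks, kernel 3, channel width equal to
`d_model`). A block applies a causal dilated 1-D convolution producing
twice the input channels, splits them into a content half and a gate
half, multiplies the content by the sigmoid of the gate, applies layer
normalization, and adds the block input residually. Dilation rates
default to (1, 2, 4): exponential dilation is the standard way to grow the
receptive field (at kernel 3 the three blocks reach back 14 positions,
which the tests verify by input-perturbation probing). The convolution is
causal (left-padded) because its defining sum only indexes backward; with
tail-only padding this also means pad positions can never contaminate
real ones. The channel split assigns the first half to content and the
second to the gate — the choice is arbitrary but fixed. Masked global max
pooling (pads excluded from the per-channel maximum) yields one vector
per stream; the drug vector is the bag's private instance, and both
vectors feed the late-fusion concatenation.

**Public branch.** Multi-head cross-attention (same head count as the
encoders, since no separate value is specified) with queries from one
stream and keys/values from the other, a residual add of the query
stream, and masked max pooling produce the two early-fusion instances;
the concatenation of the two private vectors is the late-fusion instance.

**MIL head.** Each instance has its own scoring MLP (hidden widths 1024,
1024, 512 at full scale, ReLU activations, linear scalar output). The
scorers are independent rather than shared: the concatenation instance is
twice as wide as the others, and independent scorers preserve the
per-instance meaning of each score. The affinity is the weighted sum of
the scores with learned, unconstrained weights and no intercept
(an intercept can be enabled via `fusion_intercept`, default off).
Weights initialize to 0.25 each — a symmetric start. The loss is the mean
squared error; the mean convention (divide by N) keeps the loss scale
independent of batch size.

**Optimization.** AdamW with learning rate 1e-3, betas (0.9, 0.999),
eps 1e-8. The decoupled weight-decay coefficient is not part of the
published settings; it defaults to 0 and is configurable. Early stopping
monitors the validation loss with a default patience of 20 epochs; the
checkpoint stores the parameters of the best validation epoch. All
forward and backward passes are hand-derived; the tests compare every
layer against scalar straight-line oracles (tolerance 1e-5) and the full
model against central finite differences (about 1e-5, and 1e-4 for the
fusion weights). Weight initialization is fan-in-scaled uniform under a
fixed seed, so a run is a pure function of (seed, config, data) on a
single CPU thread.

## Evaluation protocol

Four metrics: concordance index, MSE, Pearson R, and rm². Two
documented conventions deserve note. First, the CI normalization constant
is implemented as the number of *comparable pairs* (ordered pairs whose
true affinities differ), not the number of samples: CI is an average over
pair comparisons, and this is the standard definition of the
Gönen–Heller lineage. Pairs tied in the true affinity are excluded;
prediction ties contribute one half. Second, rm² is implemented in its
standard form `r2 * (1 - sqrt(r2 - r02))`, where `r02` derives from the
least-squares regression of observed on predicted values through the
origin (slope `sum(y*p)/sum(p^2)`); when `r2 - r02` is negative within
numerical noise the square-root argument is clamped at zero with a
warning. Metrics that are undefined on a partition (constant predictions,
all-tied labels) are reported as `NA` with an explanatory flag rather
than aborting the evaluation.

Splitting supports the two standard regimes. The *random* split shuffles
pairs into five balanced folds, takes one as the test set, and divides
the rest 80/20 into training and validation; it is deliberately pair-level
and therefore leaky with respect to entities, which the overlap report
quantifies. The *blind* split partitions drugs and targets independently
0.8/0.2; a pair is a test pair only when both its entities are test
entities, a training pair only when both are training entities, and mixed
pairs are discarded — including them on either side would leak an entity
across the boundary the protocol defines. Retained pairs split 0.75/0.25
into training and validation. Affinity transformations (for example pKd
conversion) are out of scope; affinities are consumed as given.

## The synthetic benchmark

The generator emulates the *shape* of public DTA benchmarks: a bipartite
drug x target grid observed at a configurable density (the public
benchmarks span densities from 1 down to 7e-4), SMILES-like strings over
a compact chemical alphabet, and protein-like strings over the 20
amino-acid letters. The planted signal inserts `n_motifs` drug-motif /
target-motif pairs into random entities and sets

```
affinity = baseline + sum_k a_k * I(motif_k in drug) * I(motif'_k in target) + noise
```

with defaults: 3 motifs, insertion probability 0.5, effects `a_k` uniform
in (0.8, 1.6), baseline 5 (a pKd-like scale), Gaussian noise sd 0.2, and
a 50 x 30 grid at density 0.25 — a desk-scale silhouette of a medium
benchmark. Indicators are evaluated on the realised strings, so chance
motif occurrences still count and the label is an exact function of the
sequences. The signal is multiplicative in the two indicators, so neither
a drug-only nor a target-only model can fit it — recovering it requires
exactly the interaction modeling the public instances provide. Pair
sampling is uniform by default; a power-law drug-degree option exists for
stress tests.

What the generator does *not* emulate: real SMILES grammar (validity,
ring closure semantics), protein domain structure, assay noise
heteroscedasticity, and the entity-similarity structure that makes real
cold-split generalization hard. Passing tests therefore demonstrate that
the architecture can represent and recover planted interaction signal and
that the protocol machinery is correct — not that the model reaches any
particular accuracy on laboratory data.

## Problem sizes used by the tests

The suite runs at deliberately small scale, chosen as the smallest sizes
at which each property is meaningful: layer oracles on 2–7 position
inputs at width 8; the fusion-weight recovery on a 60-pair grid with a
frozen feature extractor (its per-pair scores are constant, so they are
computed once and the same AdamW machinery runs on the fusion weights
alone — mathematically identical to re-running the frozen forward every
step); the end-to-end learnability check on a complete 25 x 20 grid (500
noiseless pairs) with a reduced model (width 32, one encoder layer, one
gate block, scorer widths 64/32, batch 32, learning rate 2e-3 — a mildly
larger step than the full-scale default, appropriate for the small model),
which reaches training CI >= 0.95 within 80 epochs; and the ablation
harness over all seven instance subsets at width 8. The blind-split
leakage invariant is checked across 100 seeds at four densities.

## Known limitations

* Training is pure R on one CPU thread: suitable for desk-scale studies
  and method validation, not for the full public benchmarks at
  ~10^7 parameters.
* The unigram trainer uses expected-count pruning between EM rounds — the
  standard scheme — but no lattice-level regularization; extremely
  repetitive corpora can concentrate probability on long tokens (their
  single-character fallbacks always remain usable).
* The atom-level (character) input view is available but not wired into a
  second parallel encoder stream; the substructure view is the default
  and only stream, and the published context-matrix shapes for the
  character view are supported through `char_tokenizer()` plus the
  standard pipeline.
* `rm2`'s orientation (observed regressed on predicted, zero-intercept)
  follows the external-validation literature; reversing the orientation
  changes the value and is not offered.
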