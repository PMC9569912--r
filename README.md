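# mildta

Multiple-instance learning for drug–target binding affinity (DTA)
prediction from raw sequences.

## The problem

Estimating how strongly a small molecule binds a protein (Kd, Ki or
IC50-derived scores) is a bottleneck of early drug discovery: assays are
slow and expensive, while the space of candidate drug–target pairs is
enormous. Sequence-based deep models predict the affinity directly from the
drug's SMILES string and the protein's amino-acid sequence. Most of them
commit to a single fusion style — either *late* fusion (encode drug and
protein separately, concatenate at the end) or *early* fusion
(cross-attend between the two sequences) — although both carry
complementary signal.

`mildta` instead treats one drug–target pair as a multiple-instance
learning **bag** holding up to four **instances**, each a feature vector
produced by a different fusion philosophy:

| instance | construction | fusion style |
|---|---|---|
| `public_dp` | cross-attention, drug queries → protein keys/values, max-pooled | early |
| `public_pd` | cross-attention, protein queries → drug keys/values, max-pooled | early |
| `public_concat` | concatenation of the two private vectors | late |
| `private_d` | drug branch alone (ligand-based view) | none |

Each instance is scored by its own MLP and the bag label — the affinity —
is a learned weighted sum of the scores:

```
ŷ = w1·s(public_dp) + w2·s(public_pd) + w3·s(public_concat) + w4·s(private_d)
```

trained with mean-squared-error loss under AdamW
(lr 1e-3, betas (0.9, 0.999), eps 1e-8).

Under the hood: a data-driven **unigram subword tokenizer** (EM training,
Viterbi encoding) segments SMILES and protein sequences into
substructure tokens; two independent **transformer encoders** (sinusoidal
positional encodings, padding-masked multi-head self-attention, post-norm
residual layers) build contextual matrices; a **residual dilated gated
CNN** extracts the private features; **multi-head cross-attention** builds
the early-fusion features. All forward *and backward* passes are
implemented in plain R and verified against scalar oracles and finite
differences in the test suite.

Evaluation follows the field's standard protocol: concordance index (CI),
MSE, Pearson R and the rm² external-validation index (a model is
"acceptable" when rm² ≥ 0.5), under both **random** pair-level 5-fold
splits and **blind (cold)** splits in which no test drug or target is ever
seen in training, with explicit entity-overlap reports.

## Worked example

```r
library(mildta)

# a desk-scale synthetic dataset with a planted drug x target motif signal
sim   <- generate_dt_dataset(synth_config(n_drugs = 12, n_targets = 8,
                                          density = 1, noise_sd = 0, seed = 1))
ds    <- sim$dataset
dataset_stats(ds)$sparsity        # 1  (complete bipartite grid, 96 pairs)

split <- manual_split(ds, train = 1:96, val = 1:24)
mcfg  <- model_config(d_model = 16, n_heads = 2, n_layers = 1, ffn_dim = 32,
                      n_gate_blocks = 1, kernel_size = 3, dilation_rates = 1L,
                      max_len_drug = 14, max_len_protein = 28,
                      scorer_widths = c(32L, 16L))
tcfg  <- train_config(model = mcfg, batch_size = 16, learning_rate = 2e-3,
                      max_epochs = 30, early_stopping_patience = 60,
                      vocab_drug = 30, vocab_protein = 40, seed = 1)
fit   <- train(tcfg, split, ds)
evaluate(fit$checkpoint, split, ds, "train")
#> Evaluation over n = 96 pairs
#>   CI        : 0.9015
#>   MSE       : 0.132
#>   Pearson R : 0.9345
#>   rm2       : 0.8095  (acceptable: TRUE)
```

The concordance index of 0.90 says that 90% of comparable pair orderings
are predicted correctly after 30 epochs on 96 noiseless pairs; rm² above
0.5 marks the fit as acceptable by the usual external-validation rule.
A blind split of the same data shares zero drugs and zero targets between
train and test:

```r
bs <- blind_split(ds, seed = 1)
bs$overlap$shared_drugs     # 0
bs$overlap$shared_targets   # 0
```

The seven-configuration instance-subset ablation (private only, each
public family alone, all pairings, full model) runs via
`ablate(tcfg, ds, split)` and returns one metrics row per configuration.

A shell entry point covering simulation, tokenizer training, splitting,
training, evaluation and ablation is installed at
`system.file("cli", "dmil", package = "mildta")`.

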