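# tcrpair

Predicting whether a T cell receptor (TCR) binds a peptide–MHC complex
(pMHC) from sequence alone, with an emphasis on the **unseen-epitope**
setting where the test peptide never occurs in the training data.

`tcrpair` is an R package for immunoinformaticians working with paired
TCR–epitope–MHC records of the kind exported by VDJdb or IEDB. It provides
the full modelling workflow as composable, tested pieces:

- **Preprocessing** — parsing VDJdb/IEDB-style tables, V/J gene-name
  unification against a packaged functionality reference (pseudogenes and
  ORFs rejected), CDR3 anchor repair (`C…F/W`), MHC class I / human
  filtering, and precision-aware deduplication.
- **Task splits** — cross-validation folds realizing the four
  TCR–peptide pairing tasks: TPP1 (TCR and epitope seen, pair unseen),
  TPP2 (epitope seen, TCR unseen), TPP3 (both unseen) and TPP4 (TCR seen,
  epitope unseen), with epitope-balanced TPP3 folds, edit-distance
  restricted folds, low-frequency-epitope exclusion and a few-shot
  epitope-inclusion protocol. Every split is checked by an independently
  coded validator.
- **Negative sampling** — constrained TCR × epitope–MHC shuffling at an
  exact per-epitope 1:5 positive:negative ratio, under either a strict
  (any part of either chain differs) or a CDR3β-only difference rule.
- **Model** — a three-headed neural network: per-sequence 1-D
  convolutions over `[contextual embedding ‖ one-hot]` residue features,
  multi-head self-attention over each concatenated (CDR3, epitope) token
  sequence, learned linear embeddings of V/J/MHC one-hots, and sigmoid
  heads for β-only, α-only and paired predictions. Forward and backward
  passes are implemented in RcppArmadillo and verified against numerical
  gradients.
- **Training** — masked, positively-weighted (5×) binary cross-entropy;
  only the head licensed by each record's chain availability contributes.
  Adam with early stopping on validation average precision and optional
  stochastic weight averaging (SWA).
- **Evaluation** — AUROC (Mann–Whitney, ties ½) and average precision,
  overall and per epitope, frequency-binned summaries and Levenshtein
  distance strata relative to the training epitopes.
- **Synthetic data** — a repertoire generator with the statistical shape
  of the public databases (power-law epitope frequencies, mixed chain
  availability, biased V-gene usage) and a planted, recoverable binding
  rule: a cognate CDR3 carries a possibly point-mutated copy of a k-mer
  of its epitope.

The loss being maximized is the weighted Bernoulli log-likelihood

```
BCEL(θ) = −(1/N) Σₙ wₙ [ yₙ log ŷₙ + (1 − yₙ) log(1 − ŷₙ) ]
```

with `wₙ = 5` for positives, summed over observed labels only: a β-only
record observes `yβ`, an α-only record `yα`, and a paired record observes
`yαβ` alone (`yα`, `yβ` are treated as missing).

## Worked example

Generate a synthetic repertoire, build a seen-epitope (TPP2) fold with
negatives, train a small model and evaluate the held-out fold:

```r
library(tcrpair)

ds <- generateRepertoire(synthConfig(nEpitopes = 30, nPositives = 800, seed = 1))
ds
#> TcrDataset (Dab_a_b) with 801 records
#>   positives: 801, negatives: 0
#>   epitopes: 30, MHC alleles: 5
#>   gene vocab sizes: bV=48 bJ=13 aV=44 aJ=50

sp <- makeTpp2Split(ds, foldIndex = 0, seed = 3, valFraction = 0)
fd <- prepareFoldData(ds, sp, "any_part", ratio = 5, valFraction = 0.1, seed = 3)

emb   <- mockEmbedder(8)                       # deterministic mock backend
packs <- lapply(fd, packExamples, dataset = ds, embedder = emb)

model <- buildModel(modelConfig(channels = 16, heads = 2, geneDim = 8,
                                mhcDim = 8, hidden = 32), ds, embedDim = 8)
fit <- trainModel(model, packs$train, packs$val,
                  trainConfig(lr = 3e-3, maxEpochs = 40, patience = 10,
                              swaEpochs = 0, batchSize = 256, seed = 1))

scores <- predictScores(fit$model, packs$test)
aurocScore(scores, fd$test$label)
#> [1] 0.923913
```

An AUROC of ≈0.9 means the model has recovered the planted motif rule and
the gene-usage bias from the training fold: a random positive test pair
outranks a random shuffled negative about 9 times out of 10. The
per-epitope breakdown comes from `evalReport(scores, fd$test,
trainEpitopes = unique(fd$train$epitope))`.

A thin command-line interface over the same functions ships in
`inst/scripts/tcrpair.R` (subcommands `preprocess`, `synth`, `split`,
`negatives`, `pipeline`).

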