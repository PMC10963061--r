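---
title: "Modelling TCR-pMHC binding with tcrpair: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TCR-pMHC binding with tcrpair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

T cells recognize infected and malignant cells when their T cell receptor
(TCR) binds a peptide presented by an MHC molecule (pMHC). Public
databases hold hundreds of thousands of experimentally confirmed
TCR-pMHC pairs, but the data are extremely skewed: a handful of epitopes
own a large share of all records, many records carry only the beta chain,
and gene or allele annotations come at inconsistent precision. `tcrpair`
implements a complete supervised workflow for learning a binding
classifier from such data, with particular care for the evaluation
question that dominates this field: does the model generalize to
*epitopes it has never seen*?

This vignette documents the modelling decisions, the parameters that
matter, and what the synthetic benchmarks do and do not establish.

## Records, labels and the three-headed formulation

A datapoint is a TCR (per chain: CDR3 amino-acid sequence plus V and J
gene names), an epitope sequence, an MHC allele string, and a binary
label. Chain availability varies, so the model carries three sigmoid
output heads -- beta-only, alpha-only, and paired -- and each record
*observes exactly one label*: a beta-only record observes `y_beta`, an
alpha-only record `y_alpha`, and a paired record observes `y_alphabeta`
while its single-chain labels are treated as missing. The loss is the
masked, weighted binary cross-entropy

$$\mathrm{BCEL}(\theta) = -\frac{1}{N}\sum_{n=1}^{N} w_n\left(y_n\log\hat
y_n + (1-y_n)\log(1-\hat y_n)\right),$$

where positives are weighted $w_n = 5$ (matching the 1:5 class ratio of
the generated negatives), missing labels contribute nothing to loss or
gradient, and $N$ counts observed label terms. With one observed label
per record the two candidate denominators (records vs terms) coincide;
we count terms so that mixed batches keep a comparable scale if a future
labelling scheme observes several heads at once. Predictions are clipped
to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-7}$ before the
logarithm.

## Preprocessing

Raw tables pass through, in order:

1. **Class/host filter.** Only MHC class I, human-host records survive;
   records missing either annotation are dropped (the conservative
   reading -- both filters are mandatory, and an unannotated record
   cannot prove it satisfies them).
2. **CDR3 canonicalization.** CDR3 junctions are reported with or
   without the conserved anchors. A missing leading cysteine is
   prepended and a missing trailing F/W gets an `F` appended (`F` is by
   far the more common anchor); sequences with non-canonical letters or
   shorter than 5 residues after repair are discarded. The repair is
   idempotent, which the tests check on randomized inputs.
3. **Gene unification.** Names are normalized (case, whitespace, legacy
   `TCRBV`-style prefixes, leading zeros) and looked up in a packaged,
   versioned reference of human TRAV/TRAJ/TRBV/TRBJ names with
   functionality calls. Pseudogenes and ORFs are rejected as
   nonfunctional. Precision is detected as family < gene < allele; the
   packaged table is a curated subset and a declared artifact parameter
   of the package -- swap in a fuller table via `loadGeneReference(path)`.
4. **Precision deduplication.** Records identical except that their gene
   or MHC fields sit on the same precision chain (e.g. `TRBV20-1` vs
   `TRBV20-1*01`) collapse to the most precise one. Two *maximal*
   records that genuinely conflict -- different alleles of the same gene
   -- are both kept: nothing in the data says they are the same clone.
5. **Variant assembly.** `Dab_b` (complete beta information, alpha
   attached when present), `Dab` (both chains complete) or `Dab_a_b`
   (either chain complete). Vocabularies for genes and MHC strings are
   indexed by lexicographic sort so that indices never depend on row
   order. MHC strings at different precision ("HLA-A" vs
   "HLA-A*02:01") are distinct vocabulary entries, matching the
   one-hot-over-observed-strings encoding.

## Task splits and their validator

The four pairing tasks differ in what the test set shares with training:

| task | test TCR | test epitope |
|------|----------|--------------|
| TPP1 | seen     | seen (pair unseen) |
| TPP2 | unseen   | seen |
| TPP3 | unseen   | unseen |
| TPP4 | seen     | unseen |

TCR identity ("seen") is either the full six-field tuple (`strict`) or
the beta CDR3 alone (`cdr3b`), recorded on every split.

**TPP3** folds balance the skewed epitope distribution: epitopes are
ordered by descending positive count (ties broken lexicographically) and
within each consecutive block of ten the fold labels 0..9 are a uniform
random permutation -- every fold receives one epitope per block, so each
fold sees both frequent and rare epitopes. The trailing partial block
receives a random subset of distinct labels (the natural completion of
the permutation scheme; a plain independent-uniform assignment is
available behind `blocked = FALSE` for sensitivity checks). **TPP2**
partitions unique TCR keys round-robin over a shuffled order; test
epitopes that lose all train positives are recorded so the negative
generator can inject train negatives for them (their 1:5 ratio cannot be
retained). **TPP1** greedily moves datapoints to test while both their
TCR and epitope retain another occurrence on the training side. **TPP4**
mirrors TPP2 with the roles of TCR and epitope swapped; it ships
untested against any reference results because on database-like data
TCRs rarely pair with more than one epitope, making the task degenerate.

Edit-distance-restricted TPP3 folds guarantee a minimum Levenshtein
distance (default 5) between epitopes of different folds: epitopes
closer than the threshold are single-linkage clustered (the construction
is ours; only the constraint is given) and whole clusters are assigned
to folds by the same blocked scheme. A single giant cluster, or fewer
clusters than folds, is reported as infeasible rather than silently
relaxed.

Every constructor is paired with `validateSplit()`, an independently
coded checker that re-derives the seen/unseen sets from the index sets
alone. The validation set is carved out of the training partition, so
the validator counts it as training data for seen/unseen purposes.
Validation is carved either as a naive random datapoint sample (the
default, which also represents the seen-epitope tasks) or as whole
held-out epitopes (`unseen_epitope`), mirroring the two options one
would compare when choosing an early-stopping signal for TPP3.

The few-shot inclusion protocol models epitope screening: a panel of
novel epitopes is partitioned across repeats (1-4 epitopes each); each
repeat moves those epitopes' positives into training with 1:5 negatives
built from training-set TCRs, and evaluates on the remaining panel.
Across repeats every panel positive enters training exactly once.

## Negative sampling

Negatives are generated *per partition* (train+validation and test
separately -- this is what limits test-to-train leakage) by pairing TCRs
of the partition with its epitope-MHC units, the unit kept atomic. A
candidate is admissible only if it differs from every positive TCR of
that epitope under the active definition (`any_part`: any of CDR3/V/J on
either chain; `cdr3b_only`: the beta CDR3 itself). Sampling is by
rejection with an attempt cap of 100x the target, after which the
admissible set is enumerated exactly -- this both terminates and detects
infeasibility precisely, and is uniform over the admissible set either
way (checked by a chi-square test against exhaustive enumeration on a
toy space). Where shuffling cannot produce five negatives per positive
-- inevitably for the most frequent epitopes, whose cognate TCRs exhaust
the pool -- positives are discarded uniformly at random until the ratio
holds exactly for every epitope.

Under `cdr3b_only` no (beta CDR3, epitope) pair can carry both labels
anywhere in the combined data; under `any_part` such CDR3-level
collisions may exist (two TCRs sharing a CDR3 but differing in V), which
is precisely why the second definition exists for comparisons against
beta-only methods.

## Encoding

Each CDR3 and the epitope become an $\ell \times e$ block: a contextual
per-residue embedding concatenated with a one-hot channel, $e = d + 20$.
The embedding backend is pluggable behind a three-field contract
(`name`, `dim`, `embed`); the packaged `mockEmbedder()` produces
hash-seeded pseudo-random rows that are deterministic, contextual (each
row depends on the whole sequence) and leave the caller's RNG stream
untouched, which makes every downstream stage testable without model
downloads. A production protein-language-model backend (ProtBERT-style,
$d = 1024$) plugs into the same contract; such backends must strip
special-token rows and insert residue whitespace so output rows align
1:1 with residues -- the encoder asserts the row count rather than
assuming it.

When V and J genes resolve in a germline segment table, the full-length
chain is reconstructed -- V segment ending at its conserved cysteine
(which *is* the CDR3's first residue), the CDR3 interior, then the J
segment from its F/W anchor (the CDR3's last residue) -- the full
sequence is embedded, and only the CDR3-span rows are kept. The span
convention is a declared contract and the round trip
`substring(full, span) == cdr3` is asserted on every reconstruction.
Anchor disagreements (a W-ending CDR3 over an F-anchored J) and genes
missing from the table fall back to embedding the CDR3 alone, so both
paths yield one row per CDR3 residue. The packaged germline table is a
six-gene toy with invented segments, for tests and examples only.

The alphabet is the 20 canonical residues in alphabetical order with no
gap/X symbol (preprocessing rejects them). Default maxima are
$\ell = 25$ (CDR3) and $\ell_e = 15$ (epitope); over-length sequences
are rejected with a length report rather than truncated. Gene and MHC
vocabularies carry one reserved "unknown" row so inference on new
alleles degrades gracefully; training data never uses it.

## Architecture

Per example: a one-layer 1-D convolution (kernel 3, ReLU) over each
available CDR3 block and over the epitope block (the epitope convolution
is shared between chains); the epitope conv output is concatenated
*along the sequence axis* with each chain's conv output, producing one
joint token sequence per chain; one multi-head self-attention block
(default 4 heads, width = conv channels, scaled dot-product, softmax
over keys, output projection with a residual connection, no
normalization layer) attends over the joint sequence, letting CDR3
positions interact with epitope positions; the attended sequence is
mean-pooled over its true length; the pooled vector is concatenated
with learned linear embeddings of the V/J genes and MHC allele, and a
one-hidden-layer ReLU MLP with dropout produces the head's logit. The
paired head concatenates both chains' pooled vectors with all four gene
embeddings and the MHC embedding. Sequences enter the network at their
true lengths -- padded rows never reach it -- so padding invariance
holds by construction and no attention mask is needed.

Where the architecture left genuine choices, the defaults are: mean
pooling over positions (the simplest length-aware pool); sequence-axis
concatenation of epitope and CDR3 conv outputs (self-attention over the
pair is the direct reading of cross-sequence attention); separate
attention/conv stacks per chain with `shareChains = TRUE` available (the
shared-parameter phrasing in this model family refers to reusing the
same chain parameters across missing/full-data cases, which holds here
in either mode); the MHC embedding feeds all three heads; the joint head
concatenates rather than sums the chain representations. Default
capacity is conv 128 channels, 4 heads, gene/MHC embeddings 32, MLP
hidden 256, dropout 0.1 -- all config-exposed, with a 16-channel "tiny"
configuration used throughout the tests.

The forward and backward passes are hand-written in RcppArmadillo
(src/model.cpp); the test suite verifies every parameter's analytic
gradient against central finite differences, head independence by paired
forward passes, zero gradients on the alpha-exclusive parameters for
beta-only batches, and padding invariance.

## Training

Adam (default moments, batch size 512) minimizes the masked weighted
BCE. Early stopping monitors average precision on the validation set as
generated (1:5 ratio, not rebalanced); the parameters of the best-AP
epoch are retained (patience 10, max 100 epochs by default). Learning
rates follow the task: 1e-4 for seen-epitope (TPP2) training and 1e-3
for unseen-epitope (TPP3), the latter with an exponential scheduler
(gamma 0.95 per epoch; the scheduler family is given, the decay rate is
our choice). Stochastic weight averaging then continues for 20 epochs at
a constant rate (defaulting to the main rate) and returns the
elementwise mean of the per-epoch snapshots; the mean is computed as
first-snapshot-plus-average-of-differences so a frozen run averages to
itself exactly. The model has no normalization statistics to recompute
after averaging. All shuffling, dropout and initialization derive from
explicit integer seeds; two runs with the same seeds are bit-identical.

## Evaluation

AUROC is computed from mean ranks (the Mann-Whitney concordance
probability, ties counted one half); average precision is the
non-interpolated stepwise sum over the ranked list, with tied scores
processed as blocks. Both are verified against brute-force oracles
(exhaustive pair counting; rank-by-rank summation) to 1e-12 on a
thousand random instances. Because the pooled metrics are dominated by
the most frequent epitopes, per-epitope scores are first-class:
computed within each epitope's own positives and negatives, flagged
when only one class is present, binned by positive count (SEM of a
single-epitope bin reported as 0 with a flag), and stratified by the
minimum Levenshtein distance from each test epitope to the training
epitopes (`utils::adist`, verified against an independent DP oracle).
Aggregation across repeated cross-validation runs reports the mean and
standard error of the mean over run-level means. The test suite includes
a constructed two-epitope example where both per-epitope AUROCs are 1
while the pooled AUROC is not -- the canonical pooling trap.

## The synthetic repertoire generator

The generator is the package's study system. It emulates the features of
database data the method is sensitive to: a power-law epitope frequency
distribution (default exponent 1.5 over 60 epitopes, which makes the
three most frequent epitopes own well over a quarter of the 3000
positives -- the qualitative skew of the real databases), mixed chain
availability (55% beta-only, 40% paired, 5% alpha-only), real functional
IMGT-style gene names with an epitope-preferred V gene used at
probability 0.5 (so gene usage carries signal), a small MHC class I
allele vocabulary with one allele per epitope, and CDR3s of length
12-16 with proper anchors. Binding follows a planted rule: each epitope
donates a 4-mer of its own sequence, and every cognate CDR3 contains a
copy of that motif, point-mutated with probability 0.05; non-cognate
motifs are excluded from generated CDR3s by rejection. In
`shared_core` mode all motifs are single substitutions of one common
core and are spliced into their epitopes, so the rule is partially
transferable to unseen epitopes -- the regime in which seen- vs
unseen-epitope task difficulty can be compared meaningfully.

What the generator does **not** emulate: VDJ junctional statistics and
realistic CDR3 composition, epitope sequence families and HLA
restriction structure, cross-reactivity, batch effects between source
databases, or label noise. A model passing the synthetic benchmarks has
demonstrated that the pipeline is correct and that the architecture can
extract a relational sequence rule at realistic skew -- not that it
reaches any particular accuracy on real repertoires.

## Problem sizes and numerical choices in the tests

The test suite runs at desk scale by choice: metric oracles on a
thousand instances of n <= 30; split validation over 50 random
repertoires of 150-300 positives across all ten folds; negative-sampling
invariants verified by brute force on a ~11,000-record set (generated
with a flatter exponent, 1.2, so the full 1:5 ratio is reachable at that
scale); learnability on the default 3000-positive repertoire with the
16-channel configuration, 30 epochs, against a label-shuffled control;
and the task-difficulty comparison on 1200-positive shared-core
repertoires. Degenerate inputs are exercised deliberately: empty
partitions, single-epitope datasets (no shuffled negative exists),
one-class epitopes in evaluation, epitopes with fewer achievable
negatives than positives, and infeasible distance restrictions all have
defined, tested behaviour.

## Known limitations

- The packaged gene reference is a curated subset; production use on
  full database exports should supply a complete, versioned IMGT-derived
  table (and a real germline segment table for full-length context).
- The attention block carries no normalization layer; at much larger
  widths/depths than the defaults, training may need one.
- `fewShotInclusionSplit` partitions the screen panel so every positive
  is included exactly once across repeats; protocols that re-include
  epitopes in several repeats would need a different partition scheme.
- TPP4 splits are constructible but untested against any reference
  results, for the data-sparsity reason above.
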