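---
title: "Benchmarking promoter recognition models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking promoter recognition models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the labeling
model behind the benchmark datasets, the classifier families and their
training protocol, the synthetic-data machinery, and the places where the
design was genuinely open and a choice had to be made.

## The problem

Ab initio promoter recognition asks whether a DNA window contains an RNA
polymerase II core promoter, using sequence alone. Published deep models
report high cross-validation scores, but each study trains and tests on its
own small, roughly balanced dataset with its own negative class. Genomes
are not balanced: promoter windows are on the order of 1% of a chromosome
tiling. The package's purpose is to make the genome-scale evaluation (and
the reasons models fail it) reproducible.

## Coordinates and the labeling model

All internal coordinates are 0-based, half-open; 1-based arithmetic exists
only at the SGA parse/format boundary (SGA positions are 1-based) and in
TSS-relative labels, which follow the convention that the TSS base is +1
and there is no position 0. In a window with `u` upstream bases the TSS
base sits at 0-based index `u`; TSS-relative coordinate `r` maps to index
`u + r` for `r < 0` and `u + r - 1` for `r > 0`. A region described as
"−249 to +50" is read as 249 bases strictly upstream, the TSS base, and 50
bases strictly downstream — 300 bases — because the same studies' 251-base
region is unambiguously 200 + 1 + 50. Under the no-zero labeling the last
downstream base of that window is +51; slicing functions therefore take
explicit inclusive bounds so either reading of a motif span can be
expressed.

A window is tagged `I` when a *single* promoter region overlaps it by at
least `min_overlap` bases (default 250 of 300, boundary inclusive).
Contiguity is enforced by construction: the overlap of a window with one
interval is an interval, and overlaps with different promoters are never
summed. Labeling is monotone in the threshold, which the tests exercise.
Windows are stored as forward-strand text regardless of the promoter's
strand — a scanning classifier reads the forward strand — while
reverse-strand promoter regions still drive labeling through genomic
overlap. Soft-masked (lowercase) bases are retained as ordinary bases;
only literal `N` removes a window. Ambiguity codes are degraded to `N` on
read so real genome files always parse.

Known limitation: applying the documented recipe to a real ~250-Mb
chromosome yields the closed-form `floor((L - 300)/50) + 1` window count
(millions of windows), far above the window totals published for
comparable genome-scale datasets, which implies additional undocumented
filtering in that lineage of datasets. The package implements exactly the
stated procedure and reports counts from it.

## Classifier families and the neural engine

No deep-learning framework exists in the package's dependency footprint,
and re-implementing the published architectures is part of the package's
purpose, so it carries a small neural engine: 1-D convolution over one-hot
DNA via an im2col expansion, non-overlapping max pooling, ReLU, dense
layers, a bidirectional LSTM with hand-written backpropagation through
time, and Adam. Analytic gradients for every family are verified against
central finite differences in the test suite. One-hot row order is fixed
as (A, C, G, T) everywhere; `N` encodes as an all-zero column rather than
0.25s, so converters never fail on user data even though benchmark windows
drop `N`.

Only a few architectural facts are fixed by the source studies: filter
lengths 15 and 21 for the plain CNNs, 200 filters for the element-based
CNN, and the TATA CNN using fewer filters and a smaller pool than the
non-TATA CNN. Everything else is configuration with documented defaults
chosen once: non-TATA 200 filters/pool 4, TATA 100 filters/pool 2, dense
hidden width 64, CNN-BiLSTM embedding of 64 length-15 filters with pool 6,
16 LSTM units per direction, and dropout 0.2 on the CNN-BiLSTM's flattened
recurrent features (its feature vector is large relative to the training
sets, and unregularized it memorizes before it generalizes). The
element-CNN's element table is not published; the shipped default profile
holds the TATA box at −33..−23 and the initiator at −2..+4, with a
pool-3 compressed context, all user-configurable. The CNN-BiLSTM passes
the *full* BiLSTM output sequence to the dense stage rather than only the
final hidden states: positional evidence then reaches the classifier on a
short gradient path, which matches the original CLSTM design and is what
makes fixed-position motif structure learnable in practice.

Softmax class order is fixed (index 0 non-promoter, 1 promoter); the
sigmoid decision boundary at 0.5 is inclusive, so an exactly-0.5 score is
called `I`. Imported JASPAR PFMs become convolution filters either as
per-column frequencies or as log2 odds against a uniform background with a
0.5 pseudocount (a uniform column is exactly zero); in `jaspar_fixed`
models those filters are frozen and only the dense layers train, so each
filter remains exactly one motif.

## Training protocol

Adam with learning rate 0.001, at most 50 epochs, early stopping when the
validation MCC has not improved for 5 epochs. The validation set is a 10%
stratified holdout carved from the training data with the run seed; MCC
drives early stopping because it is the headline metric and the only one
of the four that is informative under heavy imbalance. Batches are
stratified: examples are ordered by within-class quantile rank so any
contiguous batch preserves class proportions within one example. The loss
pairs with the head (binary cross-entropy for sigmoid, cross-entropy for
softmax). Every improvement checkpoint retains the full parameter set and
is loadable; the run log records per-epoch loss and validation MCC. All
randomness (initialization, batching, holdout, dropout, samplers) flows
through one seeded generator with pinned RNG kinds, so a run is exactly
reproducible in a single-threaded session; multi-threaded BLAS builds are
reproducible at fixed thread count.

Cross-validation is stratified k-fold (default 10) with per-fold retraining
from scratch. The confidence interval construction is not fixed by the
protocol the package follows, so it is an explicit, recorded choice:
Student-t on the fold scores with k−1 degrees of freedom at the 99% level.
Zero-variance fold scores legitimately collapse the interval onto the mean.

Class rebalancing follows the two standard moves at a default ratio of 10
non-promoters per promoter: undersampling discards non-promoters (never
touching promoter content), oversampling duplicates promoters with
replacement (never changing the set of distinct non-promoters) and then
shuffles with the same seed.

Metrics with zero denominators are reported as 0 with an explicit
`undefined` flag rather than NaN, so cross-testing matrices over hundreds
of cells stay machine-readable; the flag preserves the information that
the value is conventional.

## Synthetic negatives

Two substitution-based classes turn promoters into negatives. UD
("uniform distribution") replaces selected positions with bases drawn
uniformly from the four letters — the draw may reproduce the original
base, so the expected change rate is 3/4 per substituted position, and
composition tests are calibrated accordingly. OPD ("original promoter
distribution") instead permutes the selected positions' bases among
themselves, a strict conservation law: with fraction 1 the output is an
exact seeded permutation of the input. OPD is deliberately a permutation
rather than i.i.d. draws from the empirical composition, because only the
permutation conserves the multiset exactly per sequence. The substituted
fraction is a parameter recorded in output metadata; the default follows
the segment convention of substitution-based negative generation, 20 of
32 equal-length segments, and a per-position mode is available as a
configuration switch since the segment-versus-position question is not
settled by the protocol's description. Genomic negative classes are also
provided: windows sampled strictly downstream of a gene's first exon, and
windows disjoint from all promoter regions that nevertheless contain a
given consensus motif (e.g. TATAAA), drawn by bounded rejection sampling.

## The synthetic genome generator

The generator emulates exactly what the pipeline needs from a genome: a
chromosome-like string over `{A,C,G,T,N}` with configurable GC content
(default 0.41, human-like), non-overlapping planted 300-base promoter
regions anchored on recorded TSSs, core motifs at fixed TSS-relative
offsets (defaults: TATAAA starting at −31, a TCAKTY initiator at −2),
both strands (reverse-strand promoters are written as reverse
complements), optional `N` blocks overwritten last like assembly gaps, and
a promoter:background ratio that reaches the ~1:99 genome-scale regime.
The background is i.i.d., not a Markov chain: that suffices for
separability and calibration tests and keeps every probability statement
about the fixtures analytic. What the generator does *not* emulate —
repeat structure, isochores, CpG islands, correlated k-mer statistics,
biological motif degeneracy beyond IUPAC consensus — bounds what passing
tests mean: they demonstrate that the machinery (labeling, training,
evaluation, analysis) is correct and that the architectures can learn
planted structure, not that any model recognizes real promoters. Ground
truth intervals are returned alongside the annotations so labeling tests
need no re-derivation.

Chance occurrences are a feature, not a bug: a specific 6-mer appears in a
300-base i.i.d. window with probability ≈ 7%, so even a well-trained model
has a nonzero false-positive rate on background windows, which is exactly
what drives the precision collapse experiment below.

## Problem sizes and the end-to-end checks

The package's end-to-end checks run at deliberately modest, fixed sizes,
chosen once as the smallest scales at which the phenomena are stable: the
learnability check trains the CNN-BiLSTM on 1,000 planted windows
(500 promoter-sense positives, 500 background) and requires held-out MCC
of at least 0.9 on 500 windows, with a motif-free negative control
required to stay within |MCC| ≤ 0.1; the precision-collapse check
evaluates that same fixed model at non-promoter:promoter ratios 1:1, 10:1
and 100:1 (200 positives against up to 20,000 negatives) and requires
strictly decreasing precision — the qualitative genome-scale phenomenon,
reproduced in kind. With a fixed classifier the arithmetic is
transparent: sensitivity holds the true positives near constant while
false positives grow linearly with the negative pool, so PPV falls toward
the positive prevalence. The worked example freezes a 2,000-base genome
with two promoters and a golden dataset computed by a brute-force
per-base interval oracle, giving a byte-level regression anchor for the
whole dataset-construction path.

## Numerical choices and degenerate inputs

Probabilities are clamped to `[1e-12, 1 - 1e-12]` inside the losses;
softmax subtracts the row maximum before exponentiation. An improvement
must exceed the incumbent best validation MCC by more than 1e-9 to reset
patience, so ties do not stall early stopping. Max-pool argmax ties break
toward the earliest position (strict `>` update). Duplicate windows keep
their first occurrence, and removed duplicates whose tag conflicts with
the kept copy are counted and reported — silent tag conflicts would
corrupt training labels invisibly. Empty datasets report a promoter
fraction of 0 with an explicit `empty` flag. Out-of-bounds window
extraction is an error, never a silent clip, and a genome shorter than one
window yields an empty dataset with a warning.

## Scope decisions

The alignment-based dataset route is represented by its exact-match core
(both-strand occurrence search) plus the interval-import interface an
external aligner's hits can flow through; running an aligner is out of
scope. Transformer models are ingested, not implemented: the k-mer token
converters and the external-prediction reader cover the interchange
formats. The `download` command prints source URL templates and validates
already-downloaded files by digest; it never touches the network, so the
entire test suite runs offline.
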