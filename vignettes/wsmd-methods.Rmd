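---
title: "Discriminative motif discovery as a latent SVM: model, algorithm and benchmarks"
author: "wsmd package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative motif discovery as a latent SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsmd)
```

## The problem

Transcription factors bind short, degenerate DNA patterns (motifs). A
ChIP-seq experiment yields a *foreground* set of peak sequences that are
enriched for binding sites of one factor, and a matched *background* set
that is not. Discriminative motif discovery asks for a motif — here a
position weight matrix (PWM), a 4 x l column-stochastic matrix of
per-position nucleotide probabilities — that separates the two sets as
sequence classifiers, while simultaneously locating the responsible site in
each foreground sequence. The site locations are unobserved: each sequence
is only weakly labeled, which places the problem in the multiple-instance /
weakly supervised family.

## Model

Every sequence is decomposed into the bag of its length-`l` windows, on
both strands. A window is one-hot encoded into a binary vector `x` of
length `4l` (A, C, G, T blocks per position). A motif is a weight vector
`w` of length `4l` with threshold `b`; the binding energy of a window is
the inner product `w'x`, which coincides with the log-probability score
`sum_i log P[base_i, i]` when `w` holds column-wise log PWM entries. The
sequence-level energy `E(s)` is the maximum over the sequence's window bag,
and a sequence is called motif-positive when `E(s) > b`.

Maximizing classification accuracy over the two sets is equivalent to
minimizing the error count. Replacing the 0/1 indicator with the hinge
`max(0, 1 - m)` of the functional margin `m = y (E(s) - b)` and adding an
L2 penalty gives the training objective

    min_{w, b}  ||w||^2 + (c / N) * sum_s hinge(y_s (max_x w'x - b)),

with `N` the total number of sequences and `c > 0` the error/complexity
tradeoff. With the window (latent) choice fixed per sequence this is the
standard soft-margin linear SVM; with the inner max it is a latent SVM.

## Optimization

`refine()` alternates two steps from a seed model:

* **latent update** — for every sequence select the current best-scoring
  window (ties: forward strand first, then smallest offset);
* **QP step** — exactly re-solve the resulting convex soft-margin problem
  on the selected windows.

The QP step is solved in the dual by a compiled SMO (sequential minimal
optimization) solver with max-violating-pair selection, to a duality-gap
tolerance of 1e-10; the intercept is then recovered by exact 1-D
minimization of the piecewise-linear hinge sum at the optimal weights (the
midpoint of a flat optimal segment is taken, which keeps every step
deterministic). The solver also accepts grouped constraints in which
several windows of one sequence share a slack variable, which is what the
`exact_negative` mode needs.

Two properties shape the loop. The QP step can never increase the
fixed-latent surrogate objective (it minimizes it exactly), and the latent
update on *foreground* sequences can never increase the true objective.
The latent update on *background* sequences, however, replaces each
background representative by its argmax window and can increase the true
objective; in practice the iteration settles into a short (period 2-4)
cycle. `refine()` therefore (i) declares convergence when the objective
revisits, within `tol`, any of the last four iterates — covering both
plateaus and these cycles — with a hard cap of `max_iters = 50`, and (ii)
always returns the best-by-true-objective iterate seen, including the seed
itself, so the output is well defined even without monotone convergence.

The non-default `exact_negative` mode removes the background
approximation: violated background windows are accumulated as shared-slack
constraints (hard-negative mining) until no background window violates its
constraint by more than 1e-4. The background side of the objective is then
exact; the foreground side keeps the argmax latent step.

`c` defaults to 1 and can be selected from a grid by internal 3-fold
cross-validated AUC (`choose_c()`); the tie rule prefers the smallest `c`.

## Seeding

Seeds are exact k-mers (`k = 6` by default, `k <= 10`), scored by how
reliably they sit closer (in substring-minimal-distance, the minimal
Hamming distance over all windows of both strands) to foreground than to
background sequences: the score of a word is the probability over
foreground/background pairs that its SMD is strictly smaller in the
foreground sequence, ties counting 1/2. That convention makes the score
symmetric — `score(F, B) + score(B, F) = 1` — and centers uninformative
words at 0.5. Because the score depends on the data only through the two
`(k + 1)`-bin SMD histograms, the exact all-pairs score is computed in
`O(k^2)` per word after one pass over the sequences — no pair sampling is
needed at any dataset size, and seeding is fully deterministic. Per
sequence, the SMD of *all* `4^k` words is obtained at once by a
multi-source breadth-first search over the Hamming graph of the word space,
seeded at the words that occur in the sequence. A word and its reverse
complement scan identically on a double-stranded bag, so each pair is
collapsed to the lexicographically smaller canonical form before ranking;
remaining ties are broken lexicographically. A selected word is turned into
an initial model via a PWM with 0.85 on the seed base per column.

## Extension and masking

Refinement runs at the seed width `k` first. To reach the target width
`l`, the unified extension builds all `l - k + 1` placements of the
refined core inside a width-`l` window, padding with uniform columns, and
re-refines each, keeping the lowest objective (ties: smallest upstream
offset). In weight space a uniform column is the zero 4-block — its
additive constant cannot change window ranking and zero leaves the L2 norm
unchanged — so each candidate starts scoring windows exactly as the
refined core does, and at `k = l` the single candidate starts from the
refined model itself. The `greedy` mode grows one column at a time (left
vs right, keep the better), mirroring the site-by-site strategy of older
discovery tools; it is provided as a baseline and is measurably worse on
off-center motifs, because a greedy path that starts growing on the wrong
side cannot recover.

By default only the best refined seed is extended (bounding runtime);
`extend_all_seeds = TRUE` extends every seed and keeps the best final
objective.

For multi-motif discovery, each reported motif's support is masked: in
every foreground sequence whose energy exceeds the detection threshold,
the best window and all windows overlapping it are removed from the bag
(equivalently, the called interval is N-ed out for the next seeding
round), and sequences whose bags empty out are dropped. Background bags
are never masked.

## Evaluation metrics

* **Detection threshold**: the top `q` quantile (default `q = 0.1%`,
  linear interpolation) of all site-level energies across all background
  windows.
* **Contingency table** at that threshold, following strict inequalities
  (`E - b < 0` foreground misses, `E - b > 0` background hits; a sequence
  exactly at threshold is not detected); classification accuracy and the
  one-sided Fisher exact enrichment p-value (reported as log10) derive
  from it.
* **AUC**: the tie-aware rank-sum probability that a foreground sequence
  out-scores a background sequence.
* **MHG score**: sequences are ranked by score with ties giving background
  precedence (the conservative order); the hypergeometric tail probability
  of foreground enrichment is evaluated at every prefix and the log10 of
  the minimum over prefixes `1 .. N-1` is reported, uncorrected.
* **nCC / sASP** against known site annotations: nucleotide-level Matthews
  correlation over all foreground positions (strand ignored; 0 when a
  marginal is empty), and the mean of site-level sensitivity and precision
  where a prediction counts as correct when it overlaps a true site by at
  least a quarter of the site length. These are the standard conventions
  of the motif-assessment literature.
* **cross_validate()** wraps stratified 3-fold cross-validation (fold
  sizes differ by at most one per class) around the full discovery
  pipeline and reports train and test AUC / Fisher / MHG.

## The synthetic benchmark generator

`generate_dataset()` emulates the implanted-motif study design: both sets
contain `n_seq` i.i.d.-uniform sequences of `seq_len` bp (defaults 2000 x
500 bp); a *decoy* PWM instance is implanted in every sequence of both
sets and a *signal* PWM instance additionally in every foreground
sequence, non-overlapping, by overwriting at a uniformly random
forward-strand position (so the stated sequence length is preserved
exactly). One instance of each kind per sequence is implanted; the decoy
makes the task non-trivial because it is enriched in both sets and must be
rejected by a discriminative learner. PWMs at a prescribed information
content use the single-dominant-base column family — one dominant base per
column at probability `p`, the rest at `(1 - p) / 3` — with `p` solved by
bisection so each column carries `total_ic / width` bits; the family is
one-parameter, spans the full 0-2 bits/column range, and is strictly
monotone in `p`, so any feasible target is hit to 1e-6 bits. The benchmark
grids pair a width-8 signal of IC 2-16 with a width-8 IC-10 decoy (80
experiments) and a width-18 signal of IC 6-26 with a width-18 IC-20 decoy
(110 experiments), 10 replicate datasets per setting.

What the simulator does *not* emulate: genome-like base composition
(backgrounds are uniform), variable site multiplicity, mutated or
truncated instances, and positional biases of real peaks. Passing the
synthetic benchmarks therefore demonstrates correct recovery of implanted
signals against a decoy under ideal background assumptions — not
performance on real ChIP-seq data, where background construction and
sequence composition dominate difficulty.

## Numerical and design choices

* Energies use natural logs (only orderings and linear margins matter, so
  the base is a scale choice); information content is in bits, giving the
  conventional 2 bits/column maximum.
* A probability floor of 1e-3 is applied (then renormalized) before any
  log, keeping consensus-like seeds finite.
* Learned weights are reported as a PWM via column-wise unit-scale
  softmax — the canonical inverse of log-probabilities, shift-invariant in
  the same way the classifier is. Because the trained `||w||` is typically
  well below log-probability scale, reported PWMs look flatter than the
  underlying discrimination; site calls and all metrics operate on the
  linear model and are unaffected.
* Windows containing `N` are dropped rather than imputed; sequences
  shorter than the window are rejected with a named error. Coordinates are
  0-based half-open throughout, BED-style; minus-strand windows carry the
  forward-strand start of the region they cover.
* Deterministic tie rules everywhere: forward strand/smallest offset for
  windows, lexicographic for seeds, smallest upstream offset for
  extension, smallest `c` in grid selection. Two runs with the same
  inputs, configuration and seed produce byte-identical output files.
* The SMO dual solver certifies its solutions: the primal-dual gap bounds
  the distance to the true QP optimum and is checked to 1e-6 in the test
  suite, alongside an independent libsvm reference fit.

## Problem sizes used in the shipped benchmarks

The package's own test suite and the `scripts/acceptance.R` report run the
study design scaled down so a full run stays in the minutes range on one
CPU: the refinement benchmark uses 10 replicate datasets of 200 + 200
sequences of 100 bp (signal width 8 at IC 14 and IC 4, decoy width 8 IC
10, seeds of length 8), and the extension benchmark 10 replicates of 100 +
100 sequences of 100 bp (signal width 18 IC 22, decoy width 18 IC 20,
seeds of length 6). At these sizes the high-IC refinement runs recover
implanted sites with mean nCC and sASP well above 0.5, accuracy rises with
signal IC, and unified extension matches or beats the greedy baseline on
most paired replicates — the same qualitative picture the full-scale
design produces. Full-scale datasets (2000 x 500 bp) are generated and
shape-checked in the tests, and `discover()` runs unchanged on them, just
longer.

## Known limitations

* The alternation is a local method; with argmax background updates it
  carries no monotone convergence guarantee (hence best-iterate return and
  cycle-aware stopping). More elaborate schemes (e.g. convex-concave
  procedures) are out of scope.
* Motif models are position-independent PWMs; no dinucleotide or
  higher-order dependencies.
* Seeding enumerates exact words only (no IUPAC wildcards) and is capped
  at `k <= 10`.
* Real-data background construction (e.g. flank sampling from a genome) is
  outside the package; backgrounds are supplied by the user or simulated.
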