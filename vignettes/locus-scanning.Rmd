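---
title: "Scanning for small non-coding RNA loci: model, training scheme and synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for small non-coding RNA loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small non-coding RNA genes — pre-miRNA hairpins, C/D and H/ACA box snoRNAs —
leave three kinds of footprints in a genome: characteristic sequence elements,
a foldable secondary structure, and elevated evolutionary conservation.
`sncscan` trains a classifier on examples of one such class and then slides it
across large genomic regions (or small RNA-Seq peak intervals) in fixed-width
windows, turning per-window probabilities into locus calls. The package covers
the full loop: interval preparation, feature encoding, the multi-branch
convolutional model, iterative background selection, scanning, evaluation, and
a synthetic benchmark generator that makes the whole pipeline testable without
any reference downloads.

## The model

Each 100-bp window is encoded as up to three aligned feature blocks:

* **S** — one-hot DNA sequence, an L×4 matrix over (A, C, G, T). `N` bases
  become all-zero rows: the row-sum invariant (0 or 1) stays testable and a
  zero row signals absence rather than pretending uniform uncertainty.
* **F** — one-hot dot-bracket secondary structure, L×3 over (".", "(", ")").
* **C** — raw per-base conservation (phyloP-style signed reals), L×1, passed
  to the network without any preprocessing. Positions a track does not cover
  are 0, the phyloP neutral value.

Every enabled block feeds its own *branch*: three 1-D convolutional layers
(ReLU, width-2 max pooling after each). Branch outputs are flattened,
concatenated, passed through one dense ReLU layer, and a single logistic unit
emits a probability. Any non-empty subset of {S, F, C} can be enabled, which
is how the sequence-only, structure-only, and ablated two-branch variants are
built; an S-only model is structurally incapable of reacting to the
conservation input, and the tests assert exactly that.

The published architecture defers per-layer hyperparameters to its
supplement, so this package treats them as configuration with defaults chosen
to train in minutes on a CPU at L = 100: filters 32/64/128, kernel 5, pool 2,
64 dense units, Adam at 1e-3, early stopping on validation loss with patience
5. The test suite uses a smaller, faster configuration (8/16/32 filters, 32
dense units) because the synthetic signal is strong enough that capacity is
not the binding constraint; both are ordinary `model_config()` calls.

Training minimizes binary cross-entropy; with class weighting enabled the
per-class weight is `N_total / (2 * N_c)` (inverse frequency). The headline
published variant disables class weights (the "-U" models), so the weighting
is a single boolean toggle. A weighted 1:4 run is arithmetically identical to
an unweighted run with positives duplicated fourfold, which the tests check
at the loss level.

The network itself is implemented in vectorized base R (BLAS matrix products
over im2col slices) with a compiled C++ forward pass for the high-volume
predict path; the two paths are asserted equal to machine precision, and the
R backward pass is pinned by finite-difference gradient checks. This was a
deliberate build decision: no deep-learning framework is available in the
supported environment, and the model is the package's core contribution
rather than infrastructure to outsource.

## Folding

Scanning-time secondary structure comes from either a precomputed dot-bracket
file (the production path, one `<window_id>\t<structure>` line per window, so
any external thermodynamic folder can be used) or the internal fallback: a
deterministic base-pair-maximizing dynamic program over nested structures
with a minimum hairpin loop of 3 and pairs AU/UA, GC/CG, GU/UG (`N` pairs
with nothing). Traceback ties are resolved by pairing the smallest left index
with its largest admissible partner, making structures reproducible. The
fallback is *not* a thermodynamic model — no stacking energies, no
pseudoknots — but base-pair count is sufficient signal to separate planted
hairpins from background, which is all the test suite requires of it. Its
pair counts are verified against an exhaustive enumeration oracle on short
sequences.

## Interval conventions

Coordinates are BED: 0-based, half-open, strand mandatory ("+" is assumed
and logged when a BED line omits it). Scan preparation extends targets by
±5000 bp and merges same-strand overlapping-or-abutting regions; opposite
strands never merge. Windows of width 100 advance by step 5 for genome-region
scans (step 10 is the convention for peak scans); the window count obeys
`floor((len - width)/step) + 1`.

A prediction *hits* a target when both share chromosome and strand and the
overlap covers at least 50% — inclusively — of the prediction. The published
rule does not say which interval the fraction is relative to; the prediction
was chosen here because scan predictions have fixed width, making the rule
scale-free, and the denominator is an explicit argument for anyone wanting
the target-relative variant.

## Iterative background selection

Random negatives are a weak adversary: a model that separates loci from
uniformly sampled background still fires on "hard cases" when scanning
megabases. The training scheme addresses this in two steps:

1. An ensemble (50 models at full scale; 5 in the desk-scale tests) is
   trained on the same positives, each member against its own random
   negative draw — per positive, `ratio = 4` length-matched intervals
   sampled from candidate background regions, rejecting same-strand overlap
   with positives or already-drawn negatives.
2. Every member scans the training-chromosome regions. Windows scoring
   ≥ 0.5 that hit no true target are false positives; pooled across members
   and clustered by same-strand overlap (single linkage), each cluster's
   support is the number of distinct members contributing a window. Clusters
   supported by at least half the ensemble (25 of 50; 3 of 5 desk-scale) are
   emitted as hard negatives — one representative window per cluster, the
   highest-scoring, ties to the leftmost. The best ensemble member (test-set
   F1 at threshold 0.5, ties to the lower index — the selection criterion is
   unstated in the published description, so F1 was chosen as the metric the
   benchmarks themselves report) donates its negative pool, the hard
   negatives are appended, and the final model is retrained from scratch
   with that member's seed. Whether the published pipeline retrains or
   fine-tunes is unstated; retraining from scratch was chosen as the more
   reproducible default.

Clustering (rather than exact window identity) makes "the same false
positive" well-defined even when members scan at different steps. Hard
negatives keep their genomic identity and are re-encoded from the genome and
track at retraining time, so their provenance is a BED file, not a cached
tensor.

Two retraining details were forced by observed failure modes rather than
taste. First, positive training windows are replicated at offsets
{−7, 0, +7} bp (`augment_positives()`): trained only on perfectly centered
loci while hard negatives sit at arbitrary offsets, the model learns an
exact positional template — scoring a locus 0.95 when centered and ≈ 0 five
bases away — and then misses most step-5 scan windows. Second, a fifth of
the hard negatives goes to the retraining *validation* split: if validation
contains no hard cases, early stopping is blind to whether the model has
learned to reject them, and the retrain either stops before learning
orientation or, run to full budget, memorizes its training loci and fails on
held-out ones.

## Evaluation

Two modes mirror the published benchmarks. *Pre-labelled*: a fixed candidate
set with known labels, standard thresholded confusion counts. *Scanning*:
calls against annotations under the hit rule, with a deliberate asymmetry —
sensitivity is target-level (a target found by any call counts once) while
precision is call-level (every stray call costs). Duplicate hits on one
target credit a single true positive and no false positive. `TP + FN` always
equals the target count.

Precision–sensitivity curves re-derive calls at every threshold (the merge
policy is applied per threshold); the default grid combines quantiles of the
observed scores with a uniform lattice over their range — scan scores pile
up near 0, and a pure quantile grid leaves the informative high-score region
so sparse that sensitivity-anchored thresholds land far below the best
feasible operating point. Sensitivity-anchored operating points — the loose
(S ≥ 0.5) and strict (S ≥ 0.33) thresholds of the published comparisons — are
the highest thresholds reaching the target sensitivity, with an explicit
error (and CLI exit code 3) when unattainable. False-positive density is
reported as scanned bp per false positive. The naive baseline ranks
expression peaks by decreasing expression and calls the top percentile, ties
broken by genomic order.

Window-to-call conversion is itself underdetermined by the published tables,
so both policies are implemented and recorded in every report:
`cluster_max` (one call per overlap cluster, at the maximum-scoring window)
and `none` (every hot window is a call).

## The synthetic world

`synthetic_genome_spec()` states the world once: 3 chromosomes × 50 kb of
i.i.d. background at GC 0.42 (human-like), 60 positive loci (20 per
chromosome), and 20 decoys of each class, all ≥ 100 bp apart on random
strands. Conservation is Gaussian per base — mean +2 inside positives and
conserved decoys, 0 elsewhere, sd 1 — a location shift typical of a clearly
conserved element against a neutral phyloP background.

A positive locus is `box5 + arm + loop + revcomp(arm) + box3`: a 24-bp
random arm, an 8-bp loop opening with a fixed 4-nt motif, and fixed 8-nt
flanking boxes (72 bp total). The boxes are not decoration. A bare hairpin
with strand-symmetric conservation is exactly self-complementary: the
reverse-strand mirror of every positive is indistinguishable from a
positive, capping scanning precision near 0.5 by construction. Real loci
carry strand-asymmetric elements (C/D boxes, mature-arm sequence); the fixed
boxes play that role, give the sequence branch a learnable orientation
signal, and — importantly — make mirror windows into exactly the kind of
hard case the iterative background selection exists to harvest.

The decoy classes isolate single branches so ablations have predictable
winners: `sequence_only` decoys are full positive-like sequences (boxes and
hairpin) over *background* conservation — the conservation branch is the
only thing that can reject them; `conserved_only` decoys are conserved
random sequence — structure and sequence must reject them.

What a green end-to-end test does establish: the full pipeline (encode →
ensemble → consensus hard negatives → retrain → scan → sensitivity-anchored
evaluation) recovers planted signal with high precision on a held-out
chromosome, and hard-negative mining measurably reduces scanning false
positives. What it does not establish: performance on real genomes — the
synthetic world has no repeats, no transcriptional noise, no miRNA-like
sequence statistics, and its conservation is i.i.d. Gaussian rather than
autocorrelated. The published genome-scale numbers are not reproducible at
desk scale and are deliberately not claimed.

## Numerical and degenerate-input choices

* Encoded intervals shorter than L are symmetrically zero-padded (structure
  padding is "."; odd remainder pads right); longer ones are center-cropped
  with the floor of the excess cropped left. The published input-length
  policy lives in an unavailable supplement. The pipeline itself, however,
  center-expands annotated loci to the scan width before training
  (`expand_to_width()`), so training examples and scan windows share one
  geometry. This matters: training on padded loci while hard negatives are
  unpadded windows turns "padding present" into a spurious discriminative
  feature, and a model trained that way collapses on real scan windows while
  remaining perfect on its (equally padded) test split — a distribution
  shift observed directly during development. Padding remains the defined
  behavior for genuinely short inputs.
* Precision with zero calls is 0; F1 with P + S = 0 is 0 — reports are total
  functions.
* Cluster tie-breaks (scores, indices) always resolve deterministically to
  the leftmost/lowest.
* Ensemble member *i* uses seed `base_seed + i` for its negative draw,
  initialization and shuffling; every stage takes an explicit seed and equal
  seeds give byte-identical BED/TSV outputs.
* The chromosome-level split keeps the per-model test chromosome out of
  train/validation; the left-out evaluation chromosome is outside the
  training run entirely. With the default 3 chromosomes the early-stopping
  validation examples are a random 15% of training-chromosome positives
  (plus their negatives) rather than a third chromosome — a compromise the
  default world size forces.

## Known limitations

The internal folder maximizes pair count, not free energy. The CNN is small
and CPU-bound by design; no GPU path exists. Scanning loads per-region
encodings into memory (regions-in, calls-out; no streaming whole-genome
orchestration). The synthetic generator makes no attempt to mimic real
small-RNA sequence statistics, and conclusions from it transfer to real data
only qualitatively.
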