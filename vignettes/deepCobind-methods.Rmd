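---
title: "Discovering co-factor binding features from differential TF ChIP-seq"
author: "deepCobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering co-factor binding features from differential TF ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A transcription factor (TF) that is broadly bound across several tissues
can gain or lose occupancy at particular sites because a tissue-specific
co-factor binds nearby.  Differential analysis of the anchor TF's
ChIP-seq across tissues therefore carries information about *where the
co-factor binds*, even when the co-factor itself was never assayed.
deepCobind implements the full route from differential binding tables to
candidate co-factor sites:

1. train convolutional models that predict, from DNA sequence alone,
   either the per-replicate binding intensity (log-RPKM regression) or
   the differential class of a region (up-/down-binding in each tissue
   versus non-differential);
2. attribute a chosen class's prediction back to individual nucleotides;
3. rank 25-nt windows by attribution and validate the top windows
   against an independent read profile with a motif-centre Poisson test;
4. quantify how repeatable the selected windows are across model
   initializations with a feature-stability estimator.

Because the high-dimensional classification task is small and easily
overfit, the package provides three ways to regularize it with the much
larger regression task: **transfer** (copy and freeze a trained
convolution), **serial** (stack a small classifier on a frozen deep
regression trunk) and **parallel** multitask training (shared trunk,
alternating batches).

## Models

*Shallow CNN.*  One convolution (ReLU) followed by concatenated global
max- and average-pooling (2 × `nFilters` features) and fully connected
layers.  Max-pooling alone is insensitive to motif multiplicity, which
distorts perturbation-based attribution; the paired average-pool channel
repairs that while keeping translation invariance.

*Deep CNN.*  `nPoolBlocks` blocks of convolution → batch-norm → ReLU →
1× bottleneck convolution → dropout → max-pool, followed by
`nDilBlocks` dilated blocks of the same composition whose outputs are
concatenated channel-wise onto the running representation
(hyper-residual), then a linear 1× convolution and global average
pooling per output head.  The dilation rate starts at `dilationBase`
and multiplies by `dilationGrowth` per block, capped at `maxDilation`
(default 4; deeper dilation rates were consistently the better end of
the range we explored, so the cap is exposed as a parameter).
Counting the 1× convolutions, a 3-pool/7-dilation model has
`2*3 + 2*7 + 1 = 21` convolutional layers.

*Structural calculators.*  The receptive field is computed analytically
as `RF = 1 + sum_i (k_i - 1) d_i prod_{j<i} s_j` over convolution and
pooling layers, and is verified in the test suite against a
perturbation oracle on random architectures.  Input lengths for deep
models are sampled uniformly from `[RF, 2 RF]` and clipped to the
encodable range [200, 2000] nt; a spec whose clipped window cannot
contain its input length is rejected at construction.

*Conventions.*  Sequences are one-hot encoded in fixed A,C,G,T order,
centred in the target length (zero-padding split evenly, the odd base
going right; centred cropping when too long), with ambiguous bases as
all-zero columns.  Regression targets are `log(RPKM + 1)` (natural log;
the pseudocount guards zeros and is configurable).  All file
coordinates are BED-dialect 0-based half-open.

The network engine (1D dilated convolution via im2col, batch-norm,
max/avg pooling, dense layers, Adam, softmax and MSE losses) is
implemented inside the package with exact analytic gradients; the
im2col/col2im and pooling kernels are compiled C++ for speed.  Every
layer's backward pass is checked against central finite differences in
the test suite, which is what qualifies the same machinery to produce
gradient-based attributions.

## Training protocol

A fifth of the data is held out for test; the remainder is split into
3 stratified folds.  Each candidate architecture is trained per fold
with patience-based early stopping on the validation loss, restoring
the best-epoch weights.  The mean of the per-fold *training* losses at
the stoppage points becomes the stopping criterion when the winner is
retrained on all cross-validation data without a validation set — the
two-stage criterion keeps the final model from over-training relative
to what cross-validation supported.

Reverse-complement augmentation duplicates every example of the rarest
down-binding class as its reverse complement; any other class whose
count is below the augmented count is likewise fully duplicated.
Augmentation is applied to training/validation data only, never to the
test split, and test metrics are always computed on un-augmented data.

In parallel multitask training the heads (regression, down-binding,
optionally up-binding with a shared non-differential class) take
minibatches in a fixed cyclic order — regression, down, up — each batch
updating the shared trunk and its own head.  The alternation is per
batch rather than per epoch, and early stopping monitors the summed
*classification* validation loss only, so deterioration of the
auxiliary regression loss never stops training.  Cyclic order was
chosen over random interleaving for determinism.

Frozen stages (transfer and serial modes) never receive optimizer
updates — the freeze is bitwise, asserted in the tests.  Because a
frozen trunk's outputs cannot change, both builders precompute those
outputs once and train the classifier candidates on the cached
features; the assembled model is still a single end-to-end
differentiable graph so that attribution reaches the input.

## Attribution

All methods operate on the raw pre-softmax logit of the chosen class;
softmax normalization couples classes and flattens gradients, and
feature localisation is consistently better on logits.

- *In silico mutagenesis*: the L×4 map of logit changes for every
  single-base substitution, batched; entries at the reference base and
  at padded positions are exactly zero.  Per-nucleotide importance is
  `-1` times the row sum, so positive scores mark bases whose mutation
  would lower the class logit.  The raw logit deltas are kept
  (no post-hoc rescaling).
- *Integrated gradients*: mean of input gradients at `s/steps`
  interpolants between a reference and the example (right-endpoint
  rule), times `(x - x')`, channel-summed per position, averaged over
  the reference set.  Interpolants are not one-hot; the graph is
  defined on real-valued inputs, so that is acceptable.  A zero
  reference or a set of real non-differential regions may be used.
- *Gradient × input* is exactly integrated gradients with one step and
  a zero reference — asserted to machine precision in the tests.

The summation-to-delta (completeness) diagnostic reports
`|sum(attribution) - (f(x) - mean_ref f(x'))| / |f(x) - mean_ref f(x')|`;
it is identically zero for affine models at any step count, and the
package reproduces the need for several hundred steps (≤ 5% deviation
at 512 steps) on trained nonlinear models.  Degenerate denominators are
flagged and excluded from aggregates.

Feature calls maximize the attribution sum over sliding 25-nt windows
(stride 1, leftmost tie-break) and are ranked dataset-wide by score
with ties broken by region identifier.  Ensemble attribution averages
tracks over fold models; held-out mode attributes each region only with
the model that excluded it.

## Validation

*Motif-centre Poisson test.*  For each called window, reads of two
validation replicates are counted in a 500-nt window centred on the
feature midpoint and compared with the expected count λ under a Poisson
background.  λ defaults to the dataset-wide mean read rate times the
window (a MACS-style local-maximum λ over 1/5/10-kb windows is
available as an option); `P(X ≥ k)` is the upper tail, defined as 1 at
`k = 0`, and a feature passes only when `P < 0.05` in *both*
replicates.  The pass-proportion curve reports the passing fraction of
the top-n features as n grows, next to a baseline in which each
feature's position is re-drawn uniformly within its region.

*Stability estimator.*  Each model instance's 25-nt mask over a region
is a selection of k of d positions.  With `s_f^2` the unbiased sample
variance of position f's selection indicator across models,
`Phi = 1 - mean_f s_f^2 / (kbar/d (1 - kbar/d))`, averaged over
regions: exactly 1 for identical masks, 0 in expectation for
independent uniform selections.  Regions where every or no position is
selected have an undefined denominator and are excluded (and counted).
`stabilityExperiment()` retrains a model `nModels` times with different
initialization seeds on identical data and evaluates Phi over a fixed
region sample.

## The synthetic data generator

The generator is the package's test bed and the source of every
empirical number in the acceptance material.  It emulates a three-tissue
differential ChIP-seq study (replicates 2, 2 and 4 by default):

- regions of 200–2000 nt (drawn uniformly) of i.i.d. uniform background
  sequence, each carrying one instance of an anchor-TF motif at a
  uniform-random position;
- each differential class additionally carries one co-factor motif
  instance (placed to avoid the anchor): the co-factor active in every
  tissue *except* t drives class `down_t`, the one exclusive to t
  drives `up_t`;
- per-replicate RPKM = a log-normal baseline (median 10, sdlog 0.5)
  × `cofactorEffect` (default 4) in tissues where the region's
  co-factor is active × log-normal replicate noise (sdlog 0.3);
- labels come from a fold-change threshold rule (mean RPKM of one
  tissue ≥ 2× / ≤ ½× the other tissues' means) standing in for an
  edgeR-style analysis — the pipeline consumes labels as given, so only
  the label semantics need to be right, not the test statistics;
- two replicates of validation reads: 70% of each replicate's depth is
  multinomially assigned to planted co-factor sites and scattered
  Normal(site centre, 50 nt); the rest is uniform background.  This
  mimics a co-factor ChIP experiment concentrated at true sites;
- all regions are laid end-to-end (1-kb random spacers by default) on one
  synthetic contig, so BED intervals, read positions and the Poisson
  test's genome span are genuine genome coordinates.

Motif PWMs are built from a consensus with probability 0.95 on the
consensus base per position (configurable).  This models the sharp,
high-information-content consensus sites of strong ChIP-derived motifs;
at substantially lower concentrations the planted instances degenerate
(≥ 1 expected mismatch in a 7-mer) and the discovery task stops being
solvable at the few-thousand-region scale this package targets — real
studies compensate with orders of magnitude more regions.

What the generator does *not* model: GC or repeat structure of real
genomes (an optional first-order Markov background would be the first
extension), fragment-length effects in read placement, co-operative
spacing constraints between anchor and co-factor, and diploid variation.
Passing tests on synthetic data therefore demonstrate that the
machinery is correct and that the method recovers planted signal under
its stated assumptions — not that any particular biological dataset
would yield the same accuracy.

## Problem sizes and numerical choices

The bundled experiments are sized for a single CPU core: the
completeness calibration trains a 2-pool/2-dilation model
(~20k parameters) on ~2000 fixed-length 300-nt regions for up to 10
epochs and checks 50 regions at 512 integration steps; the end-to-end
feature-recovery experiment evaluates 500 labelled regions per class,
with the serial trunk trained on a larger 10,500-region companion
regression dataset (batch 64, 16 epochs — below ~5,000 regions the
deep trunk's feature-discovery phase does not reliably begin within a
CPU-scale epoch budget, which is the package-scale expression of deep
models needing more data); the stability and regularization-ordering
comparisons use reduced model counts (5 models, 200 regions) and
seed-averaged means over 3 seeds.  These sizes are deliberate
scale-downs of the corresponding full-size experiments, which used
GPU-scale models on hundreds of thousands of regions; at the reduced
scale the end-to-end recovery and stability orderings are preserved,
while comparisons that require every competing model to be trained at
learnable scale (a dozen deep models) exceed what a CPU-scale budget
can demonstrate.

Numerical details worth knowing:

- convolutions use same-padding everywhere so spatial arithmetic is an
  exact power of the pool width; max-pooling drops a trailing remainder
  (`floor(L / w)` outputs) and breaks ties to the first maximum;
- batch-norm uses batch statistics in training and running averages
  (momentum 0.1) in evaluation; its backward pass is implemented for
  both modes because attribution differentiates the evaluation graph;
- Adam with bias correction, β = (0.9, 0.999), ε = 1e-8; He
  initialization; early-stopping improvements must exceed 1e-9 to
  count;
- the softmax cross-entropy is computed via a log-sum-exp shift, and
  pre-softmax logits of every classification head are exposed
  directly;
- fresh randomly initialized networks here are positively homogeneous
  (zero biases), which makes integrated gradients exact at any step
  count — completeness experiments are therefore only meaningful on
  trained (or bias-perturbed) models;
- all entry points consume a single integer seed; with equal seeds and
  configs, dataset generation and every training mode are bitwise
  reproducible on one machine.

## Known limitations

- The engine is CPU-only and dense; it is sized for the desk-scale
  experiments above, not for genome-wide training.
- The serial and transfer builders search a small explicit list of
  classifier architectures rather than a full random search; the deep
  and shallow family searches sample architectures but not optimizer
  schedules.
- The Poisson test treats read positions as exchangeable single-base
  anchors; fragment-level effects (shift, duplication) are out of
  scope.
- Labels enter as hard classes; the conservative-labelling argument for
  prioritizing recall over precision applies to real data but has no
  analogue in the generator, whose labels are noiseless given the
  threshold rule.
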