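---
title: "GridTox: multi-channel molecular grids for toxicity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GridTox: multi-channel molecular grids for toxicity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GridTox)
options(GridTox.quiet = TRUE)
```

## Overview

GridTox turns a small molecule into a stack of six single-channel images
and classifies the stack with a small convolutional network, one
independent binary model per toxicity endpoint. The pipeline is:
standardize → deduplicate → embed in the plane → type atoms into channels →
render potential grids → (rebalance) → train → evaluate. This vignette is
the package's account of each step: the assumptions, the tunable
parameters, and the places where the design was genuinely open and a choice
had to be made.

## Standardization and deduplication

Input molecules (SMILES tables or SDF) are sanitized with the OpenBabel
toolkit: explicit hydrogens are added, aromaticity is perceived, and a
canonical SMILES plus a full 27-character InChIKey are recomputed. Records
that fail sanitization are dropped with a logged reason; a batch only fails
when nothing survives.

Deduplication groups records by InChIKey. When any endpoint carries
conflicting non-missing labels inside a group, the *whole group* is
deleted; this is the most conservative reading of "conflicting duplicates
are removed", and deliberately refuses to guess which record is right.
Non-conflicting groups are merged into one record holding the union of
non-missing labels — the merge rule is our choice; deletion-on-conflict is
the only rule the procedure inherently requires. Both operations are
idempotent, which the test suite checks directly.

## Atom typing

The six channels are: hydrogen bond, hydrophobicity, metallicity, excluded
volume, positive ionization, negative ionization. No published rule set
accompanies this channel list, so the package ships one as a versioned
data file (`inst/extdata/typing_rules.json`, Bondi-type radii in
`vdw_radii.tsv`) using standard pharmacophore conventions:

* **Hydrogen bond** — donors are N/O/S bearing at least one explicit
  hydrogen; acceptors are oxygens (non-positive charge), nitrogens that are
  not aromatic N–H (pyrrole-type) and not positively charged, and divalent
  sulfur. The heavy atom carries the channel, never the hydrogen. Amide
  nitrogens pass the acceptor rule; they are weak acceptors and excluding
  them would require an electronic model we deliberately avoid.
* **Hydrophobicity** — carbons with no N/O/S neighbour, plus halogens.
  Whether halogens belong here is a judgement call; we include them because
  halogens dominate the hydrophobic ends of many toxicants and the channel
  would otherwise ignore them entirely.
* **Metallicity** — membership in a packaged metallic-element list.
* **Excluded volume** — every atom including explicit hydrogens: this
  channel encodes molecular shape. All other channels operate on heavy
  atoms only.
* **Ionization** — positive: charged nitrogens, aliphatic amines (all
  single bonds, heavy neighbours all non-aromatic carbons without double
  bonds to O/N/S), and amidine/guanidine nitrogens. Negative: negatively
  charged O/S/N, carboxylic, sulfonic and phosphonic acid oxygens, and
  tetrazole ring nitrogens. These are the common ionizable-group
  definitions at physiological pH, applied as graph rules over the
  connection table — no pKa model is used.

Unknown elements fall back to a 1.70 Å radius with a warning rather than
failing, so exotic species degrade gracefully.

The 12-10 hydrogen-bond coefficients follow the AutoDock per-class
convention `C = 5 ε r_eq^12`, `D = 6 ε r_eq^10`, with (ε = 5, r_eq = 1.9 Å)
for N/O and (ε = 1, r_eq = 2.5 Å) for S; the well then has its unique
minimum of exactly −ε at r_eq, which the tests verify numerically to 1e-6.
A literal reading of the method description would assign C to N/O atoms and
D to S atoms, which cannot produce a well at all; we read it as a garbled
description of the per-class (ε, r_eq) parameters and emit both
coefficients per atom class.

## Grid construction

**Coordinates.** Grids are two-dimensional by design — the method operates
on depiction-style layouts, not on 3D conformers, so no conformer search is
performed. The depiction coordinates are rescaled to a mean bond length of
1.5 Å (a typical heavy-atom bond), the centroid is moved to the origin and
the first principal axis is rotated onto x, with third-moment sign
conventions breaking the reflection ambiguity. Featurization is therefore
a pure, deterministic function of the molecular graph. A `canonical = FALSE`
flag disables the rotation, which the rotation-covariance tests use.

**Geometry.** The window is 24 Å × 24 Å with 0.5 Å pixels (48 × 48) by
default; 1 Å and 2 Å are supported for the resolution sweep. Pixel centres
sit at −L/2 + (i − 0.5)Δ; row 1 is the minimum-y row; values are evaluated
at pixel centres, not averaged over pixels. Molecules wider than the window
trigger a warning but are never rescaled — rescaling would silently distort
the physical distances both equations depend on; out-of-window atoms still
contribute their tails to in-window pixels.

**Numerics.** The van der Waals term is computed as `-expm1(-(r_vdw/r)^12)`:
exact at r = 0 (limit value 1, no singularity to guard) and accurate in the
far field, where terms underflow to zero naturally — no distance cutoff is
needed. The 12-10 potential is singular at r = 0, so distances are clamped
at 0.5 Å and summed pixel values clipped to ±50 (ten times the deepest
well); both guards are logged when they fire. The clip bounds the CNN
inputs without touching the physically meaningful well region. Vectorized
grids agree with a naive per-atom/per-pixel double loop to better than
1e-9, checked over 100 random fixtures.

An ambiguity worth recording: the channel list places hydrogen bond first,
while the equation text speaks of the "first five" channels using the vdW
form. The figure captions name the five vdW channels explicitly
(hydrophobicity, metallicity, excluded volume, both ionizations), so that
reading wins: the hydrogen-bond channel uses the 12-10 equation and the
other five the vdW equation.

## Class imbalance

SMOTE is applied to flattened grid vectors of the *training split only* —
feature-space interpolation is the method's standard formulation, and
resampling evaluation splits would leak. Synthetics are
`x_i + u (x_nn − x_i)` with u uniform and x_nn among the k = 5 nearest
minority neighbours; generation runs until minority/majority reaches the
target ratio (default 1.0). Originals are always preserved and majority
samples never touched. Class weights (`w_pos = n_neg/n_pos`, `w_neg = 1`)
are available as an independent switch; the default is SMOTE on and weights
off, because applying both over-corrects the positive class twice. The
phrase "one-hot coding" in the source description is not precisely
interpretable for a binary head; the model uses a single sigmoid output,
and both imbalance mechanisms are exposed so either reading can be run.

## The classifier

Four hidden layers: three convolution blocks (3×3 kernels, same padding,
rectifier, 2×2 max-pool, filters 32/64/128) and one dense rectifier layer
(default 128 units), then a single sigmoid unit. The activation and
optimizer are not pinned down by the method description; we use the
rectifier and Adam, the standard choices for this architecture family, with
learning rate 1e-3, L2 weight decay 1e-3, batch size 32 and 20 % dropout on
the input layer only. Training runs a fixed 60 epochs by default ("epochs"
is our reading of the method's 60 training iterations, matching its
60-point loss curves); early stopping is off by default. Batch
normalization is mentioned in passing in the source description but is not
part of the specified architecture; instead inputs are standardized per
channel with training-set statistics (`scaleInputs = TRUE`), which is
logged in the model metadata.

The network is implemented directly on base-R matrix algebra (im2col plus
BLAS products). Correctness is established by tests rather than trust in a
framework: analytic gradients agree with central finite differences on
every layer, the loss agrees with a scalar-loop oracle to 1e-9, and with a
fixed seed two training runs produce bit-identical loss histories (all
randomness — initialization, shuffling, dropout — flows from the config
seed). Max-pool ties route the gradient to the first tied element in scan
order, a deterministic convention. Divergence (non-finite loss) aborts with
a diagnostic rather than returning a broken model.

Evaluation is threshold-free: ROC by sweeping the score threshold with
tied scores collapsed into a single step (the curve takes the diagonal
through ties), AUC by the trapezoidal rule — equivalent to concordant-pair
counting with ties at half, which the tests verify exhaustively and against
an independent ROC implementation. Single-class splits yield NA with a
warning rather than a fabricated number.

For the depth sweep, a model with d hidden layers has d − 1 conv blocks
(filters doubling from 32) plus the dense layer, matching the reading that
the default "4 hidden layers" = 3 conv + 1 dense. Note that *total*
parameter counts do not grow monotonically with depth in a pooled
architecture — each extra pooling stage shrinks the flatten layer — so the
harness asserts growth of the convolutional stack instead.

## Synthetic benchmarks

The generators produce everything the tests need without downloads:

* `makeGridFixtures()` — random toy molecules with hand-assigned channel
  flags and radii in [1.0, 2.2] Å, bypassing chemistry so the grid
  equations are tested in isolation.
* `makeSeparableDataset()` — the learnability benchmark. Every molecule is
  a random 8–14-atom scaffold plus a three-atom cluster; in actives the
  cluster is flagged negative-ionization, in inactives it is not, and
  nothing else differs systematically. Coordinates get 0.3 Å jitter —
  enough to prevent pixel-identical grids at 0.5–2 Å resolutions while
  keeping the motif compact, chosen once. Defaults: 60 molecules per class,
  24 Å window at 1.0 Å resolution, 75/25 stratified split. The coarser
  default (and the 2 Å setting used for ablation and null-control runs,
  both resolutions from the supported sweep) keeps a full training run in
  tens of seconds on one CPU; the vignette-level problem sizes are the
  package's own fixture-scale choices. `motif = FALSE` yields a null
  dataset with no class signal, and `imbalanceRatio` reproduces scenarios
  like the 33:1 endpoint for SMOTE tests. The metallicity channel is
  identically zero — a null channel for ablation controls.
* `makeSmilesFixtures()` — a curated labeled SMILES table covering every
  typing rule plus consistent and conflicting duplicate pairs.

What the generators deliberately do **not** emulate: real chemistry
distributions, ring-system diversity, label noise, or cross-endpoint
correlation. Passing the synthetic benchmarks shows the pipeline is
implemented correctly — the grids carry the planted information and the
network can extract it — not that any particular real-data AUC will be
reached. Reproducing published endpoint AUCs additionally requires the
actual dataset and its cleaning, which the package does not download.

## Limitations

* Channel rules are heuristic graph predicates; no pKa, tautomer or
  partial-charge model. Borderline groups (amide N as acceptor, halogens
  as hydrophobes) follow the documented conventions above.
* 2D layouts discard conformational information by construction.
* The pure-R network is sized for grid inputs up to 48 × 48 on one CPU;
  it is not a general deep-learning engine (no GPU, no batch
  normalization, no augmentation).
* The 12-10 channel's units are treated as unitless features; its clip
  bounds are a modelling guard, not physics.
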