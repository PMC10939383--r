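---
title: "Voxel-based fixed-backbone sequence design: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based fixed-backbone sequence design: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdesign)
```

## The problem and the representation

Fixed-backbone sequence design asks: given only the backbone geometry of a
protein (N, C&alpha;, C, O), which amino-acid sequence is most likely to fold
back into it? voxdesign treats this as residue-wise classification. For every
residue we cut a cubic *frame* of space around its C&alpha; (edge 12 &Aring;
by default), discretise it into 21&times;21&times;21 voxels, and render every
backbone atom that falls inside into an element-specific channel. A 3D CNN
maps each frame to a 20-class probability distribution, so a protein of *n*
residues yields an *n* &times; 20 row-stochastic matrix from which sequences
are decoded (argmax) or sampled (temperature Monte Carlo).

Two conventions make the representation well-behaved:

* **Canonical orientation.** Before voxelisation the structure is rigidly
  moved so the target C&alpha; sits at the origin with the N&ndash;C&alpha;&ndash;C
  plane on the XY plane. The essential commitment is only the plane; the
  in-plane orientation is a package convention (C&alpha;&rarr;N along +X, C at
  positive Y). Any fixed convention gives the property that matters: frame
  tensors are invariant to rigid motions of the input, which the test suite
  checks end to end at 10^-6^ (tensors) and 10^-4^ (predictions).
* **Virtual C&beta;.** Side chains are discarded, but every residue
  (glycine included) receives an ideal tetrahedral C&beta; constructed from
  N/C&alpha;/C (bond 1.522 &Aring;, L chirality). Because the construction uses
  backbone atoms only, it gives the network a side-chain direction cue
  without leaking the residue identity it must predict.

Atoms are rendered as truncated Gaussians, `exp(-d^2 / (2 sigma^2))` with
`sigma = r_vdw / 2` (C 1.70, N 1.55, O 1.52 &Aring;), cut at `2 sigma` and
accumulated additively; an occupancy mode (nearest voxel set to 1) is also
available. The Gaussian parameterisation is a package choice: peak 1 at the
atom centre, compact support, deterministic.

### Constraint channels

A design constraint can be injected as one extra channel holding a
per-residue value at each C&alpha; voxel: either **polarity** (Zimmerman
scale, threshold 20: values below 20 are non-polar, -1; others polar, +1 --
under this published threshold the polar class is exactly R, K, H, D, E) or
**formal charge** (D/E &rarr; -1; K/R/H &rarr; +1; else 0; histidine is grouped
with the basic residues as a convention). At design time user-supplied
values override the sequence-derived ones at chosen sites ("fix sites"),
which is how re-painting of surfaces or interfaces is expressed.

## Training: undersampling with per-epoch resampling

Amino acids are far from uniformly frequent, and a classifier trained on raw
counts inherits that prior. voxdesign balances classes in the sampler, not
the loss: each epoch caps every class at the count of the rarest class
present in the split, draws a fresh uniform subset (without replacement,
from the class's *full* pool) for every over-represented class, and
shuffles. Re-drawing per epoch means the network sees many more unique
frames over a run than a single capped draw, while every epoch stays
balanced. Plans are keyed by `(seed, epoch)` so they are reproducible and
independent of evaluation order. Balancing applies to train and validation
splits, never to test, and splits are assigned at *structure* level so
overlapping frames of one protein cannot straddle a split boundary.

## Architectures

The engine implements three families on a common layer set (im2col 3D
convolution, ELU, spatial dropout, global average pooling, dense, softmax
cross-entropy, Adam):

* `timed` -- convolutional blocks with **spatial dropout** (whole feature
  maps dropped) after each block and a **global-average-pooling** head.
  These two commitments preserve and enforce spatial structure; block
  sizes (default 32/64/128 filters, two 3&times;3&times;3 convolutions each,
  dropout 0.1) are configurable.
* `prodconn_like` -- convolutions followed by flatten + dense hidden layer,
  the classic image-classifier head; kept as the contrast case.
* `densenet3d` -- densely connected blocks (same-padded convolutions whose
  outputs concatenate onto the channel stack, growth 8) with 1&times;1&times;1
  transitions and a GAP head.

Exact layer counts of the published networks live in supplementary
diagrams and upstream papers; the defaults here honour the stated
architectural commitments and leave the rest configurable rather than
guessing. Optimiser defaults (Adam, 10^-3^, batch 64) are package choices.

## Sampling and the temperature convention

Temperature rescaling is applied in log-probability space:
`softmax(log(p) / T)`, i.e. `p^(1/T)` renormalised. Fed literally with raw
probabilities, the usual temperature-softmax expression would *not* return
the input distribution at T = 1, contradicting the intended limits; taking
the logits as log-probabilities makes all three stated limits hold exactly:
T = 0 is argmax (ties to the lowest class index), T = 1 is the identity, and
T &rarr; &infin; tends to uniform over the support (zeros stay zero). This
interpretive choice is the package's; it is recorded here deliberately.
Positions are sampled independently -- the models predict each frame
independently, and no autoregressive coupling is attempted.

## Metrics

* **Macro-recall** -- mean of per-class recalls; robust to composition. A
  constant predictor against a reference containing all 20 classes scores
  exactly 1/20 = 5%. Classes absent from the reference are excluded from
  the mean (the formula is undefined for them); a strict mode divides by 20.
* **Prediction bias** -- 100 &times; (predicted - true count)/positions per
  class; signed, sums to zero.
* **Charge / pI** -- Henderson-Hasselbalch net charge over termini and
  D, E, C, Y, H, K, R with the EMBOSS pKa set; pI by bisection on pH
  &isin; [0, 14] to |charge| < 10^-4^. The pKa set is a convention (none is
  named for the reference implementation).
* **Shannon entropy** -- per-row, base 2 ("0 log 0 = 0"); the 20-class
  maximum is log2(20) = 4.32 bits. Mean entropy serves as a cheap
  confidence proxy.
* **RMSD / RMSD100** -- Kabsch-superposed C&alpha; RMSD with sequential 1:1
  correspondence (compared structures are same-length by construction in
  this package, so no structural aligner is needed), normalised as
  RMSD / (1 + ln sqrt(n/100)).
* **Packing density** -- per residue, the count of backbone N/C&alpha;/C/O
  atoms (any residue, own included; virtual C&beta; excluded) within 7
  &Aring; of its C&alpha;. Centre atom, self-inclusion and C&beta; exclusion
  are logged conventions.

## The synthetic task: what it emulates and what it does not

Training the published models requires tens of thousands of experimental
structures and GPU-scale compute, which is out of scope here. Instead the
package ships a first-class generator of ideal backbones from internal
coordinates (standard bond lengths/angles; helix phi/psi = -57/-47, strand
-135/+135, omega 180) and a geometry-labelled classification task: mixed
helix/strand/coil structures (segments roughly 60/30/10, so the label
distribution is skewed and balancing has work to do) with 0.05 &Aring;
Gaussian coordinate jitter, labelled by a deterministic torsion rule
(within 30 degrees of the helix basin &rarr; 'A', of the strand basin &rarr;
'V', else 'G'). A fifth of the helix-segment torsions are drawn in an
annulus straddling the 30-degree labelling edge (d ~ U(18, 34), so in
truth three of four shell points carry the helix label), which makes a
band of frames genuinely hard; the coil torsions sit in a left-handed
basin far from both targets. The shell's 3:1 composition mirrors the
global helix:coil imbalance on purpose: a balanced sampler then sees
symmetric evidence on either side of the edge and places the decision
boundary near the true one, while an unbalanced sampler is pulled outward
by the majority class and over-predicts it -- the frequency-bias mechanism
the evaluation suite measures.

Because the label is a deterministic function of frame geometry, a
consistent classifier can recover it: a 1-nearest-neighbour baseline
exceeds 95% accuracy, and a tiny `timed` model (two blocks, 16/16 and
32 filters, trained 15 epochs at batch 8, learning rate 10^-2^ on 600
frames of 9^3^ voxels) reaches held-out macro-recall >= 0.9 in about ten
seconds on one CPU. These problem sizes were chosen to keep the full suite
quick at desk scale while leaving the learning problem non-trivial.

What passing these tests shows: the voxel representation preserves the
geometric signal, the training loop optimises it, balancing does what it
promises mechanically (uniform per-epoch class counts, fresh redraws), and
the whole pipeline is rigid-motion invariant. What it does not show:
performance on real proteins, where frames contain side-chain-shaped
cavities of *neighbouring* residues, labels are not a deterministic
function of local geometry, and twenty classes compete at natural
frequencies. Benchmark-level sequence recovery is explicitly not
reproduced here.

On the synthetic task the balanced/unbalanced contrast deserves one
honest note. With a deterministic label rule, ambiguity is concentrated
in the boundary shell, and the bias a model shows there reflects the
class frequencies of its training stream: an unbalanced stream pulls the
decision boundary outward and systematically over-predicts the majority
class -- the direction the test suite asserts at matched initialisation
and seed, with comparable macro-recall between regimes. The converse
claim, that balancing drives the *magnitude* of the bias below the
unbalanced model's, does not transfer cleanly to a deterministic-label
world: undersampling keeps every minority frame while subsampling
majority frames, so inside the shell the balanced stream over-represents
the minority by the same factor the unbalanced stream over-represents the
majority, and at convergence both regimes approach zero bias. The test
suite measures that comparison as specified (pooled over three paired
runs) and reports it; its run-to-run sign is dominated by boundary
wobble, which is itself informative about what class balancing can and
cannot do when labels are a deterministic function of the input.

## Numerical choices and degenerate inputs

* Voxel grids are zero-centred with odd `voxels_per_side` enforced, so the
  central C&alpha; falls in the centre voxel; boundary atoms are included at
  |coordinate| <= edge/2.
* Collinear N-C&alpha;-C triples (cross-product norm < 10^-6^) raise a
  degenerate-geometry error; `voxelise_structure` skips and reports them.
* Alternate locations: blank or 'A' kept; MSE read as methionine; other
  non-canonical residues skipped with a warning; first model only of
  multi-model files. These parsing rules are declared conventions, not
  inferred behaviour of any reference tool.
* Ties in argmax decoding go to the lowest class index, making decoding
  deterministic and platform-independent.
* All randomness (splits, epoch plans, dropout, sampling, jitter) flows
  from integer seeds through R's default generator; derived stream keys
  stay below 2^31.

## Known limitations

* The CNN engine is compact and CPU-oriented; it is suitable for the
  desk-scale experiments the package targets, not for training on large
  structure collections.
* No structural aligner is included: RMSD assumes equal-length,
  sequentially corresponding chains.
* mmCIF input, assemblies, hydrogens and solvent are out of scope; PDB
  ATOM records are the interchange format.
* The dataset container is an RDS serialisation of the tensor stack with
  labels, metadata and configuration; it round-trips bit-exactly and
  exports class counts to CSV.
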