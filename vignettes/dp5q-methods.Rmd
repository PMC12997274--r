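---
title: "Quantile-regression shift prediction and DP5q confidence scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-regression shift prediction and DP5q confidence scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Confirming that a proposed small-molecule structure matches a recorded
carbon-13 NMR spectrum is routine when a reference spectrum exists and
hard when it does not. Point predictions of chemical shifts help -- a
candidate whose predicted shifts sit far from the observed peaks is
probably wrong -- but a mean absolute error alone does not say *how
probable* it is that the assignment is correct: 2 ppm of error means
something very different for a quaternary aromatic carbon than for a
methyl group, and different again for a model that is simply uncertain
about that environment.

This package takes the distributional route. A graph neural network
predicts, for every carbon atom, the full inverse cumulative distribution
of its chemical shift on a grid of 99 quantiles (percentiles 1--99). The
0th and 100th percentiles are deliberately excluded: they correspond to
the extremes of the training data, not to parameters of a conditional
distribution. Given an experimental peak list, each atom's observed error
is converted into the probability mass the model itself places within
that error of its median,

$$P_i = F_i(\hat y_i + |\hat y_i - y_i|) - F_i(\hat y_i - |\hat y_i - y_i|),$$

and the atomic confidence is $\mathrm{DP5q}_i = 1 - P_i$. A molecule's
score is the geometric mean of its atomic scores, so a single clearly
inconsistent atom drags the whole molecule down -- which is exactly the
behaviour wanted when screening wrong proposals. An atom whose observed
shift falls on the predicted median contributes 1; an atom far outside
its predicted distribution contributes approximately 0, and a zero
propagates.

## The training objective

The model is trained by minimising, per atom, a sum over all grid
quantiles of an asymmetrically weighted, smoothed absolute error, plus a
crossing penalty:

* **Modified Huber core.** For residual $r = y - \hat y_\tau$ the loss is
  $r^2/(2\delta)$ for $|r| \le \delta$ and $|r| - \delta/2$ beyond, with
  $\delta = 10^{-4}$ ppm. This is within $\delta/2$ of the absolute error
  everywhere, so it is numerically indistinguishable from pinball loss at
  this $\delta$, while keeping a continuous gradient through $r = 0$ --
  the point a converged quantile sits at -- which matters for stable
  optimisation.
* **$\tau$-weighting.** Under-predictions are weighted by $\tau$,
  over-predictions by $1-\tau$: at $\tau = 0.75$ an under-prediction
  costs three times an over-prediction, and at $\tau = 0.5$ the two cost
  the same, so each output head converges to its quantile.
* **Crossing penalty.** Nothing in the per-quantile loss forbids the
  predicted 90th percentile from dipping below the 80th ("quantile
  crossing"). A hinge term $\sum_k \max(0,\ \hat y_{\tau_k} - \hat
  y_{\tau_{k+1}} + \varepsilon)$ with $\varepsilon = 10^{-6}$ penalises
  any violation of the non-decreasing property; the total loss is the sum
  of the two components (the penalty weight is exposed as
  `mono_weight`, default 1). The penalty discourages but cannot forbid
  crossings, so inference additionally sorts each predicted vector before
  building a CDF (`repair_monotonic()`); sorting preserves the value
  multiset and is a no-op on valid outputs.

Whether the per-atom quantile losses are summed or averaged over the 99
grid entries only rescales the learning rate; the sum is used. Batch
aggregation is the arithmetic mean over atoms so the loss scale does not
depend on batch size.

## The network

The backbone is a deliberately generic edge-conditioned message-passing
network -- the contribution this package reproduces is the quantile head,
the loss and the scoring layer, not a specific architecture. Heavy atoms
are nodes (hydrogens enter as per-atom counts); node features are the
element one-hot plus scaled H count, degree, total bond order and
ring/aromatic flags, all derived from the 2D graph. Edges connect every
atom pair within 5 angstrom, in both directions, with the interatomic
distance expanded in 32 Gaussian radial basis functions concatenated with
a bond-order one-hot. Because geometry enters only through distances,
predictions are exactly invariant to rotating or translating a conformer,
and the architecture is permutation-equivariant by construction; both
properties are tested numerically. Three message-passing steps (gated by
a linear map of the edge features) with residual tanh updates give each
carbon a three-bond horizon, which covers the neighbour effects the
synthetic ground truth contains; a two-layer readout maps each carbon to
its 99 quantiles. Targets are standardised internally (mean/sd of the
training shifts) and the output bias is initialised at the marginal
quantiles of the training shifts, so the untrained model starts from the
marginal distribution rather than from zero.

Ensembles of conformers are combined by (optionally weighted) arithmetic
averaging of the quantile vectors -- the quantile-function average, which
preserves ordering. Whether a thermal ensemble should be
Boltzmann-weighted or averaged uniformly is left to the caller:
`boltzmann_weights()` converts energies (kcal/mol) into weights when
wanted, and uniform weights are the default.

## Conformers

The `etkdg` backend delegates embedding to RDKit's ETKDGv3 with a fixed
random seed followed by MMFF94s relaxation, through a bundled Python
helper; coordinates are therefore bit-reproducible for a given seed. The
`passthrough` backend accepts externally supplied ensembles (for example
DFT-optimised geometries with recomputed energies) unchanged. No force
field is implemented in this package.

## The synthetic ground truth

All training and evaluation in the tests runs against a surrogate shift
model with known structure, so calibration can be checked exactly. Each
carbon's true mean shift is a base value for its environment class (sp3,
alkene, aromatic, carbonyl, sp) plus additive increments per
alpha/beta/gamma neighbour by element -- the classic empirical-additivity
form of carbon shift estimation. Base values and increments are fixture
constants chosen to span the real 13C range (roughly 0--220 ppm, methyls
low, carbonyls high); they are not claims about real spectra. Observation
noise is Gaussian and independent across carbons with a class-dependent
sigma of 1.6--2.4 ppm, the order of real prediction/assignment scatter.
The additive-increment term matters for the benchmark design: with a
lookup table keyed only on coarse environment classes, distinct
same-formula isomers would frequently share identical true spectra and
the correct/incorrect separation task would be ill-posed; with
neighbour-count increments, constitutional isomers have distinct spectra
exactly as real isomers do.

Simulated spectra contain one peak per symmetry-equivalence class of
carbons (computed by graph automorphism on the 2D graph with aromatic
bonds merged across kekule forms -- peak counts must not depend on which
kekule structure was drawn, nor on the conformer). Duplicate structures
in a generated corpus receive independent noise draws, as duplicate
entries in a real corpus would. The generator does not attempt solvent or
temperature effects, rotamer-dependent shifts, or realistic NMRShiftDB
error structure; passing tests therefore demonstrate that the
quantile/scoring machinery recovers a known heteroscedastic ground truth,
not that the desk-scale model reaches literature accuracy on real data.

## Desk-scale study design

The test suite and the acceptance script train at a scale one CPU
finishes in minutes, fixed in `desk_train()`: 3200 corpus molecules (one
ETKDG conformer each), a 48-wide net with 3 message steps, Adam at an
initial rate of 2.5e-3 decayed by 4% every 150 optimiser steps, batches
of 48 molecules, at most 350 epochs with early-stopping patience 60, and
a 10% molecule-level validation split. The full-scale defaults
(5e-4, decay every 1e5 steps, 1200 epochs, patience 10) remain the
`train_config()` defaults for full-size corpora. Two further choices
help at this scale: "improvement" for early stopping means any strict
decrease of validation loss, and an exponential moving average of the
weights (decay 0.995) is validated alongside the raw weights each epoch,
with the best-validation-loss checkpoint of either returned -- tail
averaging removes most minibatch noise near convergence and measurably
improves quantile recovery.

A final split-recalibration step corrects a systematic bias of
finite-capacity quantile nets: because the model partially fits the noise
in its training targets, its predicted distributions come out slightly
narrow. After checkpoint selection, each quantile head's output bias is
shifted so that its nominal level matches the empirical level of the
residuals on a calibration set, with the per-level offsets
median-smoothed and isotonically projected so the adjustment can never
introduce quantile crossing. The calibration set must be exchangeable
with future prediction targets: `desk_train()` uses freshly generated
molecules rather than corpus members, because corpus structures recur as
duplicates inside the training set and their residuals are
unrepresentatively small.

## Numerical choices

* **CDF tails.** Below the 1st and above the 99th percentile the CDF
  ramps linearly to exactly 0/1 over a width equal to the adjacent
  inter-quantile gap -- a local-scale extrapolation in place of the
  uncarried 0th/100th percentiles. Clamping at the outer grid levels is
  available (`tails = "clamp"`).
* **Degenerate predictions.** An all-equal quantile vector is treated as
  a point mass: an exact hit scores $P = 0$, anything else $P = 1$.
* **Median.** With the default grid the $\tau = 0.5$ entry is used
  directly; for grids without 0.5 the median is interpolated.
* **Geometric mean** is computed in log space with explicit zero
  propagation.
* **Peak assignment.** When a spectrum arrives unassigned, peaks are
  matched to predicted class medians by minimum-cost bipartite matching
  (Hungarian algorithm) on the absolute deviation; the smaller side is
  fully matched and surplus classes are excluded from scoring (the cited
  assignment procedure in the source literature is not specified in
  detail, so an exactly testable optimal matching is used). On instances
  small enough to enumerate, the matching provably attains the
  permutation minimum.
* **Curation boundary.** The outlier filter removes a record only when a
  single peak deviates from its reference prediction by *more than* the
  threshold (50 ppm default): the failure mode being caught is one
  grossly misassigned peak, and a deviation exactly at the bound is kept.
* **Class-level scoring.** Atoms within one equivalence class contribute
  one score (one peak, one score); the class quantile vector is the mean
  of its member atoms' vectors.

## What the scores look like

For a *correct* pair under a perfectly calibrated model, each $P_i$ is
close to uniform on (0,1), so atomic scores are uniform and the molecular
geometric mean concentrates near $e^{-1} \approx 0.37$ -- correct
molecules do not score near 1, they score *well above incorrect ones*,
whose single bad atoms push the geometric mean towards 0. The recommended
screening threshold of 0.2 on the molecular score discards incorrect
same-formula proposals at high rate while retaining the bulk of correct
ones; the benchmark summary written by `scripts/acceptance.R` reports the
achieved discard rate alongside the AUC.

## Known limitations

The desk-scale model is trained on a synthetic corpus; nothing here
certifies accuracy on experimental shifts. Aromaticity perception is a
deliberate minimal rule (5--7 rings whose atoms all carry a ring double
bond) sufficient for the fixture chemistry, not a full aromaticity model.
Equivalence classes ignore stereochemistry, matching how 13C peak counts
are tabulated; diastereomers are distinguished through their 3D
conformers at prediction time, not through peak counting. Proton spectra,
coupling constants and 2D experiments are out of scope.
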