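---
title: "Surrogate modelling of conformer VCD spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modelling of conformer VCD spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcdml)
```

## The problem

Vibrational circular dichroism (VCD) measures the difference
$\Delta\epsilon(\tilde\nu) = \epsilon_L(\tilde\nu) - \epsilon_R(\tilde\nu)$
in the absorption of left- and right-circularly polarized infrared light by
a chiral molecule. Because the spectrum is exquisitely sensitive to
conformation, the simulated spectrum of a flexible molecule is a Boltzmann
average over all thermally accessible conformers,

$$S_\text{mol}(\tilde\nu) = \sum_i w_i\, S_i(\tilde\nu), \qquad
  w_i = \frac{e^{-\Delta E_i / k_B T}}{\sum_j e^{-\Delta E_j / k_B T}},$$

and each conformer spectrum $S_i$ classically requires its own harmonic
frequency calculation at a quantum-chemistry level — the dominant cost of
absolute-configuration assignment. `vcdml` implements a surrogate
workflow: a feed-forward network learns the map from a torsion-angle
description of a conformer to its broadened spectrum, so that reference
spectra are computed for only a fraction of the ensemble and the remainder
are predicted.

## Spectrum representation

Reference calculations emit a *line spectrum*: discrete modes
$(\tilde\nu_k, I_k)$ with signed intensities. These are broadened with an
area-normalized Lorentzian of full width at half maximum 10 cm$^{-1}$,

$$S(\tilde\nu) = \sum_k I_k\,
  \frac{1}{\pi}\frac{\gamma}{(\tilde\nu - \tilde\nu_k)^2 + \gamma^2},
  \qquad \gamma = \mathrm{FWHM}/2,$$

and sampled on a fixed grid from 800 to 1800 cm$^{-1}$ with one node per
FWHM — a 101-dimensional vector, which is both the learning target and the
prediction. The area normalization makes the integral of each broadened
band recover the mode intensity, so broadening commutes with intensity
scaling and mode addition; both properties are asserted in the tests.
Modes outside the window still contribute through their Lorentzian tails
(no truncation). The amplitude convention was open — only the FWHM is
conventional — and the area-normalized form was chosen because it
preserves integrated rotatory strength and makes the quadrature property
testable.

Spectra are compared with the cosine similarity
$\Theta(a, b) = \langle a, b\rangle / (\lVert a\rVert\,\lVert b\rVert)$,
used both for predicted-versus-reference conformer spectra (written
$S^\mathrm{pred}$) and for hybrid-versus-full composites ($\Theta$). The
similarity of a zero spectrum is undefined and raises an error rather than
being absorbed as 0 or 1. A value of $-1$ means agreement with the
spectrum of the enantiomer.

## Geometry featurization

A conformer is described by hand-picked sidechain torsions (plus optional
extras), not by whole-molecule Cartesian descriptors:

* **Dihedrals** follow the IUPAC sign convention and are encoded as
  $(\sin\theta, \cos\theta)$ pairs by default. A raw-degree input forces
  the network to learn the $\pm 180^\circ$ wrap-around; the sin/cos
  encoding removes that discontinuity. `raw_degrees` is retained as an
  option for fidelity experiments.
* **Bisectors** handle label-symmetric groups such as NH$_2$: the two
  dihedrals to the symmetric hydrogens are combined by their circular mean
  (summed unit vectors), which is exactly invariant under exchange of the
  hydrogen labels. An arithmetic mean of signed degrees is *not*: near the
  branch cut it depends on which hydrogen got which label, defeating the
  encoding's purpose. The circular mean is undefined (and errors) only
  when the two dihedrals are exactly antipodal.
* **Hydrogen-bond features** are donor-H...acceptor distances. No angular
  term is included: distance is the minimal geometry-complete choice, and
  the feature family is config-extensible. Distances are min-max scaled
  with training-split statistics only, so no information leaks from
  validation or test conformers; angles enter unscaled since sin/cos are
  already bounded.

Torsion lists are supplied per molecule in a YAML/JSON config with 0-based
atom indices; automatic rotatable-bond perception is deliberately out of
scope. The enantiomer of a conformer is obtained by reflection
($z \to -z$), under which every dihedral changes sign; in feature space
this negates sine slots and preserves cosines and distances.

## The surrogate

The model is a fully connected network: sin/cos features in, 101 spectrum
channels out of a linear head, trained with mean squared error. The
architecture and training configuration live in a `trial_config` drawn
from the search space of `hyperparameter_space()`: 1-8 hidden layers of
50-500 units, dropout 0-0.2, {tanh, elu, relu, selu} activations, {adam,
nadam, rmsprop, nesterov momentum} optimizers (the last read as SGD with
Nesterov momentum 0.9), log-uniform learning rate in $[10^{-5}, 10^{-2}]$,
optional batch normalization, and L1 or L2 penalties with log-uniform
strength in $[10^{-9}, 10^{-4}]$. Early stopping monitors validation MSE
with a fixed patience of 5 epochs and restores the best-validation
weights.

Choices the source material leaves open, fixed here as defaults:

* **Epoch ceiling 500 and batch size 32**, both configurable via
  `fnn_control()`; the patience rule almost always halts training first.
* **Output standardization**: each of the 101 channels is z-scored with
  training-split statistics and de-standardized at prediction. Without it
  the loss over-weights strong bands; the unnormalized variant remains
  available (`standardize_y = FALSE`) and is exercised in the tests.
* **Splitting** is round-then-remainder: `round(n f_train)` and
  `round(n f_val)` records, the rest to test, reproducing 80/10/10 on 100
  records exactly. When a degenerate-pair map is supplied, both members of
  a pair are forced into the same partition — otherwise each test pair
  would have a twin of itself in training, a silent leak.
* **Seeding**: one master seed derives independent streams for splitting,
  weight initialization and trial sampling, so enlarging one budget does
  not shuffle the others.

Hyperparameters are optimized by a tree-structured Parzen estimator:
after 10 uniform start-up trials, trials are split at the best-25% loss
quantile, per-dimension "good" and "bad" densities are estimated
(categorical frequencies with a unit prior; Gaussian kernels in log space
for the two continuous dimensions), 24 candidates are drawn from the good
densities and the best likelihood ratio $l(x)/g(x)$ is evaluated next.
Because the trial-seed stream is fixed, a 20-trial run shares its first
trial with a 1-trial run of the same seed, making "more budget never
hurts" an exact property. The network engine and the optimizer are
implemented in base-R matrix code inside the package (no deep-learning
framework is used); the backward pass, including batch normalization and
penalties, is verified against finite differences in the test suite.

## Symmetry augmentation

Two augmentations teach the model symmetries that the featurization alone
does not encode:

* **Degenerate pairs**: internally symmetric molecules have geometrically
  distinct conformers that share one spectrum while presenting different
  feature vectors. Both members are included explicitly, the duplicate
  carrying the partner's features and the identical spectrum.
* **Enantiomers**: for every record a mirrored record is appended
  (mirrored features, negated spectrum), doubling the dataset. A model
  trained on one enantiomer alone does not discover the mirror rule — the
  package reproduces this transfer failure — while joint training yields
  mirror-consistent predictions.

## Hybrid composition and cost accounting

`hybrid_composite()` keeps reference spectra for
$\lceil f \cdot N \rceil$ conformers and predicts the rest. The default
selection rule is `lowest_energy`: reference spectra are spent on the
conformers that carry the most Boltzmann weight, which maximizes composite
fidelity per reference calculation; `random` selection is available for
sensitivity studies since the original workflow's rule is not documented.
Weights use $k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$ at a default
298.15 K, and whatever energy the record carries — electronic versus free
energy is the caller's modelling decision, kept outside this module.

`cost_report()` is pure arithmetic on user-supplied per-spectrum costs
(classical $= N c$; aided $= N_\mathrm{ref}\, c + c_\mathrm{ML}$); nothing
is timed at run time.

## The synthetic benchmark

Real reference data require quantum-chemistry calculations, so the test
bench is synthetic with a known oracle. The ground-truth map assigns each
of 40 modes a fixed frequency in 850-1750 cm$^{-1}$ and an intensity that
is an *odd* trigonometric polynomial of the torsions: $\sin k\theta_i$
terms with $k \in \{1, 2\}$ (torsional expansions are dominated by their
low harmonics, and the oddness makes the enantiomer rule
$\mathrm{map}(-\vec\theta) = -\mathrm{map}(\vec\theta)$ exact by
construction) plus pairwise $\sin\theta_i\cos\theta_j$ mode-coupling
products at `coupling_order = 2`. Frequencies carry a bounded, *even*
torsion-dependent shift below one FWHM, emulating the mild frequency
modulation conformational change induces without breaking the mirror
property. Energies come from one random cosine well per torsion (depths
0.5-2.5 kcal/mol), shifted to a zero minimum and truncated at the
40 kcal/mol conformer-search cut-off. Everything is reproducible from one
seed, and the noiseless map itself travels with the ensemble as the test
oracle.

Two sampling modes matter scientifically:

* `uniform` draws torsions uniformly — maximal diversity, used for the
  prediction-quality and hybrid-composition benchmarks.
* `wells` draws torsions near randomly placed, generically
  chirality-asymmetric energy minima. This is the mode used for the
  enantiomer-transfer experiments, and the distinction is essential: under
  uniform sampling the mirrored ensemble occupies the same region of
  torsion space as the original, so any model that generalizes at all
  transfers across enantiomers and no gap can appear. Real chiral
  molecules sit in chirality-specific wells; only wells sampling
  reproduces the situation in which single-enantiomer training fails on
  mirrored conformers while joint training succeeds.

With degenerate pairs enabled, base conformers are canonicalized into the
$\theta_1 \le \theta_d$ half-space and partners are their order-reversed
images carrying the identical spectrum. The canonicalization is what makes
the paired dataset a *well-defined function*: sampling bases over the full
torus would assign two different spectra to overlapping feature regions
(the raw map is not reversal-symmetric), an unlearnable contradiction. In
a real molecule the degeneracy is a property of the true map itself.

What the synthetic bench does *not* emulate: anharmonicity, solvent
effects, force-field error, the coupling of torsions to bond lengths and
angles, and any physically meaningful intensity scale. Passing tests show
the workflow recovers a smooth chirality-aware torsion-to-spectrum map at
realistic sample sizes — the structural claim of the method — not that any
particular molecule's chemistry is captured.

## Problem sizes and numerical choices

The benchmark experiments use desk-scale ensembles chosen to match the
regime the workflow targets: 400 conformers (8 torsions, pairwise
coupling) for the hybrid-composition benchmark, trained on its 15%
lowest-energy subset with a pinned 3x200 relu/adam configuration; 1000
conformers for conformer-level prediction quality (the conformer counts of
flexible drug-like molecules run to the hundreds or low thousands); and
800 well-sampled conformers for the enantiomer experiments. Measured on
these fixtures: held-out median $S^\mathrm{pred}$ clears 0.95 with no
negative records, the 15%-reference hybrid composite agrees with the
all-reference composite at $\Theta \approx 0.99$, single-enantiomer models
collapse on mirrored conformers (similarity gap $\approx 1$) while joint
training removes the gap and makes mirrored predictions mirror-consistent
above 0.99 — each of these is recomputed, not quoted, by the test suite
and the acceptance script.

Numerical details worth knowing: grids require exact divisibility of the
span by the step (tolerance $10^{-9}$) and include both endpoints; batch
normalization uses biased batch variance with $\epsilon = 10^{-5}$ and
running-statistic momentum 0.99; dropout is inverted (inference needs no
rescaling); weight penalties apply to weight matrices only, never biases
or batch-norm parameters; ties in energy-ranked selection resolve by
record order; and model persistence keeps parameters in R's native
serialization so reloaded models predict bit-identically.

## Known limitations

The surrogate is molecule-specific by design: transfer across
stereoisomers fails (reproduced here as a feature of the method, with
joint training as the remedy), and nothing in the package attempts
transfer across molecules. Hyperparameter search re-runs fresh per
application to avoid leakage, so its cost recurs. The CLI covers the
synthetic pipeline end to end; for real data the entry points are the
package functions, with reference line spectra supplied as CSV and
geometries as multi-structure XYZ.
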