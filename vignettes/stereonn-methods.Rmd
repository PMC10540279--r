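---
title: "Modelling enantioselectivity from transition-state descriptors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling enantioselectivity from transition-state descriptors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereonn)
```

## The problem

In a Pd-catalysed asymmetric Negishi cross-coupling the enantiomeric
ratio (er) is set, under Curtin–Hammett control, by the free-energy
difference between the two diastereomeric transition states:

$$\Delta\Delta G^\ddagger = RT\,\ln\frac{[\text{major}]}{[\text{minor}]},
\qquad R = 1.98720425\times10^{-3}\ \mathrm{kcal\,mol^{-1}\,K^{-1}}.$$

At 298.15 K a 90:10 er corresponds to only about 1.3 kcal/mol.
Errors of ~1 kcal/mol are routine for computed barriers, and because
the er responds exponentially to the energy gap, direct conversion of
computed $\Delta\Delta G^\ddagger$ into er is fragile: the delta-method
helper `noiseSdFromDdg()` shows that a 1 kcal/mol error around an
80:20 composition corresponds to roughly 27 S-percentage points.
`stereonn` implements the alternative strategy: *describe* the two
transition-state geometries with a small set of physically meaningful
descriptors and learn the mapping from descriptors to selectivity with
a small feed-forward network, validated in ways appropriate for a
17-point data set.

## Geometric descriptors

The descriptors summarise the three-coordinate Pd environment of the
coupling transition state.  All are invariant under rigid motions of
the coordinates and are computed from an explicit `DonorSet` (the
phosphine P and the two substrate carbons bound to Pd) — the complexes
are too specialised for generic bond perception, so donor atoms are an
input, not an inference.

* **Planarity** (Å): the unsigned perpendicular distance of Pd from
  the least-squares plane of its three donors.  Unsigned because no
  physically preferred sign convention exists for "above" the plane.
* **Y-ness** (degrees): the three donor–Pd–donor angles are measured
  after projecting Pd and donors onto the donor plane, and the L1
  deviation $\sum_i |\theta_i - 120^\circ|$ is reported.  The L1 form
  keeps the value interpretable in degrees; it is zero exactly for an
  ideal trigonal (Y-shaped) complex and invariant under donor
  relabeling.
* **Projected-metal angle** (degrees): the angle at Pd between the
  Pd→P bond and the direction from the foot of Pd's perpendicular on
  the donor plane up to Pd.  With Pd displaced out of plane and P in
  the plane this angle always exceeds 90°, growing as the complex
  pyramidalises; it is undefined (an error, not a silent value) when
  Pd lies in the plane to within the degeneracy tolerance.  The
  complementary convention (measuring to the foot itself rather than
  the out-of-plane direction) is simply 180° minus this value, so
  correlations with selectivity are unaffected by the choice.
* **Bond lengths and angles**: requested as `"bond:i,j"` and
  `"angle:i,j,k"` descriptor strings.

Numerical choices: coordinates in Å, angles in degrees; collinearity
and coplanarity are detected against a tolerance of 1e-6 Å.  Plane
fitting is total least squares via SVD, and tests verify it against an
eigen-decomposition oracle.

## Selectivity encodings

`Selectivity` records hold S and R percentages that sum to 100 and are
strictly inside (0, 100), so all five encodings — ee, er ratio,
ln(er), S%, R% — remain finite and interconvert losslessly
(`toMetric()` / `fromMetric()`).  Strings such as `"11:89"` are parsed
as R:S by default, matching the convention in which S-selective
ligands print minor:major; a `format` argument flips it.  The
temperature for the Boltzmann relation defaults to 298.15 K and is an
argument everywhere it enters.  Exact 100:0 inputs are rejected rather
than clamped: an infinite ln(er) is a modelling error the user should
see.

## The network and its training protocol

The reference architecture is deliberately small: two hidden layers of
15 nodes, a selectable hidden activation (ReLU by default; leaky ReLU,
softplus, sigmoid, tanh and linear are available), and an affine
output.  Only the input features are min–max scaled to [0, 1]; the
target metric is modelled on its natural scale.  Training is
full-batch Adam (learning rate 1e-3) on mean-squared error for up to
5000 epochs, stopping early when the relative loss change falls below
1e-10.  Weights are He-initialised from a seed; biases start at zero.
These protocol details are choices of this package — robust defaults
for n ≈ 17 — and are all exposed in `nnConfig()`.  The C++ inner loop
exists purely for speed; gradients are verified against central finite
differences for every activation.

Leave-one-out cross-validation (`looCrossValidate()`) refits the
normalization *and* the network on each fold of n−1 ligands, with the
fold seed derived as `seed + fold`, and predicts the single held-out
ligand; nothing about a ligand (not even its feature range) leaks into
its own prediction.  A `--normalize-global` style alternative
(normalising once on all rows) can be emulated by scaling the table
before modelling, but fold-wise fitting is the defensible default.
Reported diagnostics are RMSE, squared Pearson correlation of
predicted versus observed, and the slope of the least-squares fit of
predicted on observed (1 for a faithful model); the
coefficient-of-determination form of R² is logged alongside in the
`rsqAlt` slot.

## Feature engineering

`assembleFeatures()` strictly joins the geometric, electronic and
dispersion blocks on ligand id and fails loudly, naming any ligand
missing from a source.  Three reduction routes mirror common practice:

* **Manual** (`correlationRank()` + `selectManual()`): Pearson
  correlation of each feature with the chosen selectivity metric,
  ranked by |R| with name-based tie-breaking.  Pearson rather than
  Spearman because the inspection it emulates is of linear
  correlation panels.  Zero-variance features get R = 0 with a flag.
* **PCA** (`pcaReduce()`): centred PCA on the normalized table;
  component signs are fixed by making the largest-|loading| entry
  positive, so results are platform-independent.
* **Sammon mapping** (`sammonMap()`): minimises the distance-weighted
  stress by gradient descent with step halving (initial rate 0.3, at
  most 500 iterations, convergence at relative stress change below
  1e-9) from a deterministic PCA initialisation; accepted iterations
  never increase the stress.  Duplicate rows are perturbed by a seeded
  jitter of 1e-9 times the mean pairwise distance.  The embedding
  coordinates become the model inputs.  Because Sammon mapping has no
  out-of-sample extension, the pipeline projects validation ligands
  with the PCA rotation fitted on the training rows — a documented
  approximation, and one reason the manual route is the default.

Inside cross-validation, min–max parameters are always fitted on the
training fold only; held-out values may fall outside [0, 1] and are
deliberately not clipped.

## The validation battery

With 17 training points, apparent skill must be stress-tested:

* `yShuffleTest()` permutes labels (preserving their multiset) and
  reruns the full LOO; a model that learned real structure shows far
  larger shuffled RMSEs.  An explicit identity permutation reproduces
  the reference run exactly, which the tests use as a control.
* `xyRandomizationTest()` replaces features (uniform on [0, 1])
  and/or labels (uniform on the label range) and expects no
  correlation — the mean held-out R² over replicates rounds to zero.
  The default of 20 replicates balances the width of the null
  distribution against runtime.
* `metricBakeoff()` trains one model per encoding and compares all
  five on a common validation table *after converting every prediction
  to the S% scale*, which is what makes RMSEs comparable across
  encodings.  Out-of-domain predictions (a negative er ratio, an ee
  above 100) are clamped to the nearest valid value and counted,
  never fatal; ties break toward `s_select`, then lexicographically.
* `ddgBaseline()` is the conventional comparator: er straight from
  computed $\Delta\Delta G^\ddagger$.  Negative values are read as
  favouring the opposite enantiomer.  Adding Gaussian noise to exact
  energies degrades its S% RMSE monotonically — the quantitative form
  of the fragility argument above.

## The synthetic data generator

`plantedSystem()` / `simulateFeatureTable()` emulate the data regime
the method targets, not its chemistry: 17 training ligands, two
further validation sets of 10 and 3, 15 features uniform on [0, 1], a
latent S% built from three informative features through a hinge
nonlinearity, and Gaussian label noise on the S% scale.  Defaults and
the reasoning behind them:

* **Baseline 70 S%.**  The emulated ligand family is predominantly
  S-selective.  This also keeps the ee and er-ratio encodings
  invertible toward S: with a symmetric (50-centred) latent, half the
  ligands are R-major and converting an ee or er-ratio prediction back
  to S% with a fixed major label is ill-posed.  A symmetric regime
  remains available via `baseline = 50`.
* **Coefficients `c(60, -45, 40)`** on hinge terms
  $\max(f_i - 0.5, 0)$, giving a latent signal spread of roughly a
  dozen S-points — comparable to the spread of real er data — with
  mixed signs so no single direction dominates.
* **Label noise 4 S-points** by default, a regime in which signal
  clearly exceeds noise (SNR ≈ 3–4).  `noiseSdFromDdg()` converts a
  free-energy error into this unit if a thermodynamically anchored
  noise level is wanted; note that a full ~1 kcal/mol error would
  correspond to tens of S-points and no method could recover the
  signal at n = 17.
* The latent is clipped to [1, 99] so every encoding stays finite;
  the three informative columns carry domain-flavoured names (electron
  population at C2, Pd planarity, a ring bond angle) purely as a
  naming convention.

`simulateToyComplexes()` builds trigonal Pd complexes analytically, so
planarity equals the requested offset and Y-ness equals
$\sum|\theta_i - 120|$ *by construction*; seeded rigid motions and
optional jitter then exercise the descriptor code against known truth.

What the generator does **not** emulate: correlated features (real
descriptors co-vary strongly), heteroscedastic experimental error,
selection effects in which ligands get synthesised, and any actual
electronic structure.  Passing tests therefore demonstrate the
machinery — descriptors, training, validation logic — under a
controlled regime, not predictive accuracy on real chemistry.

## Known limitations

* At n = 17 with 15 inputs, the held-out performance of a freshly
  initialised network is strongly seed- and draw-dependent; an
  independent implementation of the same protocol (scikit-learn's
  MLPRegressor) shows the same variability, so this is a property of
  the regime, not of the code.  The validation battery is the honest
  lens: the planted-signal tables beat their label-shuffled
  counterparts decisively, but single-run R² values should not be
  over-read.  In particular, near-perfect held-out R² on planted
  nonlinear signals is not attainable under this training protocol at
  this sample size.
* Sammon embeddings have no exact out-of-sample rule (see above).
* The ee encoding folds at 50:50; converting ee predictions to er
  strings requires an externally supplied major-enantiomer label.
* The five-encoding bake-off winner is itself noisy; over repeated
  synthetic draws the S%-linear encodings win most often, which is the
  level of claim the tests assert (a tendency, not a certainty).

## Problem sizes used by the test suite

The suite exercises the full reference regime (17×15 tables, 2×15-node
networks, 20-replicate randomization and bake-off batteries) where the
scientific claim depends on it, and smaller tables (8–10 ligands, 3–4
features, a few hundred epochs) for contract and invariance checks
where it does not — the package's choice of proportionate test cost.
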