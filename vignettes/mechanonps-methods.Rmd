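---
title: "Mechano-NPS phenotyping, MechanoAge and Mechano-RISQ: models and methods"
author: "mechanonps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-NPS phenotyping, MechanoAge and Mechano-RISQ: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanonps)
```

## The measurement and its physical model

Mechano-node-pore sensing (mechano-NPS) drives single cells through a
microfluidic channel segmented by wide nodes into sensing pores, with one
deliberately narrow "contraction channel" in the middle. A four-terminal
current measurement across the channel reports each transit as a pulse of
sub-pulses: a cell partially blocks whichever segment it occupies, and the
relative current drop scales with the blocked volume fraction. Three regions
carry the information:

* **pre-contraction node-pores** — the drop $\Delta I_{np}/I$ encodes the
  free cell diameter $D_{cell}$;
* **the contraction channel** (width $w_c = 10.5\,\mu m$, length
  $L_c = 3000\,\mu m$, height $h = 22.3\,\mu m$) — the cell is squeezed to
  an average strain $\varepsilon = (D_{cell} - w_c)/D_{cell} \approx 0.4$
  and its transit time $\Delta T_{cont}$ reports stiffness;
* **post-contraction segments** — the time $\Delta T_r$ for the sub-pulse
  magnitude to return to $\Delta I_{np}$ reports recovery from deformation,
  recorded as "Inf" beyond the 120 ms observation window.

The size model is the resistive-pulse relation
$$\frac{\Delta I}{I} \;=\; \frac{D_{cell}^3}{D_e^2\,L}\,
  \left[\,1 - 0.8\,(D_{cell}/D_e)^3\,\right]^{-1},$$
with effective channel diameter $D_e$ (calibrated from polystyrene
microspheres of known size, `calibrate_De()`) and effective sensing length
$L$ (defaulting to the 700 um pore length; the appropriate value is
device-specific and configurable). `diameter_from_blockade()` inverts the
relation by bisection on $(0,\, D_e\,(1/0.8)^{1/3})$, where the correction
factor has its pole; the function is strictly increasing there, so the root
is unique and the forward/inverse round trip is exact to well below
$10^{-4}\,\mu m$.

In the contraction channel the cell is modelled as an oblate spheroid of
volume $V_{deform} = \pi w_c L_{deform}^2/6$. We take
$\Delta I_c / I = V_{deform}/V_{contraction}$ with proportionality constant
1 and $V_{contraction} = L_c w_c h$ (only proportionality is physically
fixed; the constant is a documented convention), giving
$L_{deform} = \sqrt{6 (\Delta I_c/I) V_{contraction} / (\pi w_c)}$ and the
transverse deformation $\delta_{deform} = L_{deform}/D_{cell}$.

The whole-cell deformability index
$$wCDI = \frac{L_c}{U_{flow}\,h}\cdot\frac{D_{cell}}{\Delta T_{cont}}$$
is dimensionless and inversely related to cortical tension: softer cells
transit faster. $U_{flow}$ is estimated per cell as pore length over the
mean pre-contraction pore sub-pulse duration (`estimate_Uflow()`).

## The synthetic-data generator

No per-cell feature distributions are published for the donor groups, so
the package ships a generator whose defaults are labelled synthetic
stand-ins, not measured values. `simulate_population()` draws free
diameters from a truncated normal (younger and older groups: mean 17.5 um,
chosen so the strain relation at $w_c = 10.5\,\mu m$ gives
$\bar\varepsilon \approx 0.4$; high-risk: 17.0 um, reflecting the reported
~0.5 um smaller trend), wCDI from a truncated normal (younger location 4.0,
older 3.2, high-risk 3.3, scale 0.45 — ordered so older/high-risk cells are
stiffer), and the recovery class from a five-bin mixture in which older and
high-risk groups carry more mass on the 70–120 ms and infinite bins. All
other quantities follow deterministically through the physics above, so
pulse extraction and the physics inversions can be tested against exact
ground truth. Every generator is bit-reproducible under its seed.

Two generator choices deserve explanation:

* **Deformation bulge.** Ground-truth deformation is
  $L_{deform} = \gamma\,\sqrt{D_{cell}^3/w_c}$ with $\gamma = 1.35$
  (3% lognormal jitter). $\gamma = 1$ would be the volume-conserving oblate
  spheroid; under the constant-1 blockade convention and the default
  $D_e = 40\,\mu m$, $\gamma > 1.16$ is what makes the contraction
  sub-pulse deeper than the node-pore sub-pulse for every physical cell
  size, as real pulse traces show. $D_e = 40\,\mu m$ itself is a synthetic
  calibration default selected for the same ordering; on a real device both
  come out of calibration, not convention.
* **Post-contraction sensing train.** The recovery bins
  (0 / 50–60 / 60–70 / 70–120 ms / Inf) imply a temporal resolution finer
  than one 700 um recovery segment can give, and the downstream segment
  layout is not described. The simulator therefore models the recovery
  region as 24 short node-pore units (20 + 55 um, a 5 ms pitch at the
  15 um/ms default flow). Ground-truth recovery times are drawn within
  each bin leaving a 6 ms guard below the bin's upper edge, so the 5 ms
  measurement pitch cannot push a cell across a bin boundary; with that
  guard the measured bin equals the generated bin by construction, which
  is what makes the recovery round-trip test meaningful. While a cell is
  still deformed its post-contraction sub-pulses are deepened by a factor
  1.35 (`deform_excess = 0.35`); this elevation is unreported in the
  source device description, and 0.35 keeps the recovered/deformed depth
  separation at roughly five standard errors of the depth estimator at the
  largest baseline noise the robustness tests cover
  ($\sigma = 10^{-3}$ of baseline), so bin assignments are stable by
  margin rather than by luck.

The CyTOF-like generator (`simulate_cytof()`) produces log-normal
intensities over a 27-marker panel with configurable per-marker log-unit
group shifts; `age_effects()` and `hr_effects()` encode the direction of
the reported differential markers (pRb, CD44, pS6 up and KRT19 down with
age; p38, GSK3, mTOR altered in high risk) with synthetic magnitudes. It
emulates a gated per-cell intensity table only: no spillover, acquisition
drift, debarcoding artefacts or donor random effects, so passing tests
show the analysis layer is correct, not that real CyTOF data would behave
this way.

## Pulse extraction

`detect_subpulses()` estimates the baseline in two passes (median of the
top quartile, then the median of everything within a 5-MAD band of it —
sub-pulses only ever lower the current, so the upper tail is pulse-free
even when pulses dominate the trace), thresholds a lightly smoothed copy of
the trace at baseline $- \max(k\,\mathrm{MAD}, 10^{-6})$ with $k = 5$, and
refines each run's edges to the half-depth crossing of the smoothed signal,
which for a centred (odd-width) moving average recovers the underlying step
position to within one sample. Runs that overlap after refinement are
merged (a deep pulse at poor SNR can fragment into several threshold
crossings). Depths are trimmed means of the raw plateau samples; noiseless
traces therefore round-trip depths to $10^{-9}$ relative and durations to
one sampling interval, which the test suite asserts.

Structurally complete events (pre pores + contraction + post train, the
count implied by the geometry) are segmented positionally; the contraction
sub-pulse must also be deeper than the pre-contraction pores or the event
is flagged. Two cells in the channel stack their blockades, which both
distorts the sub-pulse count and — more robustly — leaves stepped,
non-flat plateaus; events showing either signature are flagged
`"coincident"` and excluded from features rather than deconvolved. Events
with missing segments are flagged, never silently dropped.

Recovery time follows the convention: 0 ms when the first post-contraction
sub-pulse has already returned to $\Delta I_{np}$; otherwise the elapsed
time from contraction exit to the entry of the first recovered sub-pulse;
Inf when none recovers within the 120 ms window. "Recovered" means the
depth is within 2% of $\Delta I_{np}$ (magnitude only — sub-pulse shape
comparison is not implemented, as no shape tolerance is defined anywhere),
with a noise-aware floor of three standard errors of the depth estimate so
the decision degrades gracefully as noise grows; at the default noise
($10^{-4}$ of baseline) the 2% term dominates.

## Feature engineering

The model consumes exactly ten per-cell features: five continuous
($D_{cell}$, wCDI, $\Delta T_{cont}$, $L_{deform}$, $\delta_{deform}$) and
five binary recovery-bin indicators. The published feature list names the
recovery dummies, wCDI, the deformation diameter, the cell diameter and
$\Delta T_{cont}$ but never enumerates all ten; taking $\delta_{deform}$
as the fifth continuous feature is this package's interpretation, and
`build_feature_table(continuous = ...)` keeps it swappable. "Deform
Diameter" maps to $L_{deform}$. Finite recovery times in (0, 50) ms are
not covered by the printed bins and are assigned to the "0 ms" bin with a
logged count; on the simulated device they cannot occur. Labels come from
donor age (older > 50 y, younger < 35 y); donors aged 35–50 are excluded
with a count, matching the two-group training design. A Yeo-Johnson
transform (maximum-likelihood $\lambda$ per continuous column, via
`car::powerTransform`) is fitted on training data only and applied frozen
everywhere else.

## MechanoAge

`train_mechanoage()` implements stacking with three tree-ensemble base
learners: bagged decision trees (50 bootstrap resamples, no tuning),
a random forest tuned over up to 30 `mtry` values, and extremely
randomised trees at default settings (their internal randomisation is the
variance-control mechanism, so no grid). Base learners are evaluated under
repeated stratified k-fold cross-validation (default 10 folds, 5 repeats)
optimising ROC AUC, with the majority class down-sampled *inside* each
training fold only — held-out folds and all validation data are never
resampled, keeping performance estimates unbiased. The meta-learner is a
gradient-boosted classifier (binary logistic objective, learning rate 0.1,
depth 3) trained on the per-row mean out-of-fold base probabilities, its
boosting length chosen from a 10-point grid by 5-fold cross-validated AUC
with down-sampling maintained, then refitted along with the base learners
on the full (down-sampled) training data. Stacking on out-of-fold
probabilities is the standard construction; the reference stacking
implementation does not document its internals, so this is stated here as
the assumed behaviour. The "older" class is called at probability 0.5 by
default (no threshold is published). All randomness derives from one
config seed through named substreams, so identical seeds and data give
identical bundles, and fold assignments are stored in the bundle so the
absence of leakage is auditable.

Variable importance is per-learner Gini impurity decrease rescaled to a
0–100 maximum per learner and averaged into a consensus; the five recovery
dummies are additionally reported as one cumulative group, since recovery
time is a single biological quantity split for coding reasons.

Two learning-curve analyses mirror the study-size justification: cell-level
subsampling (AUC against a fixed held-out set at increasing training sizes,
several draws per size) and donor-level prefix curves over random inclusion
orders with leave-one-sample-out validation. Both retrain full ensembles
many times; tests run them with deliberately small configurations (3-fold,
single-repeat, tens-of-trees ensembles on cohorts of a few hundred cells),
which exercise the logic at a scale chosen to keep the whole suite fast —
the defaults remain the full protocol.

## Mechano-RISQ and inference

For a sample of cells, Mechano-RISQ is the ratio of its
fraction-classified-older to a baseline rate $b$ estimated from
average-risk reference cells never used in training: 1.0 means no
deviation. The published definition fixes $b$ for chronologically younger
samples (misclassification of average-risk young cells); scoring
perturbation experiments on older donors needs the complementary baseline
(predicted-older rate of average-risk old cells), exposed via
`reference_class = "older"` and documented as an extension. $b = 0$ is an
error (RISQ undefined) rather than a silent infinity.

Single samples are tested against the normative average-risk RISQ
distribution with the Crawford–Howell t-test,
$t = (x^* - \bar x)/(s\sqrt{(n+1)/n})$, $df = n-1$, two-sided by default
(sidedness is configurable; none is published), with Benjamini–Hochberg
correction across the samples of one analysis panel. Its simulation-based
power function supports two case conventions: the calibrated one (case
drawn from the shifted population), under which power at $d = 0$ equals
$\alpha$ and tops out near 0.78 at $n = 18$, $d = 3$; and a fixed case at
exactly $d\sigma$, under which the same design clears 0.97. Both are
implemented (`case_noise`), because the two conventions answer different
questions and only the second reproduces the headline power figure.
Group-level comparisons use the two-sided Wilcoxon rank-sum test;
perturbation-versus-control classification counts use Fisher's exact test.

## CyTOF signatures

`dep_analysis()` compares each marker between two groups with a two-sided
Wilcoxon rank-sum test on log-transformed intensities, Bonferroni-corrects
across the panel, and calls a marker significant only when adjusted
$p < 0.05$ *and* $|LFC| > 0.5$. The LFC is a difference of group means of
`log1p` intensities by default; the LFC base/transform is nowhere defined,
so `arcsinh` (cofactor 5) and plain `log` are selectable and the choice is
recorded with the result. Constant markers are reported with $p = 1$, not
dropped. `train_signature()` fits a gradient-boosted binary classifier on
unperturbed control cells of one lineage with a stratified 70/30 split and
5-fold cross-validated boosting length maximising AUC, then freezes the
model as raw bytes; `transfer_evaluate()` scores perturbation conditions
without any parameter update (a checksum makes the frozen-model contract
testable) and `delong_compare()` tests AUC differences, paired when the
two curves share cells.

## Numerical choices and degenerate inputs

* Bisection tolerance for the diameter inversion: $10^{-10}$ (uniroot),
  giving round trips $< 10^{-4}\,\mu m$; the admissible blockade range is
  named in the error when exceeded.
* Constant feature columns: Yeo-Johnson $\lambda$ undefined — identity with
  a warning, never a hard failure.
* Degenerate folds (single class) are errors in `downsample_fold()`;
  donor-level learning-curve prefixes whose training remainder is
  single-class are skipped and logged.
* `wilcox.test` exact p-values for small tie-free samples, normal
  approximation with tie correction otherwise; identical-score DeLong
  comparisons return $p = 1$ conceptually (pROC emits NaN variance for
  exactly identical curves, surfaced as-is).
* Tree counts, folds and grid lengths all live in
  `mechanoage_config()`; the acceptance-grade classifier checks in the
  test suite run at n = 1000 cells with 5-fold / 2-repeat
  cross-validation and 200-tree forests, a size chosen as a sensible
  desk-scale rendering of the full protocol.

## What passing tests do and do not show

The test suite demonstrates that the pipeline is internally consistent:
physics inversions round-trip, extraction reproduces simulator ground
truth, the classifier separates populations built to be separable and
collapses to chance under label permutation, and the inferential pieces
are calibrated against enumeration or simulation oracles. Because every
input is synthetic, nothing here validates the biological claims —
distinguishing real donor age groups, the published AUCs (0.95/0.91), or
per-donor RISQ values all require the original donor dataset, which is
available only on request. The synthetic group separations are stand-ins
with configurable effect sizes, not estimates of the real effect.

## Known limitations

* The simulator is phenomenological at the sub-pulse level: no
  electrokinetics, no hydrodynamics, no cell-channel interaction beyond
  the volume-blockade model, rectangular sub-pulses with Gaussian noise.
* Coincident transits are excluded, not deconvolved.
* Only magnitude (not shape) defines sub-pulse recovery.
* Viscoelastic (frequency-dependent) mechanics are out of scope, as are
  CyTOF preprocessing (normalisation, debarcoding, gating) and any
  biological interpretation of marker shifts.
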