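---
title: "Motion censoring for resting-state fMRI: models, choices and limits"
author: "motionscrub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion censoring for resting-state fMRI: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Head motion corrupts resting-state fMRI at every scale: it shifts the imaged
anatomy between frames, modulates signal intensity through spin history, and
leaves spatially structured artifacts that masquerade as functional
connectivity (FC). In populations that cannot be stabilized — fetuses above
all — motion is both larger and more intermittent than in adults: long
stretches of low displacement punctuated by spikes of several millimetres.
Nuisance regression against the rigid-body realignment parameters removes a
substantial part of the artifact but demonstrably not all of it; the residue
is weak at the level of a single time series or a single connection, but the
*whole-brain FC profile* still carries enough motion information that a
classifier can read the scan's motion level back out of it. Volume censoring
("scrubbing") — deleting frames whose motion metric exceeds a threshold —
targets exactly the frames regression cannot fix.

This package implements the full evaluation loop for that strategy: motion
metrics, a one-step censoring + regression + band-pass cleaner, FC profiles
with autocorrelation-corrected z-scores, association screens at three scales,
connectome-based prediction of motion versus neurobiological targets with
permutation nulls, and voxel-level seed-map contrasts — exercised end to end
on a synthetic generator with known ground truth.

## Motion metrics

**Framewise displacement.** For frame $i$ with translations $d_x, d_y, d_z$
(mm) and rotations $\phi, \theta, \psi$ (rad),
$$FD_i = |\Delta d_{ix}| + |\Delta d_{iy}| + |\Delta d_{iz}|
  + r\,(|\Delta\phi_i| + |\Delta\theta_i| + |\Delta\psi_i|),\qquad FD_0 = 0,$$
where $\Delta$ is the backward difference and $r$ converts rotation to arc
length. The default radius is $r = 35$ mm, a typical late-gestation fetal
head; it is configurable per scan because a fixed adult value (50 mm) would
overweight rotations in small brains. After censoring, `fd_ave`/`fd_max` are
computed from the *original* FD values of retained frames — the literal
reading of "mean over preserved volumes". Whether displacement should instead
be recomputed between newly adjacent frames is genuinely ambiguous;
`summarize_motion(recompute_gaps = TRUE)` provides the other reading.

**Scaled DVARS.** The RMS over gray-matter voxels of the temporal intensity
difference, divided by the grand mean gray-matter intensity so that the
measure is comparable across scans; frame 0 is defined 0. Both FD and sDVARS
are backward differences, so frame 0 is excluded from FD-vs-sDVARS
concordance counts.

**tSNR** is voxelwise temporal mean over temporal SD. The SD is the sample SD
($n-1$); the estimator choice is documented because the oracles in the test
suite must match it exactly. Zero-SD voxels are excluded from the brain-mask
average and counted.

## One-step censoring, regression and band-pass

The cleaner solves a single least-squares problem per ROI on the *retained*
frames only. The design contains:

* an intercept and a linear trend (the band excludes 0 Hz only
  asymptotically on a 7-minute scan);
* a motion regressor set: 6 parameters $R$ (rotations pre-scaled to mm); 12
  adds backward-difference derivatives $R'$; 24 is the Volterra expansion
  $[R, R^2, R_{t-1}, R_{t-1}^2]$; 36 adds $[R_{t-2}, R_{t-2}^2]$. Lagged
  columns are zero-padded, never truncated, to keep design and data
  row-aligned under censoring;
* the first three principal components of white-matter/ventricle signals,
  centered and unit-scaled;
* sine/cosine pairs at every DFT frequency of the original frame grid
  *outside* the pass band (default 0.01–0.1 Hz), which implements band-pass
  filtering by regression.

Because the spectral columns are built on the original grid and the fit sees
only retained rows, a censored frame cannot influence any residual: filtering
with interpolation-free censoring and no leakage. This is verified by an
oracle test: injecting arbitrary artifacts confined to censored frames leaves
retained-frame residuals unchanged to $10^{-10}$.

Two numerical notes. First, with intercept + out-of-band sin/cos only, the
one-step fit *is* the FFT band-pass projector (the basis is orthogonal), and
the tests assert exact agreement. With the trend and motion columns added,
the joint fit and the classical "regress, then FFT-filter" sequence differ by
coefficient-estimation noise of order $n^{-1/2}$ — about 10% relative
residual power at 144 frames. The two pipelines are *not* interchangeable at
short scan lengths; this package commits to the joint fit. Second, degrees of
freedom are `retained frames − design rank`; scans where this is not positive
are excluded with a distinguishable error, and a scan-level floor of 40
retained frames (two minutes at TR = 3 s) gates the group analyses.

Censoring is strict (`metric > T` removes the frame); a frame exactly at the
threshold is retained. `extend_before` optionally removes the predecessor of
each flagged frame, since a displacement is a property of a transition
between two frames.

## FC profiles and the autocorrelation correction

FC is Pearson correlation over retained frames, reported as
$z = \mathrm{atanh}(r)\sqrt{n_\mathrm{eff} - 3}$. BOLD series are serially
correlated and censored scans have unequal lengths, so using the raw frame
count makes z-scores incomparable across scans and grossly anticonservative
(type-I error ~0.36 at $\alpha = 0.05$ for AR(1) with coefficient 0.8 at 144
frames). The package estimates a per-pair effective sample size by inflating
the variance with a Bartlett-tapered sum of the two series' sample
autocorrelations up to lag $\lfloor 3\sqrt{n}\rfloor$:
$$n_\mathrm{eff} = \frac{n}{1 + 2\sum_{k=1}^{M} w_k\,
  \hat\rho_x(k)\hat\rho_y(k)}, \qquad w_k = 1 - \frac{k}{M+1},$$
clamped to $[4, n]$. This is the classical variance-inflation correction in
the spirit of the xDF family; equivalence with any specific published
estimator is not claimed, and a `correction = "naive"` switch exposes the
uncorrected behavior. Calibration is part of the acceptance suite: type-I
error within $[0.03, 0.07]$ on AR(1) nulls where the naive z exceeds 0.07.

Profiles vectorize the upper triangle in row-major order — the documented,
stable edge order that makes profiles comparable across scans, runs and the
ground-truth edge sets. $|r| = 1$ is capped at $1 - 10^{-7}$ before
`atanh` so degenerate fixtures stay finite.

### Association screens and their null calibration

The FD–BOLD screen correlates the FD trace with each ROI's cleaned series.
A subtlety: residuals live in the nuisance-orthogonal subspace of dimension
$\nu = n - \mathrm{rank}(X)$, so the ordinary Pearson test (df $n-2$) is
mis-calibrated. The package projects FD onto the same subspace and uses
$t$ with $\nu - 1$ df, which restores nominal behavior (fraction of null
tests with $p < 0.05$ close to 0.05 — slightly above because in-band BOLD
autocorrelation survives cleaning; the measured value on artifact-free
synthetic data is ~0.06). The fixed-length control (first 40 retained
frames) cannot re-project (the design rank exceeds 40), so it reports
ordinary correlations — it is a data-length control, not a calibrated test.
The FD–FC screen correlates each edge across scans with `fd_ave`/`fd_max`;
multiple-testing summaries pool all scan×ROI (or edge) tests into one
BH-FDR family at $q = 0.05$, the stricter reading of an unspecified family.
All p-values are two-sided.

## Connectome-based prediction

The prediction instrument asks: does the FC profile predict a non-neural
variable (mean/max FD) better than chance? An effective cleaning strategy
should make motion unpredictable while *improving* prediction of
neurobiological targets (gestational age, sex). Per repeat (default 50):
a random 80/20 split (stratified on sex for classification); univariate
feature selection at $p_\mathrm{unc} < 0.05$ on the training scans only
(Pearson for continuous targets, pooled-variance t for sex); features
standardized with training statistics; a linear SVR ($\epsilon = 0.1\,
\mathrm{SD}(y_\mathrm{train})$, $C = 1$) or linear SVC ($C = 1$) fit by
deterministic dual coordinate descent. Held-out performance is Fisher-z of
predicted-vs-actual correlation (continuous) or percent correct (sex). The
permutation null shuffles targets once per permutation set (default 50 sets)
and reruns the identical procedure with a reduced repeat budget (default 1);
significance is a one-tailed two-sample t of original repeats against null
performances. "Repeated random holdout" is implemented as the primary scheme
(with a true k-fold option) because the described procedure reassigns scans
randomly on every repetition. No SVM library being available in the target
environment, the solver is built in; MATLAB-default equivalence is neither
claimed nor needed — the instrument compares conditions under one fixed
model. A regression test guards the leakage contract: selecting features on
all scans before CV detectably inflates null sex accuracy, fold-internal
selection does not.

## Voxel-level contrasts

Seed maps are Fisher-z'd voxelwise correlations with the mean seed time
course on cleaned volumes. Group inference is a one-sample t (within-group)
or two-sample t (high- vs low-motion subgroups, each the extreme 10% by
post-censoring `fd_ave`, ties broken by scan id). Pooled-variance Student's
t is the default (Welch switchable). Cluster-extent thresholding binarizes
at $p_\mathrm{unc} < 0.01$ and keeps components of at least 40 voxels under
6-face connectivity (18/26 configurable; the choice is recorded in every
result). The percentage of significant voxels uses the brain mask as
denominator.

## The synthetic world

The generator is the package's test bed; its defaults are a *stated world*,
fixed once:

* **Motion**: per-axis AR(1) baseline (coefficient 0.9, stationary SD
  0.33 mm) plus Poisson spike events (rate 14 per scan, gamma-dispersed
  across scans with shape 2, exponential amplitudes of mean 1.2 mm, random
  sign, random split over the six axes) injected as one-frame positional
  pulses, so FD spikes at the event frame and its successor. This yields
  uncensored `fd_ave` ≈ 0.9 mm with a heavy-tailed `fd_max` — the regime the
  fetal literature reports — and frequent spikes above 1.5 mm, the "spike
  scale" used as the censoring threshold in the recovery tests.
* **BOLD**: a latent correlation matrix from a low-rank spatial factor model
  (Gaussian-process loadings over centroids drawn in a 45 mm ball, length
  scale 40 mm), so true FC decays with distance; AR(1)-in-time innovations
  (coefficient 0.4); two smooth tissue components with random loadings; white
  noise (SD 0.5 against unit signal).
* **Artifact**: additive and linear in FD — the simplest mechanism that
  reproduces the three observed signatures — with two deliberate
  elaborations. (1) Per-frame lognormal amplitude jitter (sdlog 0.75):
  without it the artifact of a positional pulse lies *exactly in the linear
  span of the motion regressors* and nuisance regression removes it
  completely, which no empirical study observes; real artifacts (spin
  history, intra-volume corruption) are not deterministic functions of the
  realignment parameters. (2) A ROI loading mixing a global and a focal
  term, $w = 0.27 + 0.73\,e^{-d/22\,\mathrm{mm}}$ with a per-event random
  focus: the global part dilutes genuine correlations in high-motion scans
  (masking weak covariate effects until censoring removes the spikes), the
  focal part induces the distance-dependent FC bias. Gain 2.2 per mm FD:
  spike frames corrupt the signal grossly, baseline frames mildly.
* **Covariates**: gestational age uniform over 19–40 weeks modulates its
  designated edges multiplicatively (0.25 per SD); sex shifts a disjoint
  edge set by +0.07 correlation for one class; each set is 5% of edges.
  Disjointness makes recovery separable by construction.
* **Volumes**: a 16×16×8 grid, four gray-matter blocks (two sharing a
  network signal), white-matter and ventricle regions, baseline intensity
  100, FD-locked global+focal intensity corruption (0.7 per mm, jittered),
  voxel noise.

All randomness flows from one master seed through pure per-scan/per-stage
sub-seeds, so any single scan is reproducible in isolation and identical
seeds give byte-identical output files.

**Calibration protocol and what a green test establishes.** Free parameters
were calibrated in a pilot (before the acceptance assertions were run) to
place the world in the regime the empirical literature describes: uncensored
FC profiles predict mean FD above the permutation null while
censored-at-spike-scale profiles do not; sex classification improves with
censoring; the censored-minus-uncensored FC difference rises with edge
distance; and the high-vs-low-motion voxel contrast shrinks with censoring.
A green acceptance run therefore establishes that the *pipeline recovers
known truth in a world built to contain it* — internal validity. It does not
establish that real fetal artifacts follow this contamination law, and the
generator deliberately omits spin-history dynamics, susceptibility and
k-space physics, fetal-specific geometry, and between-scan length variation.
Two known divergences from real cohorts: between-scan `fd_ave` spread is
narrower than reported distributions (the baseline amplitude is homogeneous
by design, so that censoring genuinely removes the predictable motion
signal), and prediction accuracies are cleaner than clinical values.

## Degenerate inputs, ties, tolerances

Zero-variance ROIs abort FC with the offending ROI named; constant design
columns other than the intercept are dropped and logged; all-censored scans
raise a distinguishable condition that drives scan exclusion; subgroup ties
are broken by scan id; Bonferroni caps at 1; $|r|$ caps at $1-10^{-7}$;
cluster labeling is scan-order invariant. Desk-scale reductions used by the
test suite and acceptance script (documented where applied): 10 CV repeats /
20 permutation sets instead of 50/50, and `min_cluster = 10` on the 16×16×8
grid where the conventional 40-voxel extent would exceed most true clusters.

## Configuration and environment limits

Config files are JSON or flat `key = value` text; there is no YAML reader in
the supported environment. NIfTI support is a minimal built-in NIfTI-1
single-file reader/writer (uncompressed, sform, common datatypes) because no
NIfTI-capable R package is available in the supported environment; it is not
a general-purpose implementation.
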