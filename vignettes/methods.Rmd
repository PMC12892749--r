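---
title: "Methods: source imaging, directed networks and the bistable seizure index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source imaging, directed networks and the bistable seizure index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eznetsi)
```

# Overview

`eznetsi` localizes candidate epileptogenic zones (EZ) from the scalp EEG
recorded in the minutes before seizure onset. The premise is that the EZ
behaves, already preictally, as a *driver* in the cortical network: it
shows elevated slow (delta, 1--4 Hz) activity and exerts directed influence
on other regions. The pipeline turns a 21-channel 10--20 recording into
per-region scores along two complementary routes:

1. **structural/driving**: sLORETA source reconstruction, region-level
   MVAR models, directed transfer function (DTF) networks, and degree
   centralities (total DC, in-degree DCin, out-degree DCout) integrated
   over a sparsity-threshold sweep;
2. **dynamical**: a *seizure index* (SI), the inverse of the mean escape
   time of a noise-driven bistable node model coupled through the same
   directed network.

High-scoring regions (normalized score $\ge 0.95$) form the predicted EZ
set, which is evaluated against the resected-region/Engel-outcome
reference standard with standard diagnostic statistics.

# Signal conditioning

Recordings are band-pass filtered 0.5--80 Hz and notch filtered 48--52 Hz
(50 Hz mains), both as 4th-order Butterworth filters applied
forward-backward. Zero-phase filtering matters here: preictal timing
relationships feed the lagged MVAR models downstream, and a causal filter
would add frequency-dependent delays. The analysis window is the 10
minutes preceding the seizure-onset marker, segmented into 2-s epochs.
Epochs are treated as independent realizations when pooling MVAR
regressions, so epoch boundaries never create artificial lagged mixing.

Independent-component artifact rejection is deliberately out of scope:
component selection is a manual, operator-dependent step that cannot be
reproduced from a written description. The pipeline assumes pre-cleaned
input; `common_average()` is available but off by default, because the
inverse operator applies its own average-reference projection.

# Forward model and inverse solution

The forward model is the exact surface potential of a current dipole in a
homogeneous conducting unit sphere with insulating exterior, evaluated by
its Legendre expansion (truncated when the geometric tail bound falls
below $10^{-14}$). A subject-specific boundary-element model is a
non-goal; with 21 electrodes the spherical model is adequate for the
region-level resolution targeted here, and it is analytic, fast, and
testable against an independent naive evaluation.

The default source space places one fixed-orientation (radial) source at
each of 68 region centroids (34 per hemisphere, mirror-symmetric Fibonacci
lattice at radius 0.75). Two choices deserve comment:

* **Scalar rather than free-orientation sources.** Region-level signed
  time series are what the spectral, DTF and Hilbert stages consume;
  fixed orientations make those series well defined and avoid the
  threefold ambiguity of free-orientation estimates.
* **Region-centroid grid rather than a dense cortex.** 21 sensors cannot
  resolve thousands of vertices; all downstream stages operate on 68
  regions anyway. A dense grid plus within-region averaging (with
  per-vertex sign alignment, since orientations are defined up to sign)
  is supported through `parcellation_table()` and used in the imaging
  tests.

The inverse is the standardized minimum-norm solution: kernel
$T = G^\top (G G^\top + \alpha I)^{+}$ (average-reference projector
applied first), with each source standardized by its resolution-derived
variance, $\hat s_j = (T y)_j / \sqrt{(TG)_{jj}}$. With $\alpha = 0$ this
estimator has the zero-localization-error property for noiseless single
sources, which the test suite exercises on random lead fields. The
automatic regularization is $\alpha = \mathrm{tr}(G G^\top)/(m\,
\mathrm{SNR}^2)$ with SNR = 3, the conventional default; the value used in
the original clinical analysis is unknown, so it is config-exposed.
Identity noise covariance is assumed throughout (no covariance estimation
procedure is described for the clinical data). The standardized estimate
is invariant to joint rescaling of lead field and data, so the arbitrary
conductivity scale of the spherical model is immaterial.

# Spectral description

Welch PSD with 2-s Hann windows and 50% overlap, one-sided density
normalized so that its integral equals signal variance. Band powers are
mean in-band density converted to dB/Hz (mean, not sum, to keep density
units). Band edges: delta 1--4, theta 4--8, alpha 8--13, beta 13--30,
low-gamma 30--48, high-gamma 52--80 Hz, half-open $[lo, hi)$. Only the
delta edges are fixed by the underlying clinical observation (preictal
delta-power increase); the others are the conventional choices, and the
gamma split leaves out 48--52 Hz because the notch filter empties it.

# Directed networks

Per-epoch samples are pooled into a ridge-regularized least-squares MVAR
fit. Regularization is not cosmetic: 68 region series reconstructed from
21 sensors are rank-deficient by construction, and the ridge (default
$10^{-3}$, trace-scaled) makes the pooled design invertible while leaving
well-conditioned problems essentially untouched (coefficient recovery
RMSE < 0.005 on a 68-region VAR(2) test at the full 300-epoch size).
Model order is chosen by BIC over 1..10 by default; the order used
clinically is unstated.

The DTF is the row-normalized squared transfer function
$\gamma^2_{ij}(f) = |H_{ij}(f)|^2 / \sum_m |H_{im}(f)|^2$ with
$H(f) = (I - \sum_k A_k e^{-\mathrm{i} 2\pi f k / f_s})^{-1}$: the
fraction of inflow into sink $i$ attributable to source $j$, summing to 1
over sources for every sink and frequency. Band networks average
$\gamma^2$ over in-band frequencies and are stored as
`W[source, sink]` with zero diagonal, so out-degree is a row sum — the
convention under which the packaged toy-graph example (a node with two
incoming and one outgoing unit edge having DCin 2, DCout 1, DC 3) reads
naturally.

Node scores integrate each centrality over a proportional-threshold sweep
(densities 0.05--0.50 in steps of 0.05 by default; the clinical sweep
range is unstated) by the trapezoidal rule. Thresholding keeps the
strongest edges *with their weights* — the degree definition in use
explicitly covers weighted networks — and breaks ties deterministically
by index order. Scores are normalized by their maximum and regions
$\ge 0.95$ are hubs. The published figures also mention a "top 5%"
visualization rule; whether it coincides with the $\ge 0.95$ rule is
unclear, so the package implements the normalized-score rule and leaves
top-k selection to the caller.

# The seizure index

The SI is specified conceptually as the inverse mean escape time from a
resting to a seizure state in a bistable stochastic model informed by the
DTF network and Hilbert-transformed signals; the source description cites
prior work without equations. This package fixes one canonical
instantiation and isolates every choice in `si_config()` so alternatives
can be swapped in:

* **Node dynamics.** Double-well potential $V(x) = x^4/4 - x^2/2$
  (resting attractor $-1$, seizure attractor $+1$, barrier height 1/4 at
  $x = 0$), additive white noise, Euler--Maruyama integration at
  $dt = 0.01$ model-time units. Halving $dt$ changes mean escape times by
  well under 5% (tested).
* **Coupling.** Diffusive coupling through the band's unthresholded DTF
  weights, $c \sum_j W_{ji} (x_j - x_i)$, gain $c = 0.5$. Diffusive form
  keeps the uncoupled fixed points exact and means a region is pulled
  towards the seizure basin only when its inputs have already escaped.
  Whether the original analysis thresholded the SI network is unstated;
  unthresholded is the neutral choice.
* **Noise from the Hilbert envelope.** $D_i = d_0 (CV_i / \mathrm{median}
  \, CV)^2$, clipped to $[10^{-4}, 1]$, with $d_0 = 0.1$ and $CV_i$ the
  coefficient of variation of region $i$'s band-limited envelope. Bursty,
  strongly amplitude-modulated activity — the preictal signature —
  therefore maps to higher noise intensity and faster escape. The square
  makes $D$ scale like envelope *variance* fluctuations. Hilbert phase is
  extracted but not yet used beyond the envelope; this is a known,
  deliberate limitation of the instantiation.
* **Escape definition.** First passage to $x \ge 0.5$: the trajectory has
  crossed the barrier and committed to the seizure basin. The attractor
  point itself is *not* a usable threshold: the drift vanishes linearly
  at $x = +1$, so the approach is asymptotic and "first time at $+1$"
  systematically exceeds the Kramers time by ~20% in the relevant noise
  range (verified by quadrature of the exact mean-first-passage-time
  integral). With the basin-midpoint threshold, simulated mean escape
  times agree with the Kramers closed form
  $\tau = (2\pi/\sqrt{2}) e^{1/(4D)}$ to within 15% for
  $D \in [0.08, 0.15]$, as the acceptance suite checks.
* **Censoring.** Realizations that never escape by `t_max` (default 100)
  enter the mean at `t_max`, biasing SI *downward* for stable regions —
  the conservative direction — and the censored fraction is reported.

SI values are normalized by their maximum; regions $\ge 0.95$ form the
epileptogenic set, mirroring the centrality hub rule.

# The synthetic-data generator

Because no patient recordings are distributable, every downstream stage
is validated on ground-truthed synthetic preictal EEG
(`scenario_preictal()`):

* 68 regions (reduced 16-region / 60-s profile for fast tests), 10 min at
  256 Hz, one planted driver region;
* source dynamics: MVAR(1) recursion whose off-diagonal coefficients
  (driver $\to$ 5 random targets, coefficient 0.35) carry the directed
  structure; innovations are white noise plus per-band AR(2) resonators
  (alpha for all regions; delta with power multiplier 8 for the driver);
* the driver's delta drive is multiplied by a slow periodic burst
  envelope (period 10 s, depth 0.85), emulating intermittent preictal
  rhythmic delta. This is not decoration: the Hilbert envelope of any
  stationary Gaussian process is Rayleigh with a fixed coefficient of
  variation ($\approx 0.52$) *regardless of its power*, so an unmodulated
  driver would be invisible to the envelope-CV noise map however strong
  its delta power. Amplitude modulation is exactly the feature the SI
  route detects;
* scalp projection through the spherical lead field plus white sensor
  noise at SNR 5 (broadband power ratio; no noise model is described for
  the clinical recordings).

What the generator does *not* emulate: ocular/muscle artifacts,
non-stationary background rhythms, volume-conducted deep sources,
electrode-position error, and ictal dynamics. Passing the end-to-end
tests therefore demonstrates that the pipeline recovers drivers under its
own model assumptions — a necessary condition, not clinical validation.

The core end-to-end property: across 20 seeded runs of the reduced
profile, the planted driver attains the top delta-band DCout AUC in at
least 90% and a top-2 normalized SI in at least 80% of runs. The
published patient-level concordances (7/15 for DCout, 8/15 for SI) are
not reproducible without the clinical recordings and are excluded; the
property-based surrogate replaces them.

# Evaluation

Per patient, the predicted set is compared with the resected regions:
overlap with Engel class I is a true positive, overlap without seizure
freedom a false positive, no overlap despite seizure freedom a false
negative, and no overlap with an unfavorable outcome a true negative.
From the pooled counts the package computes sensitivity, specificity,
accuracy, PLR, NLR and DOR with Wilson score 95% intervals for the three
proportions. Wilson was chosen because it uniquely reproduces all four
published CI pairs for the cohort proportions (6/10: 31.3--83.2%; 4/5:
37.6--96.4%; 5/6: 43.6--97.0%; 4/10: 16.8--68.7%); the exact
Clopper--Pearson interval does not. Ratio-statistic CIs use the log-scale
normal approximation with Haldane correction for zero cells; the
published DOR intervals are not reproduced by the standard Woolf method
and are therefore not asserted anywhere.

The per-metric TP/FP/TN/FN counts shipped in
`extdata/printed_derived_contingency.tsv` are tagged
derived-from-printed-values: they were recovered uniquely from the
published statistics, not printed directly. The implied
favorable/unfavorable splits are mutually inconsistent across metrics
(SI and DCin imply 10/5, DC implies 9/6) while the cohort reports 10
Engel-I patients; the fixtures record the published numbers verbatim and
the discrepancy is left unresolved.

Metric comparisons use Pearson's chi-square on the correct/incorrect 2x2
table when all expected counts are at least 5, otherwise Fisher's exact
test (point-probability two-sided rule); both can be forced.

# Numerical choices and degenerate inputs

* Sparsity-threshold ties break by (source, sink) index order, making
  thresholded networks reproducible on weight-tied graphs.
* All-zero score vectors yield empty hub sets with a warning; fully
  censored SI runs flag every region and warn.
* The EDF writer stores 16-bit samples with per-channel physical scaling
  (round-trip error bounded by one digital step) and pads non-integer
  final seconds with zeros, warning when it does.
* Unstable fitted MVAR models are returned flagged (`stable = FALSE`)
  with a warning rather than an error, since short noisy segments can
  produce borderline fits that are still usable for inspection.
* The bistable integrator halves `dt` once if a trajectory diverges
  (|x| > 10), then errors.
* Vertex/region ids are 1-based in all files and in `parcellation_table`;
  matrix code indexes rows directly.

# Problem sizes used by the shipped tests

The suite uses the reduced 16-region / 60-s profile for its 20-seed
end-to-end checks, the full 300-epoch / 68-region size for the MVAR
recovery check, 2000 realizations per noise level for the Kramers check,
and 100 random stable models for DTF normalization. These sizes were
chosen so that Monte-Carlo sampling error is several times smaller than
each tolerance being asserted.

# Known limitations

* The SI instantiation is one faithful reading of an underdetermined
  description; Hilbert phase is currently unused.
* The spherical forward model ignores skull conductivity layering; no
  claim of anatomical accuracy is made for real recordings.
* Evaluation treats region overlap as binary; partial-volume overlap
  between predicted hubs and resections is not graded.
* The generator's coupling, gains and burst parameters are calibration
  choices of this package, not facts about the clinical cohort.
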