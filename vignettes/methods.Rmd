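---
title: "Quantifying cortical activity and synapse morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical activity and synapse morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroact)
```

# Scope

`neuroact` implements the quantitative core of an in-vivo / ultrastructural
study of cortical hyperactivity: processing of two-photon calcium movies
up to per-cell activity metrics, EM synapse morphometry, confocal puncta
density, Cavalieri volumetry, and the two group comparisons those metrics
feed (two-sample Kolmogorov–Smirnov, unpaired t). A synthetic-data module
generates all inputs with known ground truth; everything below about what
the tests demonstrate is conditional on how faithful those simulations are
to real recordings, which is discussed at the end.

# The calcium trace model

A cell's somatic fluorescence is modelled as

$$F_i(t) = F_0\,\Big(1 + \sum_k a_{ik}\,K(t - t_{ik})\Big)
          + r\,N(t) + \varepsilon_i(t),$$

where events \(t_{ik}\) form a homogeneous Poisson process, amplitudes
\(a_{ik}\) are Gaussian (truncated at zero) in ΔF/F units, \(N(t)\) is a
shared neuropil trace entering through the contamination coefficient
\(r\), and \(\varepsilon\) is white Gaussian sensor noise. The kernel

$$K(t) = \frac{e^{-t/\tau_d} - e^{-t/\tau_r}}{\max_s\,(e^{-s/\tau_d} - e^{-s/\tau_r})},
\qquad t \ge 0,$$

is normalized to peak exactly 1, so an isolated event's peak ΔF/F equals
its amplitude.

Key parameters, defaults, and reasons:

| parameter | default | unit | why |
|---|---|---|---|
| `frame_rate_hz` | 30 | Hz | the acquisition rate of the recordings being emulated |
| `tau_rise_s`, `tau_decay_s` | 0.07, 0.8 | s | mid-range GCaMP6m-like kinetics; no analysis decision rests on them and both are free parameters |
| `neuropil_coeff` | 0.7 | — | the printed compensation coefficient; the generator applies the same value so compensation inverts contamination exactly |
| `baseline_f` | 100 | a.u. | arbitrary fluorescence scale |
| `amp_mean`, `amp_sd` | 0.5, 0.1 | ΔF/F | somatic transient sizes typical of GCaMP recordings |
| `noise_sd` | 4 | a.u. | per-frame noise ≈ 0.04 ΔF/F, i.e. transients ≈ 12× the noise floor — a realistic somatic SNR at 30 Hz; a transient must exceed roughly 4 robust SDs to survive the 20-frame criterion with \(\tau_d = 0.8\) s, so detection-recovery results are meaningful rather than borderline by construction |
| `np_mean_f`, `np_sd_f` | 30, 5 | a.u. | slow shared background at ~30 % of baseline |

The neuropil trace is a random walk smoothed by a 1 Hz zero-phase low-pass
and standardized to `np_sd_f` around `np_mean_f`: a slow, spatially
uniform background — exactly the regime the compensation rule targets.
It deliberately has no spatial structure; see the limitations section.

All randomness flows from one seed through named substreams (events,
amplitudes, neuropil, noise, shifts, geometry, phantoms), so any stage can
be regenerated in isolation and identical configurations are bit-identical.

# Motion correction

Frames are corrected by integer-pixel rigid translation only: the source
material gives no sub-pixel procedure, and integer shifts make recovery
testable exactly. A candidate shift's score is the Pearson correlation
between the frame and the displaced reference **on their overlap** — no
FFT wrap-around, matching the edge-replication padding used when shifting.
Ties are broken toward the smallest \(|dy|+|dx|\), then smallest \(dy\),
then \(dx\); a zero-variance frame gets shift (0, 0) and a degenerate
flag. The default search radius of 10 px is generous for anesthetized
preparations.

One identifiability caveat: translations are only defined relative to a
reference. If the reference is the mean of *uncorrected* frames, it sits
at the mean displacement, and estimates recover applied shifts up to that
constant offset. The recovery tests therefore translate a known scene and
estimate against that scene, which is also the honest statement of what
"exact recovery" can mean.

# Trace extraction and compensation

- ROI signal: unweighted mean over the ROI pixel set.
- Neuropil signal: mean over an annulus of pixels at Chebyshev distance
  in (2, 8] px from the ROI, with the pixels of *every* ROI removed, and
  clipped at image borders. The annulus defaults are standard practice at
  this magnification; an empty annulus is an error asking the caller to
  widen it.
- Compensation: \(F_{comp} = F_{ROI} - r\,F_{np} + r\,\mathrm{median}(F_{np})\)
  with the median over the whole recording — the rule as printed uses a
  single median term, not a windowed one. Two consequences are used as
  exact test identities: constant neuropil and \(r = 0\) leave the trace
  untouched, and the output minus input equals
  \(-r\,(N - \mathrm{median}\,N)\) independently of \(F_{ROI}\).
- Filtering: 4th-order Butterworth at 10 Hz applied forward–backward
  (zero phase, so onsets don't move), with odd-reflection padding so that
  DC — and hence a constant trace — passes through exactly. Filtering is
  applied **after** compensation; the source is silent on the order, and
  this choice keeps the compensation identities exact at the raw stage.
  Both the cutoff and the order are arguments.
- ΔF/F: \(F_0(t)\) is the rolling 20th percentile over a centred 30 s
  window (truncated at the edges); \( \Delta F/F = (F - F_0)/F_0\). A low
  percentile keeps the baseline robust to event density. \(F_0 \le 0\) is
  an error, not a silent NaN.

# Transient detection and activity metrics

"Prominent" transients are not defined in the source; they are
operationalized as excursions above

$$\theta = \mathrm{median}(\Delta F/F) + k\,\cdot 1.4826\cdot
\mathrm{MAD}(\Delta F/F), \qquad k = 3,$$

the robust scale being resistant to the events themselves contaminating
the baseline. An event is a maximal run of consecutive supra-threshold
frames, after bridging sub-threshold gaps of at most `minGap` frames
(default 1 — a single-frame noise dip must not split one transient in
two), and is kept only if it spans at least `minRun = 20` frames — the
printed criterion, stated in frames and tied to the 30 Hz rate
(≈ 0.7 s). Amplitude is the peak ΔF/F inside the run: the simplest
reading of "average transient amplitudes", and on noise-free simulated
traces it equals the generated event amplitude because the kernel peaks
at 1. A cell is *active* with ≥ 1 event; frequency is events per minute
of recording; FOV summaries report the active fraction and pooled metric
vectors.

Two detection properties are enforced by construction and tested: raising
\(k\) never adds events, and the 19-vs-20-frame boundary is exact. The
boundary tests use bounded (uniform) noise so that no noise frame can
cross \(\theta\) — with Gaussian noise a rare supra-threshold spike
adjacent to a 19-frame pulse would occasionally merge and the boundary
statement would be false with small probability, which is a property of
the fixture, not of the detector.

# Morphometry, puncta, volumetry

Geometry is measured in the annotation plane (micrographs are 2-D
sections): absolute shoelace area for bouton outlines (orientation
independent, rejecting self-intersecting polygons), summed segment
lengths for active zones, and point-to-segment distances clamped to
endpoints for the vesicle "beeline". Classification applies the
mitochondrion rule first — at least one on each side of the synapse ⇒
inhibitory — then PSD asymmetry ⇒ excitatory, else unclassified; the
mitochondrion criterion is the explicit operational rule, so it takes
precedence. Outputs carry unit labels (nm for EM, µm for confocal, mm for
MRI) and mixing units across annotations in one table is an error.

Puncta analysis labels 26-connected components (6-connectivity is
available), converts each component's voxel volume \(V\) to the
sphere-equivalent diameter \((6V/\pi)^{1/3}\) — the source filters
"diameter" of 3-D particles without defining it, and the sphere-equivalent
convention is the standard particle-analysis reading — keeps the
0.01–1 µm band, and divides the kept count by the analysed volume after
dropping the requested top/bottom z slices.

The Cavalieri estimator is the plain cumulative area × slice increment,
with no end correction — that is the formula as printed. On analytic
sphere phantoms sliced at midplanes the estimate converges quadratically,
and at the 0.01 mm increment used in the tests it sits within 0.01 % of
\(4\pi r^3/3\). Regional volumes normalize to intracranial volume as a
percentage. The laminar profile splits an ROI's extent along a direction
into 10 equal bands (half-open intervals, last band closed) and counts
in-ROI objects per band; counts always sum to the in-ROI total.

# Statistics

Both tests are implemented from first principles, with `stats::ks.test`,
`stats::psmirnov` and `stats::t.test` used as independent cross-checks in
the test suite only.

The KS statistic is the exact supremum of the ECDF difference evaluated
at pooled unique points (right-continuous ECDFs, so ties are handled
exactly). The p-value uses the exact Smirnov null distribution — a
lattice-path recursion over the \(\binom{m+n}{m}\) interleavings —
whenever the samples are tie-free and \(mn \le 10^4\), and the asymptotic
Kolmogorov distribution with effective size \(mn/(m+n)\) otherwise. The
wider-than-usual exact range is deliberate: at per-group sizes around
100 the asymptotic approximation is visibly conservative (attained size
2–4 % at nominal 5 %), which would distort calibration claims. Ties fall
back to the asymptotic p with a warning. Two further subtleties are
documented because they look like bugs when first encountered: (i) with
*exactly equal* group sizes the null lattice of D is coarse (multiples of
\(1/n\)) and even the exact test attains only ≈ 3.6 % at nominal 5 % —
pure discreteness, which is why the calibration simulations use 100 vs 99;
(ii) the KS D is invariant under strictly monotone transforms of both
samples, which the tests exploit.

The unpaired t test offers the pooled-variance (Student) and Welch
variants, two-sided p via the regularized incomplete beta tail. The
genotype-comparison report applies KS to pooled per-ROI / per-synapse
distributions and the t test to per-FOV summary metrics, mirroring how
such studies treat the two kinds of samples; ANOVA families for
behavioural designs are out of scope here.

# Pipeline and reproducibility

`runPipeline()` executes simulate → register → extract → detect → stats
from a versioned YAML configuration. Unknown keys anywhere in the config
are errors, not warnings — a silently ignored typo in `min_run` would
corrupt scientific output. Cross-stage preconditions (cutoff below
Nyquist) are validated before any stage runs; a stage failure halts the
run, keeps completed outputs and records the failing stage in the
manifest, which also stores the package version, seed and a config hash.
Reruns with the same config and seed are bit-identical, verified by
checksums over the CSV/JSON/TIFF outputs.

# Problem sizes

Tests and the acceptance script run simulations sized for a desk machine:
the detection-recovery study uses 50 cells × 500 s at 30 Hz (the full
per-trace pipeline on 15,000-frame traces), registration fixtures use
100 frames of 56² px with ±5 px shifts, calibration uses 400 null
replicates of 100 + 99 samples and 100 power replicates of 300 + 300
Poisson-derived frequencies, and geometry oracles run on 1000 random
instances each. The full suite completes in a few minutes.

# What the simulations do and do not show

The generator reproduces the *structure* the pipeline assumes: linear
event kernels, additive spatially uniform neuropil, white sensor noise,
rigid integer motion, star-shaped boutons, spherical puncta. Passing
tests therefore demonstrate internal correctness — each stage inverts or
recovers what the generator put in — and calibrated statistics. They do
not demonstrate robustness to what real data add: spatially structured
neuropil and overlapping cells, sub-pixel and non-rigid motion, photon
(Poisson) noise and bleaching, nonlinear indicator saturation, irregular
bouton shapes, or anisotropic confocal point-spread functions. Those are
deliberate non-goals; ROI segmentation is likewise an input, not a
feature. Where the source leaves a rule unstated (the prominence
threshold, the ΔF/F definition, the filter/compensation order, the
vesicle distance reference point — centroid assumed), this package's
choice is stated above and exposed as a parameter, and published figure
statistics that depend on those unstated rules are treated as
out of reach rather than as targets.
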