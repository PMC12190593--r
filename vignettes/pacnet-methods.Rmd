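---
title: "Methods: coupling, spectra and networks in pacnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling, spectra and networks in pacnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacnet)
```

pacnet analyses multichannel EEG from working-memory protocols through
three feature families — delta–gamma phase–amplitude coupling, Welch band
power, and binary correlation networks — and compares them with paired
nonparametric tests. This vignette records the model assumptions, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic generator does and does not emulate.

## Preprocessing model

A `recording()` is one subject in one state: a channels × samples matrix
in microvolts at a nominal 1000 Hz. Re-referencing subtracts the
sample-wise *average* of the mastoid channels (M1, M2) and drops them;
after subtraction a reference channel carries only the negated reference
mean, so keeping it would duplicate information. Whether the original
protocol averaged the two mastoids or linked them electrically is not
knowable from the recording itself; averaging is the common digital
convention and is what `rereference()` implements. Artifact removal (ICA,
blink rejection) is out of scope: synthetic inputs are artifact-free and
real-data users are expected to clean upstream.

## Filtering and the analytic signal

Band-pass filters are linear-phase FIR designs (Hamming-windowed `fir1`)
applied forward and backward, so the net response is zero-phase — any
phase distortion here would bias the coupling estimate directly. The
filter order is three cycles of the band's lower edge (6000 taps for
0.5 Hz at 1000 Hz), which bounds the transition band at roughly a third of
the lower edge frequency while keeping stopband rejection beyond 40 dB
after the double pass. The forward–backward pass is evaluated in the
frequency domain as multiplication by |H(f)|²; for a symmetric kernel this
is algebraically identical to the two time-domain passes and roughly an
order of magnitude faster at these kernel lengths. The first and last
`filter_taps` samples are edge transients and are excluded from all
phase/amplitude statistics.

Instantaneous phase and envelope come from the analytic signal
(one-sided-spectrum Hilbert construction). Phase is reported in
[−π, π); inputs shorter than three cycles of the band's lower edge are
flagged unreliable.

## Modulation index

Phase is divided into N = 18 equal bins (the standard bin count for this
estimator). The mean envelope per bin, normalized to `p`, yields

MI = (log N − H(p)) / log N,

with 0·log 0 ≡ 0 and natural logarithms internally — MI is a ratio of
logarithms and therefore base-invariant, which the test suite checks to
1e−12. Empty bins (impossible with ≥ 150 s of band-limited data, guarded
anyway) contribute zero mean amplitude; a histogram whose bins are all
zero is an error rather than a silent zero. MI is computed on the full
continuous segment per state; per-block epoching is not applied because
block boundaries are not part of the data model — users who need it can
split recordings before feature extraction.

The surrogate control circularly shifts the envelope by a random offset of
at least one second before binning, estimating the no-coupling MI floor
while preserving both marginal distributions.

## Welch spectra and band power

Defaults: 2 s segments, 50 % overlap, Hamming-family window
W(n) = (1−a) − a·cos(2πn/(N−1)) with a = 0.46. Periodograms are averaged
and normalized by fs·Σw², making `pxx` a one-sided density whose integral
recovers the signal variance (verified to 5 % at 60 segments). The band
feature is 10·log₁₀(scale · mean in-band density). The `scale` constant
(default 1) exists because published absolute dB levels depend on an
amplification factor that cannot be recovered from data; only dB
differences are comparable across analyses, and all package statistics use
differences.

## Networks

Correlations are Pearson's r between *raw band-filtered signals* (not
amplitude envelopes) over the full time course — the plain reading of the
defining formula applied to two signals. Binarization keeps an edge where
r ≥ θ, signed: published thresholds are positive and negative-edge
handling is unstated, so signed comparison is the default with an
absolute-value mode behind a flag. Degree is the row sum of the hollow
adjacency; clustering is Cᵢ = 2Eᵢ/(kᵢ(kᵢ−1)) with Cᵢ ≡ 0 where kᵢ < 2 (the
formula is 0/0 there; zero is the standard convention). Both are checked
against an exhaustive triangle-counting oracle and igraph on random small
graphs.

`select_threshold()` scans a 0.01 grid downward and returns the largest
threshold with no isolated node *and* density inside a configurable range
(default 0.05–0.45, the operationalization of "appropriate density"); if
no grid value satisfies both, it relaxes to the isolation criterion alone
with a warning. Analyses that replicate published contrasts should instead
set the printed per-band thresholds in the configuration, which is why
thresholds are config values and the scan is an offering for new data.

## Statistics

The signed-rank test drops zero differences, ranks |d| with mid-ranks, and
computes the exact two-sided p for n ≤ 25 by dynamic programming over the
doubled mid-ranks (the generating polynomial ∏(1 + x^{2rᵢ})/2). This stays
exact under ties, where the tabulated signrank distribution does not
apply; above 25 pairs a normal approximation with tie and continuity
corrections takes over. The exact branch is validated against full 2ⁿ
sign-pattern enumeration.

State contrasts are paired within subjects, per channel and on whole-brain
means. Group contrasts mirror a reporting idiosyncrasy worth flagging: the
whole-brain comparison of two *independent* groups pairs the per-channel
group means across the channels and applies a signed-rank test over those
channel pairs. That interpretation is an assumption, clearly labelled
`signed_rank_channels` in the output; per-channel subject-level contrasts
are additionally reported with an unpaired rank-sum test. No
multiple-comparison correction is applied by default (raw p < 0.05 across
nodes is the reporting convention this mirrors); Benjamini–Hochberg is
available via `p_adjust = "BH"`.

## The synthetic generator

Each channel is

x(t) = a_δ·sin φ(t) + a_γ·[(1 + χ·sin φ(t))/(1 + χ)]·sin(2π f_γ t + ψ) + ε(t),

a slow carrier (2 Hz), a fast carrier (40 Hz) whose envelope is modulated
by the slow phase with depth χ, and 1/f^β noise. The (1 + χ)
normalization keeps the *mean* envelope independent of χ, so coupling
depth and band power can be manipulated separately. The slow phase is
shared across a subject's channels (one common modulator); gamma phases
are channel-private; inter-channel correlation comes from shared 1/f
latent sources, one per community, carrying a `mixing` fraction of the
noise variance.

Two deliberate departures from the simplest textbook construction:

* **Phase drift.** The slow carrier's frequency drifts as a slow
  Ornstein–Uhlenbeck process (sd 0.3 Hz, 5 s correlation time). A strictly
  periodic modulator would make the surrogate control vacuous — shifting
  the envelope of a periodic signal merely rotates the preferred phase
  without weakening the coupling — whereas physiological delta coheres
  only over a few cycles. The drift is smooth, so the Hilbert phase tracks
  it and the carrier stays inside 0.5–4 Hz; `freq_drift = 0` restores the
  exact closed-form model used in the noiseless unit tests.
* **Amplitude calibration.** Defaults (a_δ = 10, a_γ = 22 µV, noise sd
  8 µV, mixing 0.9) are solved from a variance budget so that both
  analysis bands sit ≥ 10 dB above the 10–20 Hz background *and* the
  community contrast in mean correlation is ≥ 0.2. Because the delta
  carrier is subject-global it inflates within- and between-community
  correlations equally, so the contrast is carried entirely by the shared
  noise — these amplitudes favour separability for validation over
  physiological amplitude ratios (real gamma is far smaller than delta).

Group and state effects are multiplicative: task doubles χ; the
stimulation group gets χ×0.8, delta amplitude ×0.9, gamma amplitude ×1.15,
qualitatively matching the directions reported for anodal prefrontal
stimulation (lower coupling, lower delta power, higher gamma power than
sham) at roughly the printed effect ratios. No attempt is made to match
printed group means: those depend on unavailable recordings and an
unstated dB scale.

What the generator does **not** emulate: ocular/muscle artifacts, volume
conduction and reference topography, event-locked trial structure,
non-stationary power, heavy-tailed channel noise. Passing tests therefore
demonstrate correctness of the estimators and pipeline, not robustness to
real-world contamination.

## Problem sizes and determinism

The test and acceptance runs use reduced study profiles chosen as the
smallest designs with comfortable statistical margins: coupling recovery
at 20 replicates × 60 s single channels; null calibration over 200 studies
of 10 subjects × 4 channels × 20 s at 250 Hz (10 paired subjects make the
exact test's attainable level 0.0488, close to the nominal 0.05);
directional contrasts over 50 replicates of a 2 × 6-subject design. All
randomness flows from explicit seeds; identical configurations produce
byte-identical feature tables, which the suite asserts.

## Known limitations

* EDF support is the minimal continuous-signal profile (one data record,
  16-bit quantization); annotations and discontinuous records are not read.
* Correlation networks assume no zero-variance channels and treat the
  printed thresholds as given; no weighted-network metrics.
* The MI is the only coupling estimator provided (no mean-vector-length or
  GLM variants), and only the delta-phase/gamma-amplitude pair is
  computed by the pipeline.
* Absolute band-power levels are not comparable to published dB values
  without knowing their amplification constant.
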