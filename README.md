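# pacnet

Feature extraction and nonparametric statistics for multichannel EEG
working-memory studies. The package quantifies three complementary views of
cortical activity — delta–gamma phase–amplitude coupling, band-limited
spectral power, and correlation-based functional networks — and compares
them across task states and stimulation groups with Wilcoxon tests. It is
aimed at researchers analysing n-back/tDCS EEG protocols (60 channels,
1000 Hz) and at methodologists who need a fully verifiable pipeline: a
built-in synthetic EEG generator with ground-truth coupling lets every
stage be validated without access to clinical recordings, which such
studies typically cannot share.

## The measures

**Modulation index (MI).** Instantaneous delta phase (0.5–4 Hz) and the
gamma amplitude envelope (30–50 Hz) are extracted per channel by zero-phase
FIR filtering and the Hilbert analytic signal. Phase is divided into
N = 18 equal bins; the mean envelope per bin, normalized,

&nbsp;&nbsp;&nbsp;&nbsp;p(j) = ā(j) / Σₖ ā(k),

is compared against the uniform distribution through its Shannon entropy
H(p) = −Σ p log p:

&nbsp;&nbsp;&nbsp;&nbsp;MI = [log N − H(p)] / log N  ∈ [0, 1],

0 for phase-independent amplitude, 1 when all amplitude concentrates in a
single phase bin. MI is invariant to the logarithm base and to amplitude
scaling.

**Band power.** Welch's method: Hamming-windowed 2-s segments, 50 %
overlap, periodograms averaged and normalized by the window power so that
∫ Pxx df equals signal variance; the feature is 10·log₁₀(mean in-band
density) in dB.

**Networks.** Pearson correlation between band-filtered channel pairs,
binarized at a threshold (edge iff r ≥ θ); node degree kᵢ = Σⱼ aᵢⱼ and
clustering Cᵢ = 2Eᵢ/(kᵢ(kᵢ−1)). Thresholds are per-analysis configuration
values (0.32/0.56 delta/gamma for state contrasts, 0.43/0.67 for group
contrasts), with `select_threshold()` offering a grid scan (no isolated
nodes, density within a target range) for new data.

**Statistics.** Paired Wilcoxon signed-rank tests (exact null distribution
up to 25 pairs, computed by dynamic programming so tied ranks stay exact),
per channel and on whole-brain means; group contrasts pair per-channel
group means across channels, with unpaired rank-sum tests per channel.

## Worked example

```r
library(pacnet)

spec <- generator_spec(n_channels = 6, fs = 250, duration_s = 30, seed = 42)
study <- gen_study(spec, n_subjects_per_group = 8,
                   groups = c("sham", "tdcs"), states = c("pre_rest", "task"))
study$recordings[["sham01_task"]]
#> <eeg_recording> subject sham01 | sham | task
#>   6 channels x 7500 samples @ 250 Hz (30.0 s)

features <- extract_features(study$recordings, study_config(),
                             include = c("mi", "band_power"))
features
#> # A tibble: 576 × 7
#>    subject_id group state    channel feature_name  band          value
#>  1 sham01     sham  pre_rest CH01    band_power_db delta       12.6
#>  2 sham01     sham  pre_rest CH01    band_power_db gamma        8.26
#>  3 sham01     sham  pre_rest CH01    mi            delta-gamma  0.0114
#> # ...

mi_states <- compare_states(features, "mi", "delta-gamma")
dplyr::filter(mi_states, level == "whole_brain_mean")
#>   condition_a condition_b  mean_a mean_b   p_value significant
#> 1 pre_rest    task        0.00863 0.0352 0.0000305 TRUE

gamma_groups <- compare_groups(features, "band_power_db", "gamma")
format_comparison(dplyr::filter(gamma_groups, level == "whole_brain_mean"))
#> band_power_db [gamma, whole_brain]: (sham: 6.988 ± 0.02086; tdcs: 8.573 ± 0.01163; p = 0.0312) *
```

The whole-brain MI roughly quadruples from rest to task because the
generator doubles the coupling depth in the task state (MI grows faster
than linearly in the depth), and the stimulated group shows higher gamma
band power (+1.6 dB here, from the 1.15× gamma amplitude multiplier), both
detected by the signed-rank tests. `autoplot()` methods exist for
recordings, phase–amplitude histograms, spectra and networks, and
`tidy()`/`glance()` turn every result object into a tibble.

Absolute dB levels depend on an amplification constant that is exposed as
the `scale` option of `band_power_db()`; only dB *differences* are
meaningful across analyses.

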