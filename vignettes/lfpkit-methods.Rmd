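---
title: "Methods: models, detectors and design choices in lfpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, detectors and design choices in lfpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`lfpkit` quantifies hippocampal electrophysiology from two kinds of
recordings: laminar local field potentials (LFP) from linear silicon probes
spanning CA1 to the dentate gyrus (32 contacts at 25 µm in the canonical
configuration, 20 kHz), and single-channel chronic epidural EEG (2 kHz). On
top of these it implements evoked-response quantification (fEPSP,
afferent volley, population spike), Cavalieri stereology for serial-section
histology, and the group-statistics layer used to compare experimental
groups. A fully seeded forward model (`sim_config()`,
`generate_laminar_lfp()`, `generate_eeg()`, `generate_evoked_sweeps()`)
produces every input the pipeline consumes together with ground truth, so
all detectors and estimators can be benchmarked without access to animal
data.

# Signal primitives

All detectors share three primitives.

**Zero-phase FIR band-pass** (`bandpass_zerophase()`): a Hamming
windowed-sinc filter of even order (default 512) applied forward and then
backward, so the net phase response is zero and the effective magnitude
response is the squared single-pass response. Band edges are quantized to a
design grid (10 Hz for the ripple band, 0.5 Hz for the spindle band). Edge
handling: the signal is reflect-padded by `3 * (order + 1)` samples before
filtering and trimmed afterwards, which prevents onset transients from
seeding false detections. The convolution itself runs via FFT on 5-smooth
lengths, so minute-long 20 kHz traces filter in seconds.

**Savitzky–Golay smoothing** (`savgol_smooth()`): local least-squares
polynomial smoothing, default polynomial order 3 over a 5 ms window
(rounded up to an odd sample count). It reproduces any polynomial up to the
chosen degree exactly on interior samples.

**Hilbert envelope** (`hilbert_envelope()`): magnitude of the analytic
signal computed by one-sided spectral doubling, with reflect padding to a
5-smooth FFT length to limit edge transients.

# Spectral analysis

`average_spectrum()` averages Hamming-tapered one-sided periodograms of
non-overlapping segments (1 s for urethane LFP work, 5 s for chronic EEG)
in the linear domain, converting to decibels (`10*log10`, reference
1 µV²/Hz) last. The normalization is chosen so a unit-amplitude tone
integrates to 0.5 µV² and unit-variance white noise sits at `2/fs` per Hz;
the total linear area therefore matches the time-domain variance (Parseval)
up to windowing bias, a contract the tests hold to 5%. When the requested
resolution is finer than a segment's native resolution the segments are
zero-padded; when coarser, native bins are averaged onto the requested grid.

**Band powers** (`band_power()`) are areas under the linear PSD over a
closed interval on the frequency grid, reported in dB. The closed-interval
convention is stated explicitly because reproducibility requires a fixed
rule when band labels overlap (delta 1–4 Hz and theta 4–10 Hz share the
4 Hz bin).

**1/f normalization** (`normalize_1f()`) divides the linear PSD by its mean
over a high-frequency reference band (500–1000 Hz), i.e. subtracts a
constant in dB. This operationalizes "normalized by the 1/f decay" as a
flat correction anchored where the spectrum is oscillation-free; fitting a
`1/f^a` slope instead would be under-determined by the available
description. Every normalized quantity is exactly invariant to scalar gain
(electrode/amplifier differences), which the tests assert to 1e-6 dB.

**Theta segment selection** (`select_theta_segments()`) scores 1 s segments
by the theta (4–10 Hz) over delta (1–4 Hz) linear power ratio with a
default threshold of 2. On simulated schedules alternating theta and
large-irregular-activity (LIA) states, selected segments fall inside true
theta epochs essentially always once LIA epochs carry realistic slow
activity (see the generator section).

**Multitaper time–frequency** (`multitaper_tfr()`) uses Slepian (DPSS)
tapers, default time–bandwidth `NW = 3` with `K = 5` tapers, in 400 ms
windows with 97.7% overlap — a hop of exactly 9.2 ms. No DPSS
implementation ships with the available dependencies, so the tapers are
computed from the standard symmetric tridiagonal eigenproblem; for windows
longer than 1024 samples they are computed at 1024 points and
spline-interpolated to the window length, then renormalized (the error of
this interpolation is negligible for power averaging, and the tapers are
verified orthonormal in the tests). Event spectra (ripples, spindles) are
multitaper spectra of single windows centred on the event.

# Event detection

Both detectors (`detect_band_events()` with `ripple_config()` or
`spindle_config()`) run the same pipeline: band-pass (100–600 Hz for
ripples, 7–16 Hz for spindles, both order 512), rectify, Savitzky–Golay
smooth, z-score over the full analysis epoch, and mark candidates where the
z-score exceeds 2.5. Event boundaries come from the Hilbert envelope of the
band-passed signal: the contiguous region exceeding 1.6 robust-SD units
that contains the candidate peak.

Three implementation details matter and were settled by explicit analysis:

* **Robust envelope scale.** The boundary threshold uses a median/MAD
  z-score of the envelope rather than mean/SD. With event duty cycles of a
  few percent (60 spindles of 0.8 s in 600 s is ~9%), the plain SD of the
  envelope is inflated by the events themselves, which silently raises the
  boundary threshold and truncates measured durations by >100 ms. MAD
  matches the SD on Gaussian background (so sparse-event bands behave
  identically) while staying calibrated when events are dense. The
  detection-stage z-score keeps the plain mean/SD of the smoothed signal.

* **Candidates need boundaries.** A candidate whose peak lies in no
  supra-threshold envelope region has no delimitable extent and is dropped
  rather than kept as a point event.

* **Duration filter before merging.** Each candidate's own envelope region
  must reach the minimum duration (20 ms ripples, 300 ms spindles) before
  nearby events are merged (30 ms / 300 ms gaps). Filtering after merging
  lets chains of millisecond noise excursions bridge into apparently long
  events: on event-free 1/f noise that ordering produces on the order of
  one false ripple per second, while filter-then-merge leaves both
  detectors at or near zero false events per second at default settings.

**Ripple features** (`characterize_ripples()`): duration from the boundary
step; event power and peak frequency from the 100–300 Hz multitaper
spectrum of the ±200 ms window around the peak; occurrence rate at table
level. The sharp-wave amplitude is measured on the stratum radiatum
channel, smoothed with a 15 ms Savitzky–Golay window (so ripple-band and
unit activity do not contaminate the slow deflection), as the depth of the
trough within ±50 ms below a baseline interpolated between the 60–90 ms
flanks. The interpolated local baseline detrends the slow activity a sharp
wave rides on; flank distance was chosen by comparing estimators on
simulated events (closer flanks track the slow background better and the
sharp wave's Gaussian tail at 60 ms is only ~6% of its peak). Events whose
window crosses the recording edge are flagged `"edge"` and measured on the
available samples.

**Spindle features** (`characterize_spindles()`): duration from the
boundary step; spindle power in 10–16 Hz (the power band is deliberately
narrower than the 7–16 Hz detection band); inter-spindle interval
`t_start(k+1) − t_end(k)` within an epoch, undefined for a lone or last
spindle.

# Laminar analysis

**CSD** (`compute_csd()`): the discrete second spatial derivative
`-(V[j-1] - 2 V[j] + V[j+1]) / h²` at unit conductivity, sinks negative,
edge channels dropped. It is exactly zero on depth-affine potentials and
matches analytic second derivatives of smooth profiles to the discretization
error of the 25 µm grid (~1% for profiles a few contacts wide).

**Layer identification** (`identify_layers()`) is a deterministic
evidence-scoring version of the classic criteria: stratum pyramidale is the
channel maximizing ripple-band (100–250 Hz) power locked to detected
ripples, cross-checked against the MUA (500–5000 Hz) power profile;
radiatum is the channel below it with the largest event-locked sharp-wave
deflection (windows smoothed so MUA spikes cannot masquerade as slow
deflections); lacunosum-moleculare is the channel below radiatum maximizing
theta power among channels whose theta phase is shifted more than 120° from
pyramidale; the granule layer is the deepest MUA peak below slm (requiring
3 dB of prominence). Layers without evidence are returned as
`"unresolved"` with a reason code, never guessed. Theta power and phase are
computed on a Fourier-decimated copy (target 2 kHz) because a 513-tap
filter cannot be frequency-selective at 4–12 Hz when applied at 20 kHz.
Ripple detection for layer work should be run on LIA epochs, as in
practice.

# Evoked responses

`measure_evoked()` uses a 5 ms pre-stimulus baseline. The fEPSP amplitude
is baseline-to-extremum in the fEPSP window; the slope is the least-squares
fit over the 20–80% amplitude span of the initial falling phase. The span
levels are computed from a 3 ms median-filtered amplitude and the crossing
times are read on a 2 ms smoothed copy: the median filter keeps a narrow
population spike from stretching the span (the paper-level convention of
"using the initial falling phase to avoid contamination"), and the smoothed
crossings suppress first-passage bias, which otherwise biases the slope by
several percent at realistic noise. The population-spike amplitude is the
depth of the sharpest trough below the chord joining its flanking
positivities, falling back to the one-sided flank level (tangent method)
when the fEPSP limb swamps one positivity; smooth sub-threshold responses
have no flanking positivities and correctly measure zero.
`population_spike_threshold()` reports the lowest tested intensity whose PS
amplitude exceeds 3× the pre-stimulus noise SD of the measured (averaged)
trace. Paired-pulse ratios reuse the pre-first-pulse baseline for the
second response, whose windows are offset by the inter-pulse interval;
facilitation is probed at 40% of the maximal-response intensity and
inhibition at maximal intensity, at intervals of 25–150 ms.

# Stereology

`cavalieri_volume()` implements `V = sum(areas) × thickness × k` for every
k-th section (the study convention is every 3rd 50 µm section), with a
consistency check between stated positions and implied spacing. A cluster's
anteroposterior extension includes one section spacing, so a single-section
cluster has nonzero extent; multiple clusters in one animal are merged into
a single complex before the midpoint/extension are measured. Interlayer
distance is the mean point-wise separation of the two layer midlines over
their common support; the centroid-to-layer distance is the exact minimum
distance from the centroid to the layer polyline.

# Statistics

`student_t_two_tailed()` (pooled by default, Welch available),
`one_way_anova()` and `adjust_multiple()` delegate the numerics to
`stats::t.test`, `stats::oneway.test` and `stats::p.adjust`; the package
adds the degenerate-case policy (identical constant groups return
`t = 0, p = 1` with a warning rather than erroring, keeping batch pipelines
alive) and an uncapped Bonferroni mode in which adjusted values above 1 are
reported as-is, matching the reporting style of corrected tables. The Welch
variant exists because published tables of this kind often carry degrees of
freedom inconsistent with the stated group sizes; reconstructing groups
from reported moments reproduces pooled t statistics only to within a few
percent, which the tests treat as agreement at the precision of two-decimal
summary statistics.

`simulate_theta_power_study()` is a Monte-Carlo power analysis for the
flagship comparison: per replicate, 8 control and 8 deficit animals are
simulated as single-channel theta-state recordings (10 s at 2.5 kHz — the
rate must reach the 1 kHz normalization band), the deficit group's theta
amplitude reduced by 3 dB of power, normalized theta area measured per
animal, and a two-tailed pooled t-test applied. Between-animal variability
is 1 dB SD of theta power, a deliberately moderate value: with it, a 3 dB
deficit is detected with power above 0.9 at n = 8 per group, while
realistic between-animal spreads of 2–3.5 dB (as in published group tables)
would require larger groups — the study design question the function exists
to explore.

# The synthetic forward model

`generate_laminar_lfp()` sums, per channel: (i) independent `1/f^a` noise
(a = 1, total RMS 30 µV) synthesized by spectral shaping of white noise —
one complex inverse FFT per channel *pair*, since with a frequency-symmetric
gain spectrum the real and imaginary parts are independent Gaussian traces
with identical spectra;
(ii) theta (5 Hz with slow frequency drift and amplitude modulation) whose
amplitude profile peaks at stratum lacunosum-moleculare and whose phase
steps by 180° between the pyramidale and slm sides of the probe; (iii)
gamma (40 Hz) amplitude-modulated by theta phase; (iv) a shared
"large irregular activity" slow component (0.5–4 Hz, 40 µV RMS) gated to
LIA epochs — without it the theta/delta classifier sits on a knife edge
because plain 1/f noise under-represents LIA delta; its amplitude is kept
moderate so single-event sharp-wave amplitudes remain measurable (real
recordings can show much larger slow activity, in which case sharp-wave
amplitudes should be read from event averages); (v) sharp-wave-ripple
events at Poisson times (or a fixed count) during LIA: a 150 Hz burst
maximal at pyramidale plus a negative Gaussian sharp wave (300 µV, σ 25 ms)
maximal at radiatum; and (vi) MUA spike trains at the cell-body layers
(3-cycle 1.5 kHz wavelets, 200 µV, 50/s — the wavelet keeps spike energy
above the ripple band, as for real ~0.5 ms spikes, while giving the MUA
profile a >3 dB peak).

Two generator conventions deserve justification:

* **Flat-topped event envelopes.** Ripple bursts and spindles use a
  raised-cosine (Tukey) envelope with a 10–15% taper, and the ground-truth
  duration is the full envelope extent. A threshold-based duration estimate
  (the 1.6 SD Hilbert criterion) is only well-defined against truth when
  onset and offset are fast relative to the event length: for bell-shaped
  (Hanning/Gaussian) envelopes the supra-threshold support is 20–45%
  narrower than any nominal duration and varies with amplitude, making
  "duration error" ill-posed. The flat-top is also why detected peak times
  wander across the event plateau, and why detection-to-truth matching is
  interval-overlap based (tolerance 10 ms for ripples, 100 ms for
  spindles) rather than peak-to-peak.

* **Amplitudes in envelope z units.** From its synthesis gains the
  generator knows the band-limited noise RMS σ_b exactly; the Hilbert
  envelope of band-passed Gaussian noise is Rayleigh with mean 1.2533 σ_b
  and SD 0.6551 σ_b, so a requested envelope z-score maps deterministically
  to a burst amplitude. Ripples default to z in [5, 8], spindles to z = 6.

`generate_eeg()` builds SWS epochs from a 1 Hz slow oscillation plus
K-complexes (biphasic derivative-of-Gaussian transients, 250 µV, σ 80 ms),
each spindle preceded by a K-complex with probability 0.7 ("typically but
not always"); REM/awake epochs are theta-dominated. Spindles are 12 Hz,
800 ms, placed in SWS with a 2 s minimum gap.

`generate_evoked_sweeps()` models the afferent volley as a brief biphasic
deflection scaling sublinearly with intensity, the fEPSP as a negative
alpha function (τ = 4 ms, latency 3 ms) whose amplitude is sigmoidal in
intensity (midpoint 300 µA, slope 90 µA, maximum 1.2 mV) over the 8-step
25–900 µA grid, and the population spike as an inverted Ricker wavelet
(σ 0.6 ms) above a 400 µA threshold — the Ricker's flanking positivities
are what the classic chord measurement reads. White noise is added at
`amplitude_max / SNR` (default SNR 10) per sweep; ten sweeps per intensity
are averaged before measurement, as in standard input/output practice.
Ground-truth slopes are computed on a dense grid independent of the
estimator's sampling.

Determinism: identical config and seed give bit-identical recordings and
truth on a given platform; every output records its seed.

# What the benchmarks do and do not show

The simulator reproduces the phenomenology the detectors key on —
band-limited bursts on 1/f background, laminar amplitude/phase profiles,
state-gated events, sigmoidal evoked behaviour — with Gaussian noise and
stationary statistics within states. It does not reproduce non-Gaussian
artifacts (movement, chewing, electrical transients), non-stationary
background drift, overlapping event types (ripples riding on dentate
spikes), electrode drift, or realistic between-animal variability in
spectra. Passing benchmarks therefore demonstrates correctness of the
implementations and well-calibrated behaviour under the modelled
conditions, not field performance on arbitrary recordings; on real data the
fixed 2.5 SD threshold inherits the usual dependence on how much of the
scored epoch the events themselves occupy.

Problem sizes used by the packaged benchmark suite: the ripple benchmark is
a 600 s, 32-channel, 20 kHz scene with 80 events; the spindle benchmark
600 s of SWS EEG at 2 kHz with 60 spindles; false-positive rates use 300 s
(20 kHz) and 600 s (2 kHz) of event-free noise; layer identification runs
on 12 s scenes (long enough for ~6 ripples and thousands of theta cycles);
the power study uses 10 s per animal. The ripple stages read only the
pyramidale and radiatum channels, so the benchmark extracts those two
channels before detection to bound memory at scale.

# Known limitations

* The order-512 FIR at 20 kHz has a ~130 Hz transition band; the "10 Hz
  design resolution" is honoured as an edge-quantization grid, not as a
  transition width (which would need thousands of taps).
* DPSS tapers for windows over 1024 samples are interpolated, not exact.
* Layer identification assumes a single CA1 probe track with the canonical
  dorsal-to-ventral ordering; double cell layers are visible in the MUA
  profile but only the deepest peak below slm is labelled granule.
* The evoked fEPSP amplitude above population-spike threshold reflects the
  compound response (as in real field recordings); amplitude recovery is
  therefore benchmarked at the largest spike-free intensity.
* Uncertainty on single-event sharp-wave amplitudes is dominated by slow
  background activity; group comparisons should use event medians.
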