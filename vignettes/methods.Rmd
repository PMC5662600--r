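---
title: "Cycle-wise phase-amplitude coupling and stimulation entrainment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-wise phase-amplitude coupling and stimulation entrainment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegpac)
```

## The scientific question

Slow (0.5–4 Hz) cortical oscillations during NREM sleep organize faster
rhythms: sleep-spindle (10–16 Hz) and gamma (70–110 Hz) amplitude wax and
wane with the slow-oscillation phase. Whether a weak external periodic
driver — low-frequency transcranial alternating current stimulation (tACS)
or rhythmic acoustic stimulation — can entrain these nested rhythms is a
question with direct consequences for sleep-dependent memory consolidation
protocols. `ieegpac` implements the intracranial-EEG analysis chain needed
to answer it: band decomposition, stimulation-artifact removal, cycle-wise
phase-amplitude coupling (PAC) with surrogate statistics, sleep-event
detection, and electrode-level electric-field estimation — together with a
synthetic-data generator that provides ground truth for every stage.

## The coupling statistic

For a high-frequency amplitude envelope $A(t)$ and a low-frequency phase
$\phi(t)$, the package uses the unnormalized modulation index

$$ r \;=\; \bigl|\langle A(t)\, e^{i\phi(t)} \rangle\bigr|, $$

the absolute value of the time average of $z(t) = A(t)e^{i\phi(t)}$,
pooled over all retained samples (across cycles and time within cycles,
not per-cycle means averaged). Its argument is the preferred phase. $r$
carries amplitude units (µV); a normalized companion $r/\bar A$ is
reported for cross-channel comparison. For a noise-free multiplicative
coupling $A(t) = \bar A\,[1 + d\cos(\phi - \phi_0)]$ under uniform phase,
$r/\bar A = d/2$ exactly — the closed-form oracle the synthetic generator
is designed around.

The phase convention everywhere is: **0° at the positive peak** of the
reference waveform (the cortical up-state for most surface electrodes, the
anodal peak for the stimulation reference), ±180° at the trough, phase
increasing with time, wrapped to (−180°, 180°].

### Phase sources

* **Endogenous**: complex Morlet filter at (fc = 1 Hz, bw = 1 Hz) (or
  0.75/0.75); the instantaneous phase is the argument of the analytic
  signal. Because slow oscillations are non-sinusoidal, their phase dwells
  unevenly; a rank-based *histogram equalization* maps the sorted phases
  onto an equally spaced circular grid (anchored at the smallest sorted
  value, so an already-uniform grid is a fixed point), ensuring a non-zero
  $r$ reflects amplitude modulation only.
* **tACS**: the stimulation artifact, modeled as a harmonic series (below);
  phase comes from the fitted fundamental.
* **Acoustic**: elapsed time since each trigger onset, one cycle per
  trigger, cycle duration equal to the mean inter-trigger interval.

### Cycle screening

Cycles are the analysis unit (300 per 5-min block at 1 Hz, 225 at
0.75 Hz). A cycle is dropped when

* it overlaps a wavelet edge-transient region (`"edge"`),
* its mean high-frequency power exceeds `median + 2·IQR` of all cycle
  powers in the electrode (`"outlier power"`) — the reference point of the
  published 2·IQR rule is ambiguous, so the literal `power > 2·IQR`
  variant is available via `rule = "2iqr"`; the median-anchored form is
  the default because the bare IQR has the wrong scale for a location
  threshold,
* (endogenous only) its peak slow-oscillation amplitude is below 50 µV
  (`"low SO amplitude"`); *peak* rather than mean amplitude was chosen so
  that a cycle with a usable phase excursion anywhere is kept.

Screening is single-pass: thresholds are computed once on all cycles.

## Surrogate significance

The null distribution of $r$ is built by incrementing each cycle's phase
by an independent uniform draw — the same draw for every electrode within
a cycle, so electrode-wise results share their randomization — and
recomputing $r$ 10,000 times. The p-value is the fraction of surrogates
meeting or exceeding the observed $r$, floored at $1/n_{\text{shuffles}} =
10^{-4}$. Benjamini–Hochberg FDR is applied across electrodes within a
block; deliberately, no correction is applied across blocks (they measure
stability of an effect) or bands (planned comparisons).

### The shift-range choice, and a known calibration property

The shift range is **[0°, 180°)** by default, following the published
procedure literally. This choice has a measurable consequence: because
$E[e^{i\delta}] = 2i/\pi \neq 0$ for a half-circle shift, surrogates are
not exchangeable with the observed statistic, and the test is
*conservative* — on simulated null electrodes (constant-amplitude
envelopes, ramp phases) the empirical rejection rate at $\alpha = 0.05$ is
about 0.3–0.5% rather than 5%. Full-circle randomization
(`shift_range_deg = 360`) restores exchangeability and nominal calibration
(measured ≈ 5%). The package keeps the literal half-circle default for
fidelity and exposes the full-circle option; the acceptance suite records
both rates. Conservatism costs power in principle, but with 300 cycles a
coupling depth of 0.5 is still detected essentially always, so the
practical impact at study sample sizes is small. Note this conservatism
only *strengthens* any significant finding made with the default.

## Harmonic artifact model

During sinusoidal tACS the recorded signal is dominated (>10×) by the
stimulation artifact plus harmonic distortion from the amplifier chain.
Because the artifact is periodic, it is fit per channel and per block as

$$ \hat a(t) = dc + \sum_{k=1}^{K} a_k \cos(2\pi k f_0 t) + b_k
\sin(2\pi k f_0 t), \qquad K = \lfloor 40 / f_0 \rfloor, $$

with the base frequency refined by golden-section search on residual
variance within ±1% of the nominal stimulation frequency (tolerance
$10^{-6} f_0$; the nominal value is restored with a warning if the search
pins at the window boundary). Coefficients come from the normal equations
— the sinusoid basis is near-orthogonal over ≥10 periods, so this is both
fast and well-conditioned. Subtracting $\hat a$ suppresses a stationary
artifact by ≥40 dB at the fundamental and harmonics and leaves the neural
signal essentially untouched (residual-to-injected correlation >0.99 in
the round-trip tests).

Fit quality is summarized by the residual variance ratio *at the harmonic
frequencies* (±f₀/8 around each harmonic, wide enough to catch
drift sidebands); a ratio above 0.2 flags the channel "poor artifact
removal" — the non-stationary case, typically caused by movement — and
the screening stage discards it. Trapezoidal stimulation waveforms are
refused outright: their broadband spectrum does not permit analysis during
stimulation, which is why entrainment after such blocks is assessed from
the stimulation-free intervals instead (see `post_stim_phase_coherence`).

Whether one global $f_0$ or one per channel should be fit is not
prescribed anywhere; the package fits per channel (artifact amplitude and
phase vary with electrode distance) and records the fitted $f_0$ per
channel in the output.

## Band decomposition

`morlet_bandpass` parameterizes a complex Morlet wavelet by center
frequency and bandwidth, where **bandwidth is the full width at half
maximum of the frequency-domain magnitude response** (so (14, 7) means the
amplitude response falls to one half at 10.5 and 17.5 Hz). The competing
reading — half-*power* width — would make the wavelet √2 narrower;
the FWHM-of-magnitude definition was chosen as the more literal one and is
pinned by a regression test, with this paragraph serving as the sensitivity
flag. The wavelet carries the standard zero-mean correction so DC offsets
cannot leak into amplitude estimates. Edges are reflect-padded by one
support (4 temporal σ) and the edge region is reported so downstream
stages flag, rather than silently keep, boundary-contaminated cycles and
events.

Canonical bands: fast spindle (14, 7), slow spindle/alpha (10, 5), theta
(7, 3.5), gamma (90, 40), slow oscillation (1, 1) and (0.75, 0.75) Hz.

### Multitaper power

Band-integrated power uses K = 5 sine tapers (Riedel–Sidorenko) with a
leave-one-taper-out jackknife CI. Sine tapers were chosen because they
have closed form and need no eigendecomposition; with five tapers their
effective spectral concentration matches the usual time-bandwidth-3
Slepian configuration for band-integrated work.

For **pre/post band-power comparisons** (`band_power_change`, 30-s
segments after each stimulation block vs 30 s before the first), the
per-taper jackknife must *not* be used for significance: per-taper band
powers share the segment's realized in-band energy, so their scatter
understates the between-segment variance — measured type-I error of a
taper-jackknife t-test on white-noise nulls was ≈40% at α = 5%. Each
band-integrated power is instead treated as a scaled χ² with
$2\,bw\,T$ degrees of freedom (the independent spectral components a
segment of duration $T$ contributes to a band of width $bw$), giving an
F-test on the power ratio. The theoretical null SD of the log ratio,
$\sqrt{2/(bw\,T)}$, matches simulation to a few percent.

### Time-frequency responses

`time_frequency_response` uses fixed 6-cycle Morlet wavelets over
5–25 Hz, expresses power in dB relative to the mean baseline power per
frequency, and compares conditions with a per-pixel one-tailed paired
t-test masked by BH-FDR. Epochs shorter than the wavelet support are
zero-padded symmetrically; edge bias stays in the pads.

## Event detection

**Spindles**: instantaneous band power (squared Morlet amplitude); upper
threshold 6× the median power; onset/offset extended to where power falls
below mean + 1 SD (the "absolute 1 SD" reading is a documented variant);
duration gate 0.2–2 s. The movement-artifact screen excludes events whose
maximum *broadband* power exceeds the 90th percentile of 1-s
window maxima over the whole recording. Broadband power is computed from
the signal with the spindle band excised entirely (brick-wall mask,
1–45 Hz minus [fc−bw, fc+bw]): a duration-respecting spindle contributes
no sideband energy and cannot trip its own screen, while broadband
artifacts do. The screen also backstops the duration gate: under the
(14, 7) Morlet (σ_t = 54 ms) even an instantaneous transient smears into
a ≈0.25-s power bump, so threshold durations alone cannot reject a strong
sub-0.2-s burst — but such bursts are spectrally wide by the uncertainty
principle (a 0.1-s burst spans ±15 Hz) and light up the sidebands. Note
the percentile construction implies ~10% of genuine events falling in
top-decile background windows are discarded — the accepted cost of the
published rule. Two
earlier formulations were rejected: comparing event maxima against
*instantaneous* power percentiles discards every event (a max over ~500
samples almost always exceeds a pointwise 90th percentile), and
subtracting the Morlet in-band component leaks ~15% of a strong spindle
(Gaussian response < 1 across the passband). The event "peak time" used
for phase preference is the time of maximum band power within the event.

**Slow waves**: the trace is filtered at (0.75, 0.75) Hz; two subsequent
negative-going zero crossings separated by 0.5–2 s delimit an event; the
down-state is the minimum filtered voltage within it. The bare crossing
rule accepts arbitrarily small slow-band fluctuations, so an optional
down-state amplitude floor (`min_down_uV`) is provided for recordings with
background activity; the default keeps the literal rule.

**Event-rate comparison**: stimulus-locked event-count histograms are
compared to baseline counts scaled to the same total, χ² with
dof = bins − 1.

## Field projection

The stimulation voltage at each electrode is the amplitude of a
least-squares sinusoid at the stimulation frequency (phase free); channels
with >1% of samples within 0.1% of the recording extremes are flagged as
saturated. The projected field pairs each electrode with its closest
same-array neighbor within 10 mm (grid/strip) or 5 mm (depth), using
Euclidean distance on the 3-D coordinates, and reports |ΔV|/distance in
V/m normalized to 1 mA. Magnitude fitting loses the voltage sign, so each
electrode's fitted phase restores it (within 90° of the stimulation
reference → positive); anti-phase neighbors therefore produce summed
differences. Because only the component along the pair axis is captured,
projected values are a lower bound on the true field magnitude — verified
as an invariant against synthetic 3-D gradients.

## The synthetic generator

`generate_sleep_recording` emulates exactly the features the analysis
depends on:

* **Slow oscillations as unitary events**: Hann-windowed sinusoid snippets
  of 1–2 cycles (a regular rhythm never persists longer), frequency drawn
  log-uniformly over 0.5–4 Hz, exponential inter-event gaps at 30
  events/min by default, ~200 µV peak (the 50 µV analysis floor must be
  exercisable from both sides). The resulting spectrum is broadband over
  0.5–4 Hz with no narrow peak — a tested invariant.
* **Coupling**: spindle and gamma carriers are narrowband Gaussian noise
  whose envelope is multiplied by $1 + d\cos(\phi_{SO} - \phi_0)$, where
  $\phi_{SO}$ is the Morlet phase of the clean slow-oscillation trace at
  the analysis band. The multiplicative form gives the closed-form
  $r/\bar A = d/2$ oracle. A "bursts" mode gates the carrier with discrete
  0.5–1.5 s Hann bursts and records their intervals for detector
  round-trips.
* **Background**: 1/f Gaussian noise (exponent 1, 15 µV RMS by default);
  endogenous spindle carrier 20 µV RMS, gamma 5 µV RMS. The spindle burst
  rate is deliberately a free parameter — no reliable per-channel value is
  established.
* **Artifacts**: `inject_tacs_artifact` adds a sinusoid plus harmonic
  terms (>10× neural RMS in typical use), optionally with multiplicative
  amplitude drift; `inject_outlier_epochs` multiplies broadband power by a
  gain inside given intervals (movement surrogates); acoustic trigger
  trains are exact at jitter 0.
* **Determinism**: one RNG stream per generation call, seeded from the
  config, with per-channel sub-streams derived deterministically —
  identical seeds give bit-identical recordings.

What it does **not** emulate — and what passing tests therefore do not
establish about real data: epileptiform discharges, amplifier saturation
waveform shape, volume conduction between channels, non-stationary sleep
depth, or realistic spindle morphology beyond a modulated narrowband
envelope.

## Problem sizes and numerical choices

Validation runs use 600-s single-block recordings (≈300 usable endogenous
cycles after screening, matching a 5-min stimulation block's cycle count
at 1 Hz), 3 channels at coupling depths {0, 0.5, 1}, 20 generator seeds,
2,000 surrogate shuffles for recovery runs and 10,000 wherever the p-value
floor itself is the quantity of interest. Type-I calibration uses 200
simulated null electrodes of 300 cycles; FDR-under-null uses 50
simulations × 40 electrodes. With these sizes, end-to-end sensitivity at
depth ≥ 0.5 exceeds 0.9 and mean preferred-phase error stays under 10°.

Tie-breaks and degenerate inputs: equal cycle powers reject nothing (the
outlier rule uses a strict inequality, so IQR = 0 is a no-op); a
single-cycle surrogate test returns p = 1 (|z| is rotation invariant, and
the surrogate comparison uses a 10⁻¹⁰ relative tolerance so exact ties do
not fall to floating-point round-off); an amplitude floor of 0 flags
nothing; empty FDR input returns an empty mask; a zero fundamental refuses
to serve as a phase reference.

## Known limitations

* The half-circle surrogate default is conservative under the null (see
  above); switch to `shift_range_deg = 360` when calibrated type-I error
  matters more than procedural fidelity.
* Endogenous cycle counts depend on the per-channel Morlet phase, so
  cycles are not aligned across electrodes; the shared-shuffle structure
  is preserved by cycle index, not by wall-clock time.
* The harmonic model assumes a stationary artifact within a block;
  non-stationary blocks are flagged and excluded rather than fit
  adaptively.
* Field projections bound the true field from below; no head modeling is
  attempted.
* Recordings and results serialize to plain text (TSV/JSON); no EDF or
  HDF5 I/O is provided.
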