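---
title: "Analyzing striatal sound responses and cloud-of-tones behavior with striatune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing striatal sound responses and cloud-of-tones behavior with striatune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatune)
library(dplyr)
```

## The scientific problem

The posterior ("auditory") striatum receives convergent glutamatergic input
from the auditory thalamus (medial geniculate body, MGB) and from primary
auditory cortex (ACx), and striatal activity drives choices in auditory
discrimination tasks. A central question is what each input contributes to
the striatal representation of sound: a *gain* signal that scales responses
across frequencies, or *tuning* information concentrated at a neuron's
preferred frequency. striatune implements the complete analysis chain used
to answer that question with extracellular tetrode recordings and a
two-alternative forced-choice (2AFC) "cloud-of-tones" task:

1. **Unit classification** — striatal single units are assigned to medium
   spiny neurons (MSN), fast-spiking (FS) or cholinergic (ChI) interneurons
   from the spike waveform's half-valley width.
2. **Response detection** — tone-evoked response windows are found in
   peristimulus time histograms (PSTHs) against baseline statistics and
   classified as onset, sustained, offset or suppression responses.
3. **Frequency tuning** — per-unit tuning curves, best frequency, half-peak
   tuning width, and a Gaussian receptive-field fit.
4. **Silencing decomposition** — the effect of optogenetically silencing one
   input pathway is decomposed into a subtractive offset and a divisive gain,
   and tested at the best frequency versus the half-octave "shoulders".
5. **Behavior** — logistic psychometric fits and session metrics for the
   cloud-of-tones task, compared across saline/CNO sessions.

Because no public dataset accompanies this analysis, the package ships a
first-class synthetic-data generator (`simulate_recording()`,
`simulate_behavior()`) that emulates the statistical structure the analysis
assumes; every quantitative claim the test suite makes is a property of the
method evaluated on that generator.

## The cloud-of-tones stimulus and evidence strength

A trial's stimulus is a stream of 30-ms pure tones presented at 100 Hz
(overlapping), each drawn from an 18-frequency grid spaced uniformly in
log2 from 5 to 40 kHz — six grid frequencies per octave, three octaves. The
low octave (5–10 kHz) and high octave (20–40 kHz) are the two targets; the
middle octave is uninformative. With stimulus strength $r \in [0, 100]$
(percent), each tone falls in the target octave with probability

$$p_{target} = \frac{1 + 2r/100}{3},$$

otherwise uniformly in one of the two other octaves. We read the printed
formula "1 + 2r/100/3" with this parenthesization because it is the only
reading bounded in $[1/3, 1]$: at $r = 0$ each of the three octaves is
equally likely (chance), and at $r = 100$ every tone is a target-octave tone.
Tone onsets sit on the regular 10-ms grid implied by "presented at 100 Hz";
a Poisson process would not produce a fixed 100-Hz rate with fixed 30-ms
tones. In vivo the stream stops at withdrawal; `generate_tone_cloud()` takes
an explicit duration instead.

The per-trial evidence statistic is

$$\mathrm{evidence} = \frac{\#\mathrm{high} - \#\mathrm{low}}
                           {\#\mathrm{high} + \#\mathrm{low}},$$

with middle-octave tones in neither term; ±1 is full evidence, 0 none. It is
antisymmetric under swapping the octaves and undefined (an error) when no
tone falls in either band.

```{r evidence}
stim <- generate_tone_cloud(r = 100, target = "high", duration_s = 0.3, seed = 1)
nrow(stim)
evidence_strength(stim)
```

## Psychometric model

Choice behavior is modeled by a two-parameter logistic,
$\log(p / (1-p)) = \beta_0 + r\,\beta_1$, where $p$ is the probability of
choosing the port associated with high frequencies. `fit_psychometric()`
maximizes the Bernoulli likelihood on trial-level data (not least squares on
binned accuracies) using completed trials only. No lapse parameter is
included — the model in use has none — but `simulate_behavior()` can inject
lapses to probe robustness. Perfect separation is detected three ways
(glm warnings, numerically zero residual deviance, runaway coefficients) and
reported as non-convergence with capped estimates rather than silently
returned. Session metrics bin accuracy by the nominal strength $r$ by
default (`by = "evidence"` switches to realized evidence); the
reaction-time summary per level is the **median**, a choice we make because
reaction-time distributions are right-skewed. Saline/CNO comparisons use the
paired t test (`compare_sessions()`), with the degenerate zero-variance case
handled explicitly: all-zero differences give $t = 0, p = 1$; constant
nonzero differences give an infinite statistic and $p = 0$, with a warning.

## Unit classification

The half-valley width is the duration of the spike trough at half its depth.
The trough is the waveform's global minimum; depth is measured from the
pre-trough baseline, defined as the mean of all samples preceding the onset
of the descent into the trough (the conventional width definition leaves the
reference level open; a pre-trough mean is robust to slow drifts).
Half-depth crossings are located by linear interpolation between samples —
at 32-kHz acquisition a raw sample is ~31 µs, too coarse for thresholds at
100 and 150 µs. Classes: FS below 100 µs (strict), ChI above 150 µs
(strict), MSN in the inclusive interval [100, 150] µs, so every positive
width receives exactly one label.

## PSTH and response windows

`compute_psth()` slides a 3-ms window in 1-ms steps from 100 ms before tone
onset to 200 ms after tone end; the rate in a window is the pooled spike
count divided by (trials × width). Bins are indexed by the window **start**
time, which makes "the first time point of the response window" — the
latency — well defined. Baseline statistics use only windows lying entirely
within the 50-to-0-ms pre-onset span, so no post-onset spikes leak into the
baseline.

A response window is the earliest contiguous run of bins, starting at or
after tone onset and within 200 ms of tone end, in which the rate exceeds
mean + 3 SD of baseline; if no excitatory run exists, a suppressive run
below mean − 2 SD is sought. Runs separated by even one sub-threshold bin
are distinct, and only the earliest is the response window — any other
reading would break the latency definition. Classes follow the timing
rules: excitatory windows ending before 50 ms are *onset*, ending at or
after 50 ms are *sustained*; windows starting at or after tone end and
strictly within 20 ms of it are *offset* (start time takes precedence when
the rules collide for long tones); any suppressive window is *suppression*.

Two numerical guards matter in practice:

* **SD floor** (0.1 Hz): a silent baseline has SD 0 and would otherwise make
  any spike a "response".
* **Minimum run length** (`pipeline_config(min_run = 4)`): with a 3-ms
  window stepped by 1 ms, one chance spike cluster elevates three
  consecutive bins; requiring a run longer than one window width removes
  such single-event artifacts. The primitive `detect_response_window()`
  keeps `min_run = 1` (the rule verbatim); the pipeline default is 4. Both
  are configurable.

Response windows are always determined on control (light-off) trials and
then applied unchanged to light-on trials.

## Tuning curves, width, and the Gaussian fit

Most striatal units do not respond below 60 dB SPL, so analysis uses the
*lower responsive intensity* of 60 or 70 dB (never 50). The tuning curve is
the per-frequency mean firing rate inside the control response window minus
the unit's pooled baseline rate — one scalar baseline per unit, not per
frequency, which keeps baseline estimation error out of the per-point noise
and inside the fitted baseline term where it belongs. Best frequency is the
argmax (ties to the lowest frequency). The tuning width is the half-peak
range of the Savitzky–Golay-smoothed curve (span 5; we use polynomial order
2, the conventional choice the span alone does not determine), measured in
octaves with linear interpolation on the log2-frequency axis; a side that
never falls below half peak is truncated at the grid edge and flagged.

The receptive-field model is

$$R(f) = A \exp\left(-\tfrac{1}{2}\,\frac{(x - f_0)^2}{\sigma^2}\right) + B,
\qquad x = \log_2 f,$$

fit by bounded Levenberg–Marquardt least squares with multi-start over
$\sigma \in \{0.25, 0.5, 1, 2\}$ octaves, initialization $A = \max - \min$,
$B = \min$, $f_0 = \arg\max$, and bounds $A \ge 0$,
$\sigma \in (0.05, 5]$. Fitting in log2 frequency makes $\sigma$ an octave
width, consistent with every octave-scaled comparison. $R^2 = 1 -
SS_{res}/SS_{tot}$ is computed on the raw (unsmoothed) curve — smoothing is
documented only for the width — and a unit counts as *tuned* when
$R^2 > 0.4$.

## Silencing analysis: offset, gain, and shoulders

For population displays, each unit's control and light-on curves are
re-indexed in octaves from that condition's own best frequency and both are
normalized by the unit's control rate at the control best frequency
(`align_and_normalize()`); the control population curve is 1.0 at offset 0
by construction. `shoulder_rates()` averages the normalized rate at +1/2 and
−1/2 octave per unit and condition and applies a paired t test.

The transform model says silencing maps the control curve to the light
curve by a subtractive offset and a divisive gain with unchanged shape:

$$R_{light}(f) = \frac{R_{control}(f) - \mathrm{offset}}{\mathrm{scale}},
\qquad f_0, \sigma \text{ shared}.$$

Given two Gaussian fits the closed form is
$\mathrm{scale} = A_c / A_l$ and
$\mathrm{offset} = B_c - \mathrm{scale}\,B_l$ (`decompose_gain()`), and
applying a transform and decomposing recovers it exactly
(`apply_transform()` round-trip). Because the model itself asserts shared
$f_0$ and $\sigma$, the pipeline estimates the per-unit transform from a
**joint fit with shared shape** (`fit_gaussian_shared()`): given the shape,
the per-condition amplitudes are linear coefficients, which avoids the
low-SNR inflation a free-shape fit gives the weak silenced curve (we
measured ~5% amplitude inflation at $A \approx 20$ Hz with realistic noise,
which attenuates the recovered scale correspondingly). Free per-condition
fits remain available and are what the fits table reports; a joint
least-squares regression of one curve on the other
(`decompose_gain(method = "joint")`) is the fallback when shapes genuinely
differ. The population transform is summarized as mean ± SEM across units,
with the offset expressed as a fraction of the control fitted peak.

## The synthetic generator

`simulate_recording()` emulates the recording protocol: pure tones at
0.5 Hz in random order, intensities of 50, 60 and 70 dB SPL, light on in a
random half of trials with the light epoch spanning 100 ms before tone
onset to 100 ms after tone end. Spike trains are inhomogeneous Poisson,
$\lambda(t, f) = \mathrm{baseline} + \mathrm{kernel}(t) \cdot T(f)$, drawn
as per-1-ms-bin Poisson counts with uniform placement (exact for the
piecewise-constant rate), with an optional absolute refractory period
(default 1 ms). Waveforms are Gaussian troughs whose FWHM equals the target
half-valley width, with a small after-wave kept six trough-SDs away so it
cannot bias the half-depth crossings. Default population composition is
~80/13/7% MSN/FS/ChI, the proportions typical of striatal tetrode datasets.

Pathway-silencing models act on the evoked tuning $T(f)$ during the light
epoch:

* **divisive(scale, offset)** — the thalamic gain-controller model:
  $T_{light} = (T - \mathrm{offset} \cdot P)/\mathrm{scale}$ with $P$ the
  control peak, so the offset is in normalized (fraction-of-peak) units.
* **peak_subtractive(depth)** — the cortical tuned-input model. The control
  receptive field is the sum of a broad Gaussian ($\sigma$ from the unit's
  tuning) and a narrow one (0.15 octaves, half the amplitude) at the same
  preferred frequency; light removes a fraction `depth` of the narrow
  component. Modeling the *removal of a tuned input component* — rather
  than subtracting a free-standing dip — keeps the best frequency stable at
  any depth and leaves the ±1/2-octave shoulders nearly untouched, which is
  the defining signature of this pathway.
* **abolition** — both inputs silenced: evoked response removed.

`silencing_population_spec()` freezes the study conditions used in the
recovery experiments: 25 sustained-response MSN-like units, evoked
amplitudes 40–80 Hz over 2–6 Hz baselines, tuning $\sigma$ 0.4–0.8 octaves,
20 trials per frequency and condition at 60 dB, and `refractory_s = 0`.
The last choice deserves a note: a 1-ms refractory period deletes ~9% of
spikes at a 90-Hz control peak but only ~3% at the silenced rate, so the
*measured* gain is compressed by several percent relative to the rate-level
generating truth. Recovery experiments compare estimates against that
rate-level truth, so they disable the refractory distortion; everything
else keeps the 1-ms default.

Recording frequency grids default to quarter-octave spacing over 2–45 kHz
(19 frequencies spanning the 2–50 kHz testing band), which places the
±1/2-octave shoulder offsets exactly on the grid.

### What the generator does and does not emulate

It reproduces Poisson spiking with the four response taxonomies, Gaussian
(and two-component) frequency tuning, intensity thresholds, interleaved
light trials, waveform width classes, and logistic choice behavior with
non-reported trials. It does **not** model bursting or other non-Poisson
spike statistics, rate adaptation across a session, spike-sorting errors,
correlated noise across units or trials, intensity tuning beyond a
threshold, or any local-circuit interaction among MSN/FS/ChI. Passing tests
therefore certify the analysis chain under the stated statistical
assumptions, not the biology of any particular recording.

## Problem sizes and numerical choices

The test suite runs at desk scale, chosen as the smallest sizes at which
the estimators' sampling noise is clearly below the assertion margins:
1,000 randomized PSTHs for the detection oracle; 200 units at 20 trials per
frequency for Gaussian-fit recovery (median relative errors ~7% for $A$ and
$\sigma$, ~1% for $f_0$; the evoked-baseline $B$, a 2–6 Hz quantity
estimated from curve tails, is intrinsically noisier at these counts);
three divisive populations spanning scale 1.2–3.0 and offset 0–0.05 plus
one peak-subtractive population, 25 units each; 10,000 trials for
psychometric recovery. Degenerate inputs are handled explicitly throughout:
empty sessions, silent baselines, monotone waveforms, flat curves, zero
evidence denominators, non-positive control peaks, and zero-variance paired
differences each raise a classed error, a flag, or a documented fallback
rather than propagating NaNs.

## Known limitations

* The detection rule tests each PSTH bin marginally; with ~300 bins a
  3-SD rule has a nontrivial family-wise false-positive rate on truly
  unresponsive units. That is a property of the method being implemented;
  the `min_run` guard reduces but does not remove it.
* The closed-form decomposition requires both conditions to be tuned
  ($R^2 > 0.4$) and a positive silenced amplitude; near-abolition effects
  should be analyzed with the population curves, not the transform.
* Tuning widths on sparsely sampled, sharply tuned units are
  interpolation-limited; widths close to the grid spacing should be read
  with that in mind.
* The behavioral model has no lapse term, so at very large $|r|$ real
  lapses bias the slope downward slightly; the generator can produce
  lapses to quantify this.
```
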