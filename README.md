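# striatune

Analysis of auditory-striatum single-unit recordings and "cloud-of-tones"
2AFC behavior, with a seeded synthetic-data generator for end-to-end
validation.

## What it does, and for whom

The posterior (auditory) striatum receives convergent input from the
auditory thalamus (MGB) and primary auditory cortex (ACx). For a systems
neuroscientist asking what each pathway contributes to striatal sound
representations — broadband *gain* or frequency *tuning* — striatune
implements the full analysis chain:

- **Cell-type classification** from the spike waveform half-valley width:
  FS < 100 µs, MSN in [100, 150] µs, ChI > 150 µs, with sub-sample linear
  interpolation of the half-depth crossings.
- **Tone-response detection**: 3-ms sliding-window PSTHs (−100 ms to tone
  end + 200 ms), baseline statistics from the −50–0 ms span, response
  windows where the PSTH leaves mean ± (3 SD excitatory / 2 SD suppressive)
  of baseline, and the onset / sustained / offset / suppression taxonomy.
  Latency is the window's first time point.
- **Frequency tuning**: baseline-subtracted tuning curves at the lower
  responsive intensity of 60/70 dB SPL, best frequency, half-peak tuning
  width in octaves (Savitzky–Golay span 5 smoothing), and a Gaussian
  receptive-field fit on the log2-frequency axis

      R(f) = A · exp(−0.5 (x − f0)² / σ²) + B,  x = log2 f,

  with inclusion criterion R² > 0.4.
- **Pathway-silencing decomposition**: per-unit transform of control into
  light-on tuning, R_light(f) = (R_control(f) − offset) / scale, recovered
  in closed form from Gaussian fits with shared f0/σ; population alignment
  to per-condition best frequencies, normalization to the control peak, and
  the paired peak-versus-±½-octave-shoulder test that separates a gain
  controller from a tuned input.
- **Behavior**: trial-level Bernoulli-likelihood fit of the psychometric
  model log(p/(1−p)) = β0 + r·β1, session metrics (completed/non-reported
  counts, accuracy and median reaction time per strength), and paired
  saline/CNO comparisons.
- **Synthetic data**: inhomogeneous-Poisson spike trains with onset /
  sustained / offset / suppression kernels and Gaussian tuning, parametric
  waveforms with controlled half-valley widths, logistic choice behavior,
  and divisive / peak-subtractive / abolition silencing models.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` on PSTHs, fits and
populations.

## Worked example

Simulate a 10-unit population whose thalamic input is silenced on light
trials with a divisive gain of 1.8 and a 0.01 (fraction-of-peak) offset,
then run the full pipeline:

```r
library(striatune)

rec <- simulate_recording(
  silencing_population_spec(list(type = "divisive", scale = 1.8, offset = 0.01),
                            seed = 42, n_units = 10))
res <- run_pipeline(rec)
res
#> striatune pipeline result
#>   units: 10 ( 10 tone-responsive )
#>   ...
#>   population transform: scale 1.83 +/- 0.04, offset -0.010 +/- 0.011 (n = 10)

res$shoulders$test
#> # A tibble: 1 × 5
#>       n mean_diff     t    df    p_value
#>   <int>     <dbl> <dbl> <dbl>      <dbl>
#> 1    10     0.274  9.38     9 0.00000609
```

The recovered population transform (scale 1.83 ± 0.04, offset −0.010 ±
0.011, mean ± SEM) matches the generating divisive model, and the
half-octave shoulder rates drop significantly along with the peak — the
signature of a gain controller. A tuned-input (peak-subtractive) generator
instead produces a significant peak reduction with statistically unchanged
shoulders.

Behavior:

```r
trials <- simulate_behavior(beta0 = 0.1, beta1 = 0.05, n_trials = 5000, seed = 42)
fit_psychometric(trials)
#> Logistic psychometric fit (4730 completed trials)
#>   beta0 (bias)  =   0.1764
#>   beta1 (slope) =   0.0506 per % r
```

The slope is recovered at 0.0506 per percent of stimulus strength
(generating value 0.05); accuracy in `session_metrics(trials)` rises from
~0.6 at |r| = 10 to ~0.99 at |r| = 100.

A thin command-line wrapper over the same functions lives at
`inst/cli/striatune.R` (`simulate`, `run`, `behave` subcommands).

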