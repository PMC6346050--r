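#' Specification of one synthetic single unit
#'
#' Bundles the generative parameters of a synthetic striatal unit: a target
#' waveform width (hence cell class), a baseline firing rate, a Gaussian
#' frequency tuning profile, a tone-response kernel of one of the four
#' observed classes, and an optional light-trial modulation model.
#'
#' Modulation models act on the evoked tuning profile `T(f)` during the
#' light epoch:
#' * `divisive(scale, offset)` — `T_light(f) = (T(f) - offset * P) / scale`
#'   where `P = A + B` is the control peak, so `offset` is expressed as a
#'   fraction of the peak (the thalamic gain-controller model);
#' * `peak_subtractive(depth, half_width_oct, narrow_frac)` — the control
#'   receptive field is the sum of a broad Gaussian (`sigma` from `tuning`)
#'   and a narrow Gaussian of SD `half_width_oct` (default 0.15 octaves)
#'   carrying a fraction `narrow_frac` (default 0.5) of the amplitude, both
#'   centered at `f0`; light removes a fraction `depth` of the narrow
#'   component only (the cortical tuned-input model: the peak drops, the
#'   best frequency and the half-octave shoulders barely change);
#' * `abolition` — evoked response removed entirely on light trials;
#' * `none`.
#'
#' @param unit_id Unit identifier.
#' @param waveform_width_us Target half-valley width, microseconds.
#' @param baseline_rate_hz Spontaneous rate, Hz.
#' @param tuning Named numeric vector `c(A=, f0=, sigma=, B=)`: amplitude
#'   (Hz), preferred frequency (log2 kHz), width (octaves), evoked baseline
#'   (Hz).
#' @param response_kernel One of `"onset"`, `"sustained"`, `"offset"`,
#'   `"suppression"`.
#' @param latency_s Kernel latency after tone onset (after tone end for
#'   offset kernels), seconds.
#' @param kernel_duration_s Kernel duration, seconds (`NA` = defaults per
#'   kernel type).
#' @param suppression_depth For suppression kernels: fraction of the baseline
#'   removed during the tone.
#' @param min_intensity_db Lowest intensity (dB SPL) at which the unit
#'   responds; no evoked response below it.
#' @param modulation A list like `list(type = "divisive", scale = 1.8,
#'   offset = 0.01)`, `list(type = "peak_subtractive", depth = 0.5,
#'   half_width_oct = 0.25)`, `list(type = "abolition")`, or
#'   `list(type = "none")`.
#' @return A list of class `unit_spec`.
#' @export
unit_spec <- function(unit_id = 1L,
                      waveform_width_us = 120,
                      baseline_rate_hz = 4,
                      tuning = c(A = 40, f0 = log2(10), sigma = 0.6, B = 1),
                      response_kernel = c("onset", "sustained", "offset", "suppression"),
                      latency_s = 0.015,
                      kernel_duration_s = NA_real_,
                      suppression_depth = 0.8,
                      min_intensity_db = 60,
                      modulation = list(type = "none")) {
  response_kernel <- match.arg(response_kernel)
  stopifnot(all(c("A", "f0", "sigma", "B") %in% names(tuning)),
            tuning["sigma"] > 0, baseline_rate_hz >= 0)
  if (is.na(kernel_duration_s)) {
    kernel_duration_s <- switch(response_kernel,
                                onset = 0.020, sustained = 0.085,
                                offset = 0.015, suppression = NA_real_)
  }
  structure(list(unit_id = unit_id,
                 waveform_width_us = waveform_width_us,
                 baseline_rate_hz = baseline_rate_hz,
                 tuning = tuning,
                 response_kernel = response_kernel,
                 latency_s = latency_s,
                 kernel_duration_s = kernel_duration_s,
                 suppression_depth = suppression_depth,
                 min_intensity_db = min_intensity_db,
                 modulation = modulation),
            class = "unit_spec")
}

# Evoked tuning value T(f) in Hz under a condition, given the modulation
# model. For peak_subtractive units the control receptive field is itself the
# sum of a broad component (sigma from the tuning spec, the gain-controlled
# thalamic input) and a narrow component centered at the same preferred
# frequency (the tuned cortical input); silencing removes a fraction `depth`
# of the narrow component only, so the best frequency is stable at any depth
# and the half-octave shoulders are nearly untouched.
evoked_tuning <- function(spec, freq_khz, light_on) {
  tn <- spec$tuning
  x <- log2(freq_khz)
  g <- function(sig) exp(-0.5 * (x - tn[["f0"]])^2 / sig^2)
  mod <- spec$modulation

  if (identical(mod$type, "peak_subtractive")) {
    nf <- mod$narrow_frac %||% 0.5
    sn <- mod$half_width_oct %||% 0.15
    keep <- if (light_on) 1 - mod$depth else 1
    return(tn[["A"]] * ((1 - nf) * g(tn[["sigma"]]) + keep * nf * g(sn)) + tn[["B"]])
  }

  T_c <- tn[["A"]] * g(tn[["sigma"]]) + tn[["B"]]
  if (!light_on || identical(mod$type, "none")) return(T_c)
  P <- tn[["A"]] + tn[["B"]]
  switch(mod$type,
         divisive = (T_c - mod$offset * P) / mod$scale,
         abolition = 0,
         abort(sprintf("unknown modulation type '%s'.", mod$type),
               class = "striatune_invalid_parameter"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate spike times of one unit over a set of tone trials
#'
#' Generates an inhomogeneous Poisson spike train with instantaneous rate
#' `lambda(t, f) = baseline + kernel(t) * T(f)`, where `kernel(t)` is the
#' unit's response kernel (rectangular, by class) and `T(f)` its Gaussian
#' tuning evaluated at the trial frequency (zero below the unit's minimum
#' responsive intensity). On light trials the modulation model is applied
#' over the light epoch (100 ms before tone onset to 100 ms after tone end).
#' Negative instantaneous rates are rectified at zero.
#'
#' Spikes are drawn per 1-ms bin (Poisson counts, uniform placement within
#' the bin — exact for the piecewise-constant rate) and an absolute
#' refractory period is then enforced.
#'
#' @param spec A [unit_spec()].
#' @param trials Data frame of tone trials: `trial_id`, `onset_s`,
#'   `freq_khz`, `intensity_db`, `duration_s`, `light_on` (logical).
#' @param seed Optional integer seed.
#' @param bin_s Simulation bin width, seconds.
#' @param refractory_s Absolute refractory period, seconds (default 1 ms;
#'   0 disables).
#' @param pad_s Simulated span before onset and after tone end, seconds.
#' @return Tibble with columns `unit_id`, `spike_time_s` (sorted).
#' @export
simulate_unit_trials <- function(spec, trials, seed = NULL, bin_s = 0.001,
                                 refractory_s = 0.001, pad_s = 0.150) {
  stopifnot(inherits(spec, "unit_spec"),
            all(c("onset_s", "freq_khz", "intensity_db", "duration_s", "light_on")
                %in% names(trials)))
  if (!is.null(seed)) set.seed(seed)
  dur <- unique(trials$duration_s)
  stopifnot(length(dur) == 1L)  # one tone duration per simulated block
  t_rel <- seq(-pad_s, dur + pad_s + 0.25, by = bin_s)
  nb <- length(t_rel) - 1L
  mids <- t_rel[-length(t_rel)] + bin_s / 2

  k_on <- spec$latency_s
  kernel <- switch(spec$response_kernel,
    onset = as.numeric(mids >= k_on & mids < k_on + spec$kernel_duration_s),
    sustained = as.numeric(mids >= k_on & mids < k_on + spec$kernel_duration_s),
    offset = as.numeric(mids >= dur + k_on & mids < dur + k_on + spec$kernel_duration_s),
    suppression = rep(0, nb))
  suppress_mask <- if (spec$response_kernel == "suppression") {
    as.numeric(mids >= 0.005 & mids < dur + 0.02)
  } else rep(0, nb)
  light_mask <- mids >= -0.100 & mids < dur + 0.100

  onset_v <- trials$onset_s
  freq_v <- trials$freq_khz
  light_v <- as.logical(trials$light_on)
  resp_v <- trials$intensity_db >= spec$min_intensity_db
  bin_starts <- t_rel[-length(t_rel)]

  spikes <- vector("list", length(onset_v))
  for (i in seq_along(onset_v)) {
    responsive <- resp_v[i]
    Tf_ctrl <- if (responsive) evoked_tuning(spec, freq_v[i], FALSE) else 0
    Tf <- if (light_v[i] && responsive) {
      Tf_mod <- evoked_tuning(spec, freq_v[i], TRUE)
      ifelse(light_mask, Tf_mod, Tf_ctrl)
    } else rep(Tf_ctrl, nb)
    lambda <- spec$baseline_rate_hz * (1 - spec$suppression_depth * suppress_mask *
                                         (if (responsive) 1 else 0)) +
      kernel * Tf
    lambda <- pmax(lambda, 0)
    counts <- rpois(nb, lambda * bin_s)
    tot <- sum(counts)
    if (tot == 0L) next
    st <- rep(bin_starts[counts > 0], counts[counts > 0]) + runif(tot, 0, bin_s)
    st <- sort(st)
    if (refractory_s > 0 && length(st) > 1L) {
      keep <- c(TRUE, diff(st) >= refractory_s)
      # iterate: deletions can expose new violations
      while (!all(keep)) {
        st <- st[keep]
        keep <- c(TRUE, diff(st) >= refractory_s)
      }
    }
    spikes[[i]] <- st + onset_v[i]
  }
  tibble::tibble(unit_id = spec$unit_id,
                 spike_time_s = sort(unlist(spikes, use.names = FALSE)))
}

#' Simulate a mean spike waveform with a target half-valley width
#'
#' Builds a biphasic extracellular-like waveform whose trough is Gaussian
#' with standard deviation `width_us / (2 * sqrt(2 * log(2)))`, so its
#' measured half-valley width is `width_us` to within one sample period of
#' linear-interpolation error, plus a smaller slow positive after-wave and
#' optional additive noise.
#'
#' @param width_us Target half-valley width, microseconds.
#' @param sample_rate_hz Sampling rate (default 32 kHz, typical for tetrode
#'   acquisition).
#' @param seed Optional integer seed (used only when `noise_uv > 0`).
#' @param trough_uv Trough depth, microvolts.
#' @param noise_uv SD of additive Gaussian noise, microvolts.
#' @param span_s Total waveform span, seconds.
#' @return Numeric vector of amplitudes (microvolts).
#' @export
simulate_waveform <- function(width_us, sample_rate_hz = 32000, seed = NULL,
                              trough_uv = 80, noise_uv = 0.5, span_s = 0.0015) {
  stopifnot(width_us > 0)
  if (!is.null(seed)) set.seed(seed)
  sigma_s <- width_us * 1e-6 / (2 * sqrt(2 * log(2)))
  t <- seq(0, span_s, by = 1 / sample_rate_hz)
  t0 <- span_s * 0.4
  # after-wave kept 6 sigma out so it does not bias the half-depth crossings
  wf <- -trough_uv * exp(-0.5 * ((t - t0) / sigma_s)^2) +
    0.25 * trough_uv * exp(-0.5 * ((t - t0 - 6 * sigma_s) / (2 * sigma_s))^2)
  if (noise_uv > 0) wf <- wf + rnorm(length(wf), 0, noise_uv)
  wf
}

#' Simulate a behavioral session from the logistic psychometric model
#'
#' Choices are Bernoulli with `log(p / (1 - p)) = beta0 + r * beta1`, where
#' `p` is the probability of choosing the high-frequency port. Non-reported
#' trials (no side-port choice) occur with probability `nonreport_p`;
#' reaction times of reported trials are log-normal. An optional lapse rate
#' mixes in random choices to test fit robustness (the fitted model itself
#' stays two-parameter).
#'
#' @param beta0 Bias (log-odds intercept).
#' @param beta1 Slope per percent of stimulus strength.
#' @param r_levels Nominal signed strengths sampled uniformly per trial.
#' @param n_trials Number of trials.
#' @param nonreport_p Probability a trial ends without a side-port choice.
#' @param lapse Probability of a uniformly random choice (default 0).
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters.
#' @param high_port Side associated with high frequencies.
#' @param seed Optional integer seed.
#' @return Tibble with columns `trial_id`, `r`, `evidence`, `choice`,
#'   `correct`, `reaction_time_s`, `reported`.
#' @export
simulate_behavior <- function(beta0 = 0, beta1 = 0.05,
                              r_levels = c(-100, -50, -25, -10, 10, 25, 50, 100),
                              n_trials = 300, nonreport_p = 0.05, lapse = 0,
                              rt_meanlog = log(0.35), rt_sdlog = 0.25,
                              high_port = "right", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  low_port <- setdiff(c("left", "right"), high_port)
  r <- sample(r_levels, n_trials, replace = TRUE)
  p_high <- plogis(beta0 + beta1 * r)
  choose_high <- runif(n_trials) < p_high
  lapsed <- runif(n_trials) < lapse
  choose_high[lapsed] <- runif(sum(lapsed)) < 0.5
  choice <- ifelse(choose_high, high_port, low_port)
  reported <- runif(n_trials) >= nonreport_p
  choice[!reported] <- "none"
  correct <- (r > 0 & choice == high_port) | (r < 0 & choice == low_port)
  rt <- rlnorm(n_trials, rt_meanlog, rt_sdlog)
  rt[!reported] <- NA_real_
  tibble::tibble(trial_id = seq_len(n_trials), r = r,
                 evidence = r / 100, choice = choice,
                 correct = correct & reported,
                 reaction_time_s = rt, reported = reported)
}

#' Specification of a synthetic tetrode recording session
#'
#' Pure tones are played at 0.5 Hz in random order across a log-spaced
#' frequency grid (2-50 kHz by default) and intensities of 50, 60, and
#' 70 dB SPL; on a random half of the trials the optogenetic light is on,
#' interleaved with control trials. Default population composition follows
#' the proportions observed in striatal tetrode recordings
#' (~80% MSN / 13% FS / 7% ChI).
#'
#' @param units List of [unit_spec()]s, or an integer count (units are then
#'   drawn with `draw_unit_specs()` defaults).
#' @param freq_grid_khz Tested frequencies (kHz).
#' @param intensities_db Tested intensities (dB SPL).
#' @param trials_per_condition Trials per (frequency, intensity, light)
#'   combination.
#' @param light_fraction Fraction of trials with light on.
#' @param tone_duration_s Tone duration (s).
#' @param tone_period_s Interval between tone onsets (s); 2 s = 0.5 Hz.
#' @param refractory_s Absolute refractory period passed to
#'   [simulate_unit_trials()]. Set to 0 when measured rates must equal the
#'   generating rate model exactly (refractoriness compresses high rates and
#'   so distorts rate-level ground truth in recovery experiments).
#' @param seed Integer seed.
#' @return A list of class `recording_spec`.
#' @export
recording_spec <- function(units = 12L,
                           freq_grid_khz = 2 * 2^seq(0, 4.5, by = 0.25),
                           intensities_db = c(50, 60, 70),
                           trials_per_condition = 20L,
                           light_fraction = 0.5,
                           tone_duration_s = 0.100,
                           tone_period_s = 2,
                           refractory_s = 0.001,
                           seed = 1L) {
  if (is.numeric(units) && length(units) == 1L) {
    units <- draw_unit_specs(as.integer(units), freq_grid_khz, seed = seed)
  }
  stopifnot(all(vapply(units, inherits, logical(1), "unit_spec")))
  structure(list(units = units, freq_grid_khz = freq_grid_khz,
                 intensities_db = intensities_db,
                 trials_per_condition = trials_per_condition,
                 light_fraction = light_fraction,
                 tone_duration_s = tone_duration_s,
                 tone_period_s = tone_period_s,
                 refractory_s = refractory_s, seed = seed),
            class = "recording_spec")
}

#' Draw a population of unit specifications
#'
#' Cell classes follow the default composition (80% MSN, 13% FS, 7% ChI);
#' waveform widths are drawn well inside each class's range, baseline rates
#' and tuning parameters from realistic ranges (preferred frequencies
#' uniform in log2 over the middle of the tested grid), and response kernels
#' are mostly onset with some sustained, mirroring the observed taxonomy.
#'
#' @param n Number of units.
#' @param freq_grid_khz Frequency grid the recording will test.
#' @param composition Named class probabilities.
#' @param kernel_probs Named response-kernel probabilities.
#' @param modulation Modulation model applied to every unit (see
#'   [unit_spec()]).
#' @param seed Optional integer seed.
#' @return List of [unit_spec()]s.
#' @export
draw_unit_specs <- function(n, freq_grid_khz = 2 * 2^seq(0, 4.5, by = 0.25),
                            composition = c(MSN = 0.80, FS = 0.13, ChI = 0.07),
                            kernel_probs = c(onset = 0.6, sustained = 0.25,
                                             offset = 0.05, suppression = 0.10),
                            modulation = list(type = "none"),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  classes <- sample(names(composition), n, replace = TRUE, prob = composition)
  kernels <- sample(names(kernel_probs), n, replace = TRUE, prob = kernel_probs)
  lx <- log2(range(freq_grid_khz))
  lapply(seq_len(n), function(i) {
    width <- switch(classes[i],
                    FS = runif(1, 60, 90),
                    MSN = runif(1, 110, 140),
                    ChI = runif(1, 170, 260))
    base <- switch(classes[i],
                   FS = runif(1, 8, 15),
                   MSN = runif(1, 2, 6),
                   ChI = runif(1, 4, 8))
    unit_spec(unit_id = i,
              waveform_width_us = width,
              baseline_rate_hz = base,
              tuning = c(A = runif(1, 25, 60),
                         f0 = runif(1, lx[1] + 1, lx[2] - 1),
                         sigma = runif(1, 0.4, 1.0),
                         B = runif(1, 0.5, 2)),
              response_kernel = kernels[i],
              # offset windows must begin within 20 ms of tone end
              latency_s = if (kernels[i] == "offset") runif(1, 0.005, 0.012)
                          else runif(1, 0.010, 0.025),
              min_intensity_db = sample(c(60, 70), 1, prob = c(0.7, 0.3)),
              modulation = modulation)
  })
}

#' Recording spec for a pathway-silencing population experiment
#'
#' Fixes the study conditions used for the silencing analyses: a population
#' of sustained-response units (long response windows give stable
#' per-frequency rate estimates, and silencing analyses concern the
#' onset/sustained-responsive projection neurons), moderately sharp tuning
#' (sigma 0.4-0.8 octaves), evoked amplitudes of 40-80 Hz over 2-6 Hz
#' baselines, 20 trials per frequency and condition at a single 60-dB
#' analysis intensity, with light trials randomly interleaved.
#'
#' @param modulation Modulation model applied to every unit (see
#'   [unit_spec()]).
#' @param seed Integer seed.
#' @param n_units Population size (default 25).
#' @param trials_per_condition Trials per (frequency, condition).
#' @return A [recording_spec()].
#' @export
silencing_population_spec <- function(modulation, seed, n_units = 25L,
                                      trials_per_condition = 20L) {
  set.seed(seed)
  units <- lapply(seq_len(n_units), function(i) {
    unit_spec(unit_id = i,
              waveform_width_us = runif(1, 110, 140),  # MSN widths
              baseline_rate_hz = runif(1, 2, 6),
              tuning = c(A = runif(1, 40, 80), f0 = runif(1, 2, 4.5),
                         sigma = runif(1, 0.4, 0.8), B = runif(1, 2, 6)),
              response_kernel = "sustained",
              latency_s = runif(1, 0.010, 0.025),
              min_intensity_db = 60,
              modulation = modulation)
  })
  # rate-level ground truth: no refractory compression of high control rates
  recording_spec(units = units, intensities_db = 60,
                 trials_per_condition = trials_per_condition,
                 refractory_s = 0, seed = seed)
}

#' Simulate a full recording session
#'
#' Builds the trial schedule (random order of frequency x intensity x
#' repetition, light randomly interleaved, onsets at the tone period), then
#' simulates every unit's spike train and mean waveform. Fully reproducible
#' from the recording spec's seed.
#'
#' @param spec A [recording_spec()].
#' @return A list of class `recording` with tibbles `trials` (`trial_id`,
#'   `onset_s`, `freq_khz`, `intensity_db`, `duration_s`, `light_on`),
#'   `spikes` (`unit_id`, `spike_time_s`), `waveforms` (`unit_id`,
#'   `sample_index`, `amplitude_uv`), and `units` (`unit_id`,
#'   `sample_rate_hz`, plus the generating truth: class, width, kernel).
#' @export
simulate_recording <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  set.seed(spec$seed)
  grid <- expand.grid(freq_khz = spec$freq_grid_khz,
                      intensity_db = spec$intensities_db,
                      rep = seq_len(spec$trials_per_condition),
                      light_on = c(FALSE, TRUE))
  # keep only the requested light fraction (0.5 keeps both halves whole)
  if (spec$light_fraction == 0) grid <- grid[!grid$light_on, ]
  grid <- grid[sample.int(nrow(grid)), ]
  trials <- tibble::tibble(
    trial_id = seq_len(nrow(grid)),
    onset_s = 1 + (seq_len(nrow(grid)) - 1) * spec$tone_period_s,
    freq_khz = grid$freq_khz,
    intensity_db = grid$intensity_db,
    duration_s = spec$tone_duration_s,
    light_on = grid$light_on
  )
  sample_rate_hz <- 32000
  unit_seeds <- sample.int(.Machine$integer.max, 2 * length(spec$units))
  spikes <- purrr::map2_dfr(spec$units, seq_along(spec$units), function(u, i) {
    simulate_unit_trials(u, trials, seed = unit_seeds[2 * i - 1],
                         refractory_s = spec$refractory_s)
  })
  waveforms <- purrr::map2_dfr(spec$units, seq_along(spec$units), function(u, i) {
    wf <- simulate_waveform(u$waveform_width_us, sample_rate_hz,
                            seed = unit_seeds[2 * i])
    tibble::tibble(unit_id = u$unit_id,
                   sample_index = seq_along(wf) - 1L,
                   amplitude_uv = wf)
  })
  units <- tibble::tibble(
    unit_id = vapply(spec$units, function(u) u$unit_id, numeric(1)),
    sample_rate_hz = sample_rate_hz,
    true_width_us = vapply(spec$units, function(u) u$waveform_width_us, numeric(1)),
    true_kernel = vapply(spec$units, function(u) u$response_kernel, character(1)),
    true_min_intensity_db = vapply(spec$units, function(u) u$min_intensity_db, numeric(1))
  )
  structure(list(trials = trials, spikes = spikes, waveforms = waveforms,
                 units = units, spec = spec),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("Synthetic recording:", nrow(x$units), "units,",
      nrow(x$trials), "tone trials,", nrow(x$spikes), "spikes\n")
  invisible(x)
}
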