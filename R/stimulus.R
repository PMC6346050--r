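#' Cloud-of-tones stimulus configuration
#'
#' The discrimination stimulus is a stream of brief overlapping pure tones
#' presented at a fixed rate. Eighteen possible tone frequencies are spaced
#' uniformly in log2 from 5 to 40 kHz (three octaves, six grid frequencies
#' per octave). The low target octave is 5-10 kHz and the high target octave
#' is 20-40 kHz; the middle octave (10-20 kHz) carries no choice evidence.
#'
#' @param freq_grid_khz Tone frequency grid in kHz. Default: 18 values
#'   uniformly log2-spaced from 5 to 40.
#' @param tone_duration_s Duration of each pure tone, seconds.
#' @param tone_rate_hz Tone onset rate, onsets per second. Consecutive tones
#'   overlap when `tone_duration_s > 1/tone_rate_hz`.
#' @param low_band_khz,high_band_khz Inclusive frequency intervals (kHz)
#'   defining the low and high target octaves. Each must span exactly one
#'   octave and they must be disjoint.
#'
#' @return A list of class `tone_cloud_config`.
#' @examples
#' cfg <- tone_cloud_config()
#' length(cfg$freq_grid_khz)  # 18
#' @export
tone_cloud_config <- function(freq_grid_khz = 5 * 2^seq(0, 3, length.out = 18),
                              tone_duration_s = 0.030,
                              tone_rate_hz = 100,
                              low_band_khz = c(5, 10),
                              high_band_khz = c(20, 40)) {
  stopifnot(length(freq_grid_khz) >= 3, tone_duration_s > 0, tone_rate_hz > 0,
            length(low_band_khz) == 2, length(high_band_khz) == 2)
  if (any(diff(freq_grid_khz) <= 0)) {
    abort("`freq_grid_khz` must be strictly increasing.", class = "striatune_invalid_parameter")
  }
  steps <- diff(log2(freq_grid_khz))
  if (max(steps) - min(steps) > 1e-8) {
    abort("`freq_grid_khz` must be uniformly spaced in log2.", class = "striatune_invalid_parameter")
  }
  for (band in list(low_band_khz, high_band_khz)) {
    if (abs(log2(band[2] / band[1]) - 1) > 1e-8) {
      abort("target bands must each span exactly one octave.", class = "striatune_invalid_parameter")
    }
  }
  if (low_band_khz[2] >= high_band_khz[1]) {
    abort("`low_band_khz` and `high_band_khz` must be disjoint, low below high.",
          class = "striatune_invalid_parameter")
  }
  structure(
    list(freq_grid_khz = freq_grid_khz,
         tone_duration_s = tone_duration_s,
         tone_rate_hz = tone_rate_hz,
         low_band_khz = low_band_khz,
         high_band_khz = high_band_khz),
    class = "tone_cloud_config"
  )
}

#' Assign grid frequencies to the low / middle / high octave
#'
#' @param freq_khz Numeric vector of frequencies in kHz.
#' @param config A [tone_cloud_config()].
#' @return Character vector in `c("low", "mid", "high")`.
#' @export
tone_octave <- function(freq_khz, config = tone_cloud_config()) {
  dplyr::case_when(
    freq_khz >= config$low_band_khz[1] & freq_khz <= config$low_band_khz[2] ~ "low",
    freq_khz >= config$high_band_khz[1] & freq_khz <= config$high_band_khz[2] ~ "high",
    TRUE ~ "mid"
  )
}

#' Generate one cloud-of-tones trial stimulus
#'
#' Tone onsets are placed on a regular grid at `tone_rate_hz` starting at 0 s.
#' Each tone is independently assigned to the target octave with probability
#' `(1 + 2 r / 100) / 3` — the parenthesization that equals chance (one of
#' three octaves) at `r = 0` and certainty at `r = 100` — and otherwise
#' uniformly to one of the two non-target octaves. Within an octave the
#' frequency is drawn uniformly from that octave's grid points.
#'
#' @param config A [tone_cloud_config()].
#' @param r Stimulus strength in percent, in \[0, 100\]; the side is encoded
#'   by `target`.
#' @param target `"low"` or `"high"`: the rewarded octave for this trial.
#' @param duration_s Stimulus duration in seconds (in vivo the stream stops at
#'   withdrawal; the simulator takes an explicit duration).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A tibble of class `trial_stimulus` with one row per tone
#'   (`onset_s`, `freq_khz`, `octave`) and attributes `r`, `target`, `config`.
#' @examples
#' stim <- generate_tone_cloud(r = 100, target = "high", duration_s = 0.3, seed = 1)
#' nrow(stim)                 # 30 tones at 100 Hz for 0.3 s
#' all(stim$octave == "high") # full evidence
#' @export
generate_tone_cloud <- function(config = tone_cloud_config(), r, target,
                                duration_s, seed = NULL) {
  stopifnot(duration_s > 0)
  target <- match.arg(target, c("low", "high"))
  p_target <- (1 + 2 * r / 100) / 3
  if (!is.finite(p_target) || p_target < 0 || p_target > 1) {
    abort(sprintf("target-octave probability %.3f outside [0, 1]; r must lie in [-50, 100].",
                  p_target),
          class = "striatune_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)

  n_tones <- floor(duration_s * config$tone_rate_hz + 1e-9)
  onsets <- (seq_len(n_tones) - 1) / config$tone_rate_hz

  octaves <- tone_octave(config$freq_grid_khz, config)
  bands <- list(low = config$freq_grid_khz[octaves == "low"],
                mid = config$freq_grid_khz[octaves == "mid"],
                high = config$freq_grid_khz[octaves == "high"])
  others <- setdiff(c("low", "mid", "high"), target)

  in_target <- runif(n_tones) < p_target
  octave <- ifelse(in_target, target, sample(others, n_tones, replace = TRUE))
  freq <- vapply(octave, function(o) {
    g <- bands[[o]]
    g[sample.int(length(g), 1L)]
  }, numeric(1), USE.NAMES = FALSE)

  out <- tibble::tibble(onset_s = onsets, freq_khz = freq, octave = octave)
  structure(out, r = r, target = target, config = config,
            class = c("trial_stimulus", class(out)))
}

#' Evidence strength of a trial
#'
#' The per-trial evidence statistic is
#' `(# high tones - # low tones) / (# high tones + # low tones)`;
#' tones in the middle octave count in neither term. Values of -1 and 1 carry
#' full evidence for the low and high octave respectively; 0 carries none.
#'
#' @param stimulus Either a `trial_stimulus` (from [generate_tone_cloud()]),
#'   or a data frame with a `freq_khz` column, or a numeric vector of tone
#'   frequencies in kHz.
#' @param config A [tone_cloud_config()] used to band frequencies; ignored
#'   when `stimulus` already carries one.
#' @return A single number in \[-1, 1\].
#' @examples
#' evidence_strength(c(25, 30, 40))        # all high -> 1
#' evidence_strength(c(5, 6, 25, 30))      # 2 high, 2 low -> 0
#' @export
evidence_strength <- function(stimulus, config = tone_cloud_config()) {
  if (inherits(stimulus, "trial_stimulus")) {
    config <- attr(stimulus, "config")
    freq <- stimulus$freq_khz
  } else if (is.data.frame(stimulus)) {
    freq <- stimulus$freq_khz
  } else {
    freq <- stimulus
  }
  oct <- tone_octave(freq, config)
  n_high <- sum(oct == "high")
  n_low <- sum(oct == "low")
  if (n_high + n_low == 0L) {
    abort("no tones in the low or high octave: evidence strength undefined.",
          class = "striatune_undefined_evidence")
  }
  (n_high - n_low) / (n_high + n_low)
}
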