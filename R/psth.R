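#' Peristimulus time histogram from spike and tone-onset times
#'
#' Pools spikes across trials, aligned to tone onset, and computes the firing
#' rate in a sliding window: for each window the rate is
#' `spike count across trials / (n_trials * window_width_s)`. Windows are
#' half-open `[t, t + width)` and advance by `step_s`; each bin is indexed by
#' its window *start* time. The axis spans 100 ms before tone onset to
#' 200 ms after tone end.
#'
#' Because consecutive windows overlap (width 3 ms, step 1 ms by default),
#' each interior spike is counted in `width / step` windows, so the PSTH
#' integral `sum(rate) * step` equals `total spikes / n_trials` up to edge
#' effects. Set `step_s = window_width_s` for non-overlapping bins.
#'
#' @param spike_times Numeric vector of spike times (s), on the same clock as
#'   `tone_onsets`.
#' @param tone_onsets Numeric vector of tone onset times (s), one per trial.
#' @param tone_duration_s Tone duration (s).
#' @param window_width_s Sliding window width (s); default 0.003.
#' @param step_s Window step (s); default 0.001.
#' @param pre_s,post_s Span before onset and after tone end (s).
#' @return A tibble of class `psth` with columns `time_s` (window start,
#'   relative to onset) and `rate_hz`, and attributes `window_width_s`,
#'   `step_s`, `n_trials`, `tone_duration_s`.
#' @examples
#' psth <- compute_psth(c(0.001, 0.002), tone_onsets = 0, tone_duration_s = 0.1)
#' max(psth$rate_hz)  # 2 spikes / 3 ms
#' @export
compute_psth <- function(spike_times, tone_onsets, tone_duration_s,
                         window_width_s = 0.003, step_s = 0.001,
                         pre_s = 0.100, post_s = 0.200) {
  if (length(tone_onsets) == 0L) {
    abort("no trials: at least one tone onset is required.",
          class = "striatune_empty_input")
  }
  stopifnot(window_width_s > 0, step_s > 0, tone_duration_s >= 0)
  t_end <- tone_duration_s + post_s
  rel <- unlist(lapply(tone_onsets, function(on) {
    s <- spike_times[spike_times >= on - pre_s - window_width_s &
                       spike_times < on + t_end + window_width_s]
    s - on
  }), use.names = FALSE)
  rel <- sort(rel)
  starts <- seq(-pre_s, t_end - window_width_s + 1e-12, by = step_s)
  # count spikes in [t, t + width): #(rel < t + width) - #(rel < t)
  lo <- findInterval(starts, rel, left.open = TRUE)
  hi <- findInterval(starts + window_width_s, rel, left.open = TRUE)
  rate <- (hi - lo) / (length(tone_onsets) * window_width_s)
  out <- tibble::tibble(time_s = starts, rate_hz = rate)
  structure(out,
            window_width_s = window_width_s, step_s = step_s,
            n_trials = length(tone_onsets), tone_duration_s = tone_duration_s,
            class = c("psth", class(out)))
}

#' Baseline mean and SD of a PSTH
#'
#' Mean and standard deviation of the PSTH over the baseline span, 50 to 0 ms
#' before tone onset. Only windows lying entirely within the baseline span
#' are used, so no post-onset spikes leak into the baseline statistics.
#'
#' @param psth A [compute_psth()] result.
#' @param span_s Baseline span relative to onset, default `c(-0.050, 0)`.
#' @return A list with `mean_hz` and `sd_hz`.
#' @export
baseline_stats <- function(psth, span_s = c(-0.050, 0)) {
  w <- attr(psth, "window_width_s")
  sel <- psth$time_s >= span_s[1] - 1e-9 & psth$time_s + w <= span_s[2] + 1e-9
  if (!any(sel)) {
    abort("PSTH does not cover the baseline span.", class = "striatune_coverage")
  }
  x <- psth$rate_hz[sel]
  list(mean_hz = mean(x), sd_hz = if (length(x) > 1L) sd(x) else 0)
}

#' Detect the tone-response window of a PSTH
#'
#' Finds the earliest contiguous run of PSTH windows, starting at or after
#' tone onset and within 200 ms of tone end, in which the rate deviates from
#' the baseline mean beyond threshold. Excitatory crossings
#' (`rate > mean + 3 SD`) are searched first; if none exists, suppressive
#' crossings (`rate < mean - 2 SD`) are searched. If no window crosses either
#' threshold the unit is considered not responsive to tones.
#'
#' The first time point of the window is the response latency. Runs separated
#' by one or more sub-threshold bins are distinct; only the earliest is
#' returned. A floor is applied to the baseline SD so that silent baselines
#' (SD = 0) do not produce spurious windows.
#'
#' @param psth A [compute_psth()] result.
#' @param baseline A [baseline_stats()] result.
#' @param excite_sd,suppress_sd Threshold multipliers (defaults 3 and 2).
#' @param sd_floor_hz Minimum SD used in the thresholds (default 0.1 Hz).
#' @param min_run Minimum number of consecutive supra-threshold bins for a
#'   valid window (default 1).
#' @return `NULL` if not responsive, else a list with `start_s`, `end_s`
#'   (start times of the first and last bin of the run), `direction`
#'   (`"excited"` or `"suppressed"`), and `latency_s` (= `start_s`).
#' @export
detect_response_window <- function(psth, baseline,
                                   excite_sd = 3, suppress_sd = 2,
                                   sd_floor_hz = 0.1, min_run = 1L) {
  sd_eff <- max(baseline$sd_hz, sd_floor_hz)
  t_max <- attr(psth, "tone_duration_s") + 0.200
  eligible <- psth$time_s >= -1e-12 & psth$time_s <= t_max + 1e-12

  first_run <- function(flag) {
    flag <- flag & eligible
    if (!any(flag)) return(NULL)
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= min_run)
    if (length(ok) == 0L) return(NULL)
    c(starts[ok[1L]], ends[ok[1L]])
  }

  run <- first_run(psth$rate_hz > baseline$mean_hz + excite_sd * sd_eff)
  direction <- "excited"
  if (is.null(run)) {
    run <- first_run(psth$rate_hz < baseline$mean_hz - suppress_sd * sd_eff)
    direction <- "suppressed"
  }
  if (is.null(run)) return(NULL)
  start_s <- psth$time_s[run[1L]]
  list(start_s = start_s, end_s = psth$time_s[run[2L]],
       direction = direction, latency_s = start_s)
}

#' Classify a detected response window
#'
#' Assigns one of the four tone-response types:
#' * `suppression` — the window was a suppressive crossing (rate more than
#'   2 SD below the baseline mean), regardless of timing;
#' * `offset` — an excitatory window starting within 20 ms after tone end
#'   (strictly before `tone_end + 20 ms`; a start at or after tone end takes
#'   precedence over the onset/sustained timing rules);
#' * `onset` — an excitatory window that ends before 50 ms after tone onset;
#' * `sustained` — an excitatory window that ends at or after 50 ms.
#'
#' @param window A [detect_response_window()] result (may be `NULL`).
#' @param tone_duration_s Tone duration (s).
#' @param onset_cut_s Onset/sustained boundary after tone onset (default
#'   0.050 s; a window ending exactly at the boundary is sustained).
#' @param offset_lag_s Maximum lag after tone end for an offset response
#'   (default 0.020 s, strict).
#' @return A single string in
#'   `c("onset", "sustained", "offset", "suppression", "none")`.
#' @export
classify_response <- function(window, tone_duration_s,
                              onset_cut_s = 0.050, offset_lag_s = 0.020) {
  if (is.null(window)) return("none")
  if (window$direction == "suppressed") return("suppression")
  if (window$start_s >= tone_duration_s - 1e-12) {
    if (window$start_s < tone_duration_s + offset_lag_s - 1e-12) return("offset")
    return("sustained")  # late excitation past the offset lag
  }
  if (window$end_s < onset_cut_s - 1e-12) "onset" else "sustained"
}

#' Baseline-subtracted response firing rate
#'
#' Mean PSTH rate over the response window minus the baseline mean; negative
#' for suppression responses.
#'
#' @param psth A [compute_psth()] result.
#' @param window A [detect_response_window()] result.
#' @param baseline A [baseline_stats()] result.
#' @return Rate in Hz.
#' @export
response_rate <- function(psth, window, baseline) {
  stopifnot(!is.null(window))
  sel <- psth$time_s >= window$start_s - 1e-12 & psth$time_s <= window$end_s + 1e-12
  mean(psth$rate_hz[sel]) - baseline$mean_hz
}

#' Full response profile of one unit under one condition
#'
#' Convenience wrapper chaining [compute_psth()], [baseline_stats()],
#' [detect_response_window()], [classify_response()] and [response_rate()].
#'
#' @inheritParams compute_psth
#' @param ... Passed to [detect_response_window()].
#' @return A one-row tibble: `responsive`, `response_type`, `window_start_s`,
#'   `window_end_s`, `latency_s`, `response_rate_hz`, `baseline_hz`,
#'   `baseline_sd_hz`, `n_trials`.
#' @export
response_profile <- function(spike_times, tone_onsets, tone_duration_s,
                             window_width_s = 0.003, step_s = 0.001, ...) {
  psth <- compute_psth(spike_times, tone_onsets, tone_duration_s,
                       window_width_s = window_width_s, step_s = step_s)
  bl <- baseline_stats(psth)
  win <- detect_response_window(psth, bl, ...)
  type <- classify_response(win, tone_duration_s)
  tibble::tibble(
    responsive = !is.null(win),
    response_type = type,
    window_start_s = if (is.null(win)) NA_real_ else win$start_s,
    window_end_s = if (is.null(win)) NA_real_ else win$end_s,
    latency_s = if (is.null(win)) NA_real_ else win$latency_s,
    response_rate_hz = if (is.null(win)) NA_real_ else response_rate(psth, win, bl),
    baseline_hz = bl$mean_hz,
    baseline_sd_hz = bl$sd_hz,
    n_trials = length(tone_onsets)
  )
}

#' @export
autoplot.psth <- function(object, baseline = NULL, window = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$rate_hz)) +
    ggplot2::annotate("rect", xmin = 0, xmax = attr(object, "tone_duration_s"),
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_step(colour = "black") +
    ggplot2::labs(x = "time from tone onset (s)", y = "firing rate (Hz)") +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline$mean_hz, linetype = 2)
  }
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window$start_s, xmax = window$end_s,
                               ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red")
  }
  p
}
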