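#' Choose the analysis intensity for a unit
#'
#' Tonal response analysis uses the lower responsive intensity of 60 or
#' 70 dB SPL: 60 dB if the unit is tone-responsive at 60 dB, else 70 dB if
#' responsive at 70 dB. 50 dB is never used; a unit responsive at neither 60
#' nor 70 dB is excluded from tuning analysis (returns `NA`).
#'
#' @param responses Data frame with columns `intensity_db` and logical
#'   `responsive` (one row per tested intensity for one unit), or a named
#'   logical vector like `c("60" = TRUE, "70" = TRUE)`.
#' @return `60`, `70`, or `NA_real_` (excluded).
#' @export
select_analysis_intensity <- function(responses) {
  if (is.data.frame(responses)) {
    resp_at <- function(db) {
      any(responses$responsive[responses$intensity_db == db])
    }
  } else {
    resp_at <- function(db) isTRUE(unname(responses[as.character(db)]))
  }
  if (resp_at(60)) return(60)
  if (resp_at(70)) return(70)
  NA_real_
}

#' Build a frequency tuning curve for one unit
#'
#' For each tested frequency, the tone-evoked response is the mean firing
#' rate inside the unit's response window minus the mean baseline rate
#' (50-0 ms before onset), averaged over the trials at that frequency. The
#' response window must come from control (light-off) trials; the same
#' window is then applied to every condition.
#'
#' @param spike_times Numeric vector of spike times (s).
#' @param trials Data frame of tone trials with columns `onset_s`,
#'   `freq_khz`, and `duration_s` (one row per trial), already filtered to
#'   the unit's analysis intensity and to one light condition.
#' @param window A response window (list with `start_s`, `end_s`) from
#'   [detect_response_window()] on control trials. `end_s` indexes the start
#'   of the last supra-threshold PSTH bin; the spanned interval is
#'   `[start_s, end_s + window_width_s)`.
#' @param window_width_s PSTH window width used when the window was detected.
#' @param baseline_span_s Baseline interval relative to onset.
#' @param min_freqs Minimum number of distinct frequencies required.
#' @return A tibble of class `tuning_curve`: `freq_khz`, `rate_hz`
#'   (baseline-subtracted), `n_trials`.
#' @export
build_tuning_curve <- function(spike_times, trials, window,
                               window_width_s = 0.003,
                               baseline_span_s = c(-0.050, 0),
                               min_freqs = 5L) {
  stopifnot(all(c("onset_s", "freq_khz", "duration_s") %in% names(trials)))
  freqs <- sort(unique(trials$freq_khz))
  if (length(freqs) < min_freqs) {
    abort(sprintf("tuning curve needs >= %d distinct frequencies, got %d.",
                  min_freqs, length(freqs)),
          class = "striatune_insufficient_coverage")
  }
  win_len <- window$end_s + window_width_s - window$start_s
  base_len <- diff(baseline_span_s)
  sp <- sort(spike_times)
  count_in <- function(a, b) {
    findInterval(b, sp, left.open = TRUE) - findInterval(a, sp, left.open = TRUE)
  }
  per_trial <- tibble::tibble(
    freq_khz = trials$freq_khz,
    evoked = vapply(trials$onset_s, function(on)
      count_in(on + window$start_s, on + window$end_s + window_width_s) / win_len,
      numeric(1)),
    base = vapply(trials$onset_s, function(on)
      count_in(on + baseline_span_s[1], on + baseline_span_s[2]) / base_len,
      numeric(1))
  )
  # the baseline is the unit's, pooled over all trials, not per frequency
  baseline_hz <- mean(per_trial$base)
  out <- per_trial |>
    dplyr::group_by(.data$freq_khz) |>
    dplyr::summarise(rate_hz = mean(.data$evoked) - baseline_hz,
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$freq_khz)
  structure(out, class = c("tuning_curve", class(out)))
}

#' Best frequency of a tuning curve
#'
#' The tested frequency that evoked the highest response firing rate; exact
#' ties go to the lowest frequency.
#'
#' @param curve A data frame with `freq_khz` and `rate_hz` columns (e.g. a
#'   [build_tuning_curve()] result), or a numeric vector of rates with
#'   `freqs_khz` supplied.
#' @param freqs_khz Frequencies matching `curve` when `curve` is a bare
#'   numeric vector of rates.
#' @return Best frequency in kHz.
#' @export
best_frequency <- function(curve, freqs_khz = NULL) {
  if (is.data.frame(curve)) {
    freqs_khz <- curve$freq_khz
    rates <- curve$rate_hz
  } else {
    rates <- curve
  }
  ord <- order(freqs_khz)
  freqs_khz <- freqs_khz[ord]
  rates <- rates[ord]
  freqs_khz[which.max(rates)]  # which.max returns the first (lowest) maximum
}

#' Savitzky-Golay smoothing of a tuning curve
#'
#' Smooths the per-frequency response rates with a Savitzky-Golay filter of
#' span five (window of 5 grid points) and polynomial order 2, the standard
#' least-squares local-polynomial smoother. Constant and quadratic inputs
#' pass through unchanged.
#'
#' @param rates Numeric vector of rates ordered by frequency, or a
#'   `tuning_curve` data frame (its `rate_hz` is smoothed and returned in a
#'   `smoothed_rate_hz` column).
#' @param span Filter window length in points (odd, default 5).
#' @param order Polynomial order (default 2).
#' @return Same shape as the input: a numeric vector, or the tibble with a
#'   `smoothed_rate_hz` column added.
#' @export
smooth_curve <- function(rates, span = 5L, order = 2L) {
  if (is.data.frame(rates)) {
    rates$smoothed_rate_hz <- smooth_curve(rates$rate_hz, span, order)
    return(rates)
  }
  if (length(rates) < span) {
    abort(sprintf("need >= %d points for span-%d smoothing.", span, span),
          class = "striatune_insufficient_coverage")
  }
  as.numeric(signal::sgolayfilt(rates, p = order, n = span))
}

#' Tuning width at half peak, in octaves
#'
#' The frequency range over which the (smoothed) tuning curve stays at or
#' above half of its peak firing rate, around the global peak, measured on
#' the log2-frequency axis with linear interpolation between grid points.
#' If the curve never falls below half-peak on a side, the width is truncated
#' at the grid edge and flagged.
#'
#' @param curve Data frame with `freq_khz` and a rate column, or a numeric
#'   rate vector with `freqs_khz` supplied.
#' @param freqs_khz Frequencies when `curve` is a bare vector.
#' @param rate_col Column used when `curve` is a data frame; defaults to
#'   `smoothed_rate_hz` when present, else `rate_hz`.
#' @return Width in octaves, with attribute `truncated` (logical).
#' @export
tuning_width <- function(curve, freqs_khz = NULL, rate_col = NULL) {
  if (is.data.frame(curve)) {
    if (is.null(rate_col)) {
      rate_col <- if ("smoothed_rate_hz" %in% names(curve)) "smoothed_rate_hz" else "rate_hz"
    }
    freqs_khz <- curve$freq_khz
    rates <- curve[[rate_col]]
  } else {
    rates <- curve
  }
  ord <- order(freqs_khz)
  x <- log2(freqs_khz[ord])
  y <- rates[ord]
  pk <- which.max(y)
  if (y[pk] <= 0) {
    abort("tuning curve has no positive peak.", class = "striatune_invalid_parameter")
  }
  half <- y[pk] / 2
  truncated <- FALSE

  # walk out from the peak to the first point below half, interpolate
  cross_left <- {
    j <- pk
    while (j > 1L && y[j - 1L] >= half) j <- j - 1L
    if (j == 1L) { truncated <- TRUE; x[1L] }
    else x[j - 1L] + (half - y[j - 1L]) / (y[j] - y[j - 1L]) * (x[j] - x[j - 1L])
  }
  cross_right <- {
    j <- pk
    while (j < length(y) && y[j + 1L] >= half) j <- j + 1L
    if (j == length(y)) { truncated <- TRUE; x[length(x)] }
    else x[j] + (y[j] - half) / (y[j] - y[j + 1L]) * (x[j + 1L] - x[j])
  }
  structure(cross_right - cross_left, truncated = truncated)
}

#' Fit a Gaussian frequency tuning model
#'
#' Fits `R(f) = A * exp(-0.5 * (x - f0)^2 / sigma^2) + B` by bounded
#' nonlinear least squares, where `x = log2(frequency in kHz)` so that `f0`
#' is the preferred frequency in log2(kHz) and `sigma` is the tuning width
#' parameter in octaves. `B` is the baseline response, `A` the amplitude of
#' the strongest evoked response. Goodness of fit is
#' `R^2 = 1 - SS_res / SS_tot`; a unit counts as tuned (`included`) when
#' `R^2 > 0.4`.
#'
#' Initialization is `A = max - min`, `B = min`, `f0 = argmax`, with a
#' multi-start over `sigma` to avoid local minima; `sigma` is bounded to
#' (0.05, 5\] octaves and `A >= 0`.
#'
#' @param curve Data frame with `freq_khz` and `rate_hz` (e.g. a
#'   [build_tuning_curve()] result), or a numeric rate vector with
#'   `freqs_khz` supplied.
#' @param freqs_khz Frequencies when `curve` is a bare vector.
#' @param sigma_starts Multi-start values for `sigma`, in octaves.
#' @param r2_threshold Inclusion threshold on `R^2` (default 0.4).
#' @return An object of class `gaussian_fit`: a list with `A`, `f0`
#'   (log2 kHz), `sigma` (octaves), `B`, `r_squared`, `included`,
#'   `converged`, `best_freq_khz` (`2^f0`), plus the data. Supports
#'   [tidy()], [glance()], [predict()] and [autoplot()].
#' @export
fit_gaussian <- function(curve, freqs_khz = NULL,
                         sigma_starts = c(0.25, 0.5, 1, 2),
                         r2_threshold = 0.4) {
  if (is.data.frame(curve)) {
    freqs_khz <- curve$freq_khz
    rates <- curve$rate_hz
  } else {
    rates <- curve
  }
  keep <- is.finite(rates) & is.finite(freqs_khz)
  freqs_khz <- freqs_khz[keep]
  rates <- rates[keep]
  if (length(rates) < 5L) {
    abort("Gaussian fit needs >= 5 frequencies with finite rates.",
          class = "striatune_insufficient_coverage")
  }
  x <- log2(freqs_khz)
  dat <- data.frame(x = x, y = rates)
  start_A <- max(rates) - min(rates)
  start_B <- min(rates)
  start_f0 <- x[which.max(rates)]

  best <- NULL
  for (s0 in sigma_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-0.5 * (x - f0)^2 / sigma^2) + B,
        data = dat,
        start = list(A = max(start_A, 1e-6), f0 = start_f0, sigma = s0, B = start_B),
        lower = c(A = 0, f0 = min(x) - 2, sigma = 0.05, B = -Inf),
        upper = c(A = Inf, f0 = max(x) + 2, sigma = 5, B = Inf),
        control = nls.lm.control2()
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    return(structure(
      list(A = NA_real_, f0 = NA_real_, sigma = NA_real_, B = NA_real_,
           r_squared = NA_real_, included = FALSE, converged = FALSE,
           best_freq_khz = NA_real_, freq_khz = freqs_khz, rate_hz = rates),
      class = "gaussian_fit"
    ))
  }
  p <- as.list(coef(best$fit))
  ss_tot <- sum((rates - mean(rates))^2)
  r2 <- if (ss_tot > 0) 1 - best$rss / ss_tot else 0
  structure(
    list(A = p$A, f0 = p$f0, sigma = p$sigma, B = p$B,
         r_squared = r2, included = r2 > r2_threshold, converged = TRUE,
         best_freq_khz = 2^p$f0, freq_khz = freqs_khz, rate_hz = rates),
    class = "gaussian_fit"
  )
}

# nlsLM control with a few more iterations than the default
nls.lm.control2 <- function() minpack.lm::nls.lm.control(maxiter = 200)

#' @export
print.gaussian_fit <- function(x, ...) {
  cat("Gaussian tuning fit\n")
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  A = %.3f, f0 = %.3f log2(kHz) (%.2f kHz), sigma = %.3f oct, B = %.3f\n",
              x$A, x$f0, x$best_freq_khz, x$sigma, x$B))
  cat(sprintf("  R^2 = %.3f (%s)\n", x$r_squared,
              if (x$included) "tuned" else "not tuned"))
  invisible(x)
}

#' @rdname fit_gaussian
#' @param x,object A `gaussian_fit`.
#' @param ... Unused.
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "f0", "sigma", "B"),
                 estimate = c(x$A, x$f0, x$sigma, x$B))
}

#' @rdname fit_gaussian
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, included = x$included,
                 converged = x$converged, best_freq_khz = x$best_freq_khz,
                 n_freqs = length(x$freq_khz))
}

#' @rdname fit_gaussian
#' @param newdata Frequencies (kHz) at which to evaluate the fitted curve;
#'   numeric vector or data frame with `freq_khz`.
#' @export
predict.gaussian_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) object$freq_khz
       else if (is.data.frame(newdata)) newdata$freq_khz else newdata
  x <- log2(f)
  object$A * exp(-0.5 * (x - object$f0)^2 / object$sigma^2) + object$B
}

#' @export
autoplot.gaussian_fit <- function(object, ...) {
  obs <- tibble::tibble(freq_khz = object$freq_khz, rate_hz = object$rate_hz)
  grid <- tibble::tibble(freq_khz = 2^seq(log2(min(obs$freq_khz)),
                                          log2(max(obs$freq_khz)), length.out = 200))
  grid$rate_hz <- predict(object, grid)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$freq_khz, y = .data$rate_hz)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "frequency (kHz)", y = "response rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Fit control and light-on tuning curves with a shared Gaussian shape
#'
#' Fits both conditions jointly with a common preferred frequency `f0` and
#' width `sigma` but per-condition amplitude and baseline — the model
#' underlying the offset/gain decomposition, in which silencing rescales and
#' shifts the curve without moving or reshaping it. Sharing the shape makes
#' the per-condition amplitudes linear coefficients given `(f0, sigma)`, so
#' the weak (silenced) condition's amplitude is estimated without the
#' low-signal-to-noise inflation a free-shape fit suffers, and the
#' closed-form decomposition of the two returned fits is stable.
#'
#' @param control_curve,light_curve Data frames with `freq_khz` and `rate_hz`
#'   on a common grid.
#' @inheritParams fit_gaussian
#' @return A list with `control` and `light` (`gaussian_fit` objects with
#'   identical `f0` and `sigma`; each carries its own condition's `R^2`) and
#'   `converged`.
#' @export
fit_gaussian_shared <- function(control_curve, light_curve,
                                sigma_starts = c(0.25, 0.5, 1, 2),
                                r2_threshold = 0.4) {
  xc <- log2(control_curve$freq_khz)
  xl <- log2(light_curve$freq_khz)
  dat <- data.frame(x = c(xc, xl),
                    y = c(control_curve$rate_hz, light_curve$rate_hz),
                    is_light = rep(c(0, 1), c(length(xc), length(xl))))
  yc <- control_curve$rate_hz
  start_f0 <- xc[which.max(yc)]
  sA <- max(max(yc) - min(yc), 1e-6)

  best <- NULL
  for (s0 in sigma_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ (Ac * (1 - is_light) + Al * is_light) *
          exp(-0.5 * (x - f0)^2 / sigma^2) +
          (Bc * (1 - is_light) + Bl * is_light),
        data = dat,
        start = list(Ac = sA, Al = sA / 2, f0 = start_f0, sigma = s0,
                     Bc = min(yc), Bl = min(light_curve$rate_hz)),
        lower = c(Ac = 0, Al = 0, f0 = min(xc) - 2, sigma = 0.05,
                  Bc = -Inf, Bl = -Inf),
        upper = c(Ac = Inf, Al = Inf, f0 = max(xc) + 2, sigma = 5,
                  Bc = Inf, Bl = Inf),
        control = nls.lm.control2()
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(list(control = NULL, light = NULL, converged = FALSE))
  p <- as.list(coef(best$fit))
  mk <- function(A, B, freqs, rates) {
    pred <- A * exp(-0.5 * (log2(freqs) - p$f0)^2 / p$sigma^2) + B
    ss_tot <- sum((rates - mean(rates))^2)
    r2 <- if (ss_tot > 0) 1 - sum((rates - pred)^2) / ss_tot else 0
    structure(
      list(A = A, f0 = p$f0, sigma = p$sigma, B = B, r_squared = r2,
           included = r2 > r2_threshold, converged = TRUE,
           best_freq_khz = 2^p$f0, freq_khz = freqs, rate_hz = rates),
      class = "gaussian_fit")
  }
  list(control = mk(p$Ac, p$Bc, control_curve$freq_khz, control_curve$rate_hz),
       light = mk(p$Al, p$Bl, light_curve$freq_khz, light_curve$rate_hz),
       converged = TRUE)
}

#' Align tuning curves to best frequency and normalize across a population
#'
#' Each unit's control and light-on tuning curves are re-indexed in octaves
#' relative to that condition's own best frequency, and both conditions are
#' divided by the unit's control response rate at the control best frequency.
#' The population summary is the mean and standard error per octave offset
#' and condition; by construction the control population curve equals 1.0 at
#' offset 0. Units whose control peak rate is not positive are excluded from
#' normalization.
#'
#' @param curves Long data frame with columns `unit_id`, `condition`
#'   (values `control_label` and `light_label`), `freq_khz`, `rate_hz`.
#' @param control_label,light_label Condition labels (defaults `"control"`,
#'   `"light"`).
#' @param digits Octave offsets are rounded to this many digits when grouping
#'   grid points across units.
#' @return An object of class `aligned_population`: list with `units` (the
#'   per-unit normalized long tibble, columns `unit_id`, `condition`,
#'   `octave_offset`, `norm_rate`), `summary` (per condition x offset:
#'   `mean_norm_rate`, `sem`, `n_units`), `n_units`, and `excluded`
#'   (unit ids dropped for non-positive control peaks).
#' @export
align_and_normalize <- function(curves, control_label = "control",
                                light_label = "light", digits = 6) {
  stopifnot(all(c("unit_id", "condition", "freq_khz", "rate_hz") %in% names(curves)))
  per_unit <- curves |>
    dplyr::filter(.data$condition %in% c(control_label, light_label)) |>
    dplyr::group_by(.data$unit_id)
  # control best-frequency rate per unit (the normalizer)
  norms <- per_unit |>
    dplyr::filter(.data$condition == control_label) |>
    dplyr::summarise(norm = max(.data$rate_hz),
                     bf_control = best_frequency(.data$rate_hz, .data$freq_khz),
                     .groups = "drop")
  excluded <- norms$unit_id[norms$norm <= 0]
  norms <- norms[norms$norm > 0, , drop = FALSE]

  units <- curves |>
    dplyr::inner_join(norms, by = "unit_id") |>
    dplyr::group_by(.data$unit_id, .data$condition) |>
    dplyr::mutate(bf = best_frequency(.data$rate_hz, .data$freq_khz)) |>
    dplyr::ungroup() |>
    dplyr::mutate(octave_offset = round(log2(.data$freq_khz / .data$bf), digits),
                  norm_rate = .data$rate_hz / .data$norm) |>
    dplyr::select("unit_id", "condition", "octave_offset", "norm_rate")

  summary <- units |>
    dplyr::group_by(.data$condition, .data$octave_offset) |>
    dplyr::summarise(mean_norm_rate = mean(.data$norm_rate),
                     sem = sd(.data$norm_rate) / sqrt(dplyr::n()),
                     n_units = dplyr::n(), .groups = "drop")

  structure(list(units = units, summary = summary,
                 n_units = length(unique(units$unit_id)),
                 excluded = excluded,
                 control_label = control_label, light_label = light_label),
            class = "aligned_population")
}

#' @export
print.aligned_population <- function(x, ...) {
  cat("Aligned, normalized tuning population:", x$n_units, "units\n")
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.aligned_population <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$octave_offset, y = .data$mean_norm_rate,
                               colour = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_norm_rate - .data$sem,
                                      ymax = .data$mean_norm_rate + .data$sem,
                                      fill = .data$condition),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(control = "black", light = "red"),
                                 aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "octaves from best frequency", y = "normalized firing rate") +
    ggplot2::theme_minimal()
}

#' Offset / divisive-gain decomposition of a silencing effect
#'
#' Under the model `R_light(f) = (R_control(f) - offset) / scale` with shared
#' preferred frequency and width, the closed-form decomposition from two
#' Gaussian fits is `scale = A_control / A_light` and
#' `offset = B_control - scale * B_light`. The normalized offset divides by
#' the control fitted peak (`A_control + B_control`) so the offset is
#' expressed in fractions of the control peak response, matching
#' normalized-population reporting.
#'
#' `method = "joint"` instead regresses the control curve values on the
#' light-on curve values (`R_control = scale * R_light + offset`), a fallback
#' that does not assume shared Gaussian shape.
#'
#' @param control_fit,light_fit `gaussian_fit` objects for the two
#'   conditions (for `method = "closed_form"`), or `tuning_curve`-like data
#'   frames on a common grid (for `method = "joint"`).
#' @param method `"closed_form"` (default) or `"joint"`.
#' @return A one-row tibble: `scale`, `offset` (curve units),
#'   `offset_norm` (fraction of control fitted peak; `NA` for joint fits on
#'   raw curves unless the inputs are already normalized).
#' @export
decompose_gain <- function(control_fit, light_fit,
                           method = c("closed_form", "joint")) {
  method <- match.arg(method)
  if (method == "closed_form") {
    stopifnot(inherits(control_fit, "gaussian_fit"),
              inherits(light_fit, "gaussian_fit"))
    if (!isTRUE(control_fit$included) || !isTRUE(light_fit$included)) {
      abort("both fits must be included (R^2 > threshold) to decompose.",
            class = "striatune_invalid_parameter")
    }
    if (!is.finite(light_fit$A) || light_fit$A <= 0) {
      abort("light-condition amplitude must be positive to define a gain.",
            class = "striatune_undefined_gain")
    }
    scale <- control_fit$A / light_fit$A
    offset <- control_fit$B - scale * light_fit$B
    peak_c <- control_fit$A + control_fit$B
    return(tibble::tibble(scale = scale, offset = offset,
                          offset_norm = offset / peak_c))
  }
  # joint: linear regression of control rates on light rates
  stopifnot(is.data.frame(control_fit), is.data.frame(light_fit))
  merged <- dplyr::inner_join(
    control_fit[, c("freq_khz", "rate_hz")],
    light_fit[, c("freq_khz", "rate_hz")],
    by = "freq_khz", suffix = c("_control", "_light"))
  fit <- stats::lm(rate_hz_control ~ rate_hz_light, data = merged)
  b <- unname(coef(fit))
  if (!is.finite(b[2]) || b[2] <= 0) {
    abort("joint transform fit yielded a non-positive scale.",
          class = "striatune_undefined_gain")
  }
  tibble::tibble(scale = b[2], offset = b[1],
                 offset_norm = b[1] / max(merged$rate_hz_control))
}

#' Apply an offset / divisive-gain transform to a Gaussian fit
#'
#' Returns the `gaussian_fit` describing `(R(f) - offset) / scale`:
#' amplitude `A / scale`, baseline `(B - offset) / scale`, with `f0` and
#' `sigma` unchanged. [decompose_gain()] of a fit and its transformed copy
#' recovers `(offset, scale)` exactly.
#'
#' @param fit A `gaussian_fit`.
#' @param offset Subtractive offset, in the fit's rate units.
#' @param scale Divisive gain (> 0).
#' @return A `gaussian_fit`.
#' @export
apply_transform <- function(fit, offset, scale) {
  stopifnot(inherits(fit, "gaussian_fit"), scale > 0)
  out <- fit
  out$A <- fit$A / scale
  out$B <- (fit$B - offset) / scale
  out$rate_hz <- (fit$rate_hz - offset) / scale
  out
}

#' Normalized rates at the half-octave shoulders of the best frequency
#'
#' Per unit and condition, the normalized rate at +1/2 and -1/2 octave from
#' that condition's best frequency (linear interpolation on the octave axis),
#' averaged over the two sides, with a paired comparison between conditions.
#' Silencing a purely gain-controlling input scales shoulders and peak alike;
#' silencing a tuned input reduces the peak but spares the shoulders.
#'
#' @param aligned An [align_and_normalize()] result.
#' @param shoulder_oct Shoulder distance in octaves (default 0.5).
#' @return A list with `per_unit` (tibble: `unit_id`, condition columns of
#'   mean shoulder rate) and `test` (paired-t tibble from
#'   [compare_sessions()] comparing control vs light shoulder rates).
#' @export
shoulder_rates <- function(aligned, shoulder_oct = 0.5) {
  stopifnot(inherits(aligned, "aligned_population"))
  at_offset <- function(off, rate, x) {
    if (min(off) > -x || max(off) < x) return(NA_real_)
    mean(c(approx(off, rate, xout = -x)$y, approx(off, rate, xout = x)$y))
  }
  per_unit <- aligned$units |>
    dplyr::group_by(.data$unit_id, .data$condition) |>
    dplyr::summarise(shoulder = at_offset(.data$octave_offset, .data$norm_rate,
                                          shoulder_oct),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "shoulder") |>
    tidyr::drop_na()
  ctrl <- per_unit[[aligned$control_label]]
  light <- per_unit[[aligned$light_label]]
  list(per_unit = per_unit,
       test = compare_sessions(ctrl, light))
}
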