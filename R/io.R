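#' Read and validate the pipeline's tabular inputs
#'
#' Comma-separated tables with headers are the package's interchange format:
#' times in seconds, frequencies in kHz, sample indices 0-based. Each reader
#' checks the required columns and basic invariants and reports offending
#' rows by line number.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @name read_tables
NULL

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path), class = "striatune_io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warn(sprintf("%s file '%s' is empty.", what, path))
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s file '%s' is missing columns: %s",
                  what, path, paste(missing, collapse = ", ")),
          class = "striatune_io")
  }
  tibble::as_tibble(df)
}

#' @rdname read_tables
#' @export
read_spike_table <- function(path) {
  df <- read_csv_checked(path, c("unit_id", "spike_time_s"), "spike")
  bad <- which(!is.finite(df$spike_time_s))
  if (length(bad) > 0L) {
    abort(sprintf("non-finite spike times at data rows: %s",
                  paste(head(bad, 5), collapse = ", ")), class = "striatune_io")
  }
  df
}

#' @rdname read_tables
#' @export
read_trial_table <- function(path) {
  df <- read_csv_checked(
    path, c("trial_id", "onset_s", "freq_khz", "intensity_db", "duration_s", "light_on"),
    "trial")
  if (nrow(df) > 1L && any(diff(df$onset_s) < 0)) {
    abort("trial onsets must be non-decreasing.", class = "striatune_io")
  }
  df$light_on <- as.logical(df$light_on)
  if (any(is.na(df$light_on))) {
    abort("`light_on` must be logical (TRUE/FALSE or 0/1).", class = "striatune_io")
  }
  df
}

#' @rdname read_tables
#' @export
read_waveform_table <- function(path) {
  read_csv_checked(path, c("unit_id", "sample_index", "amplitude_uv"), "waveform")
}

#' @rdname read_tables
#' @export
read_unit_table <- function(path) {
  read_csv_checked(path, c("unit_id", "sample_rate_hz"), "unit")
}

#' @rdname read_tables
#' @export
read_behavior_table <- function(path) {
  df <- read_csv_checked(
    path, c("trial_id", "r", "choice", "correct", "reaction_time_s", "reported"),
    "behavior")
  ok <- df$choice %in% c("left", "right", "none")
  if (!all(ok)) {
    abort(sprintf("unknown choice labels at data rows: %s",
                  paste(head(which(!ok), 5), collapse = ", ")),
          class = "striatune_io")
  }
  df$reported <- as.logical(df$reported)
  df$correct <- as.logical(df$correct)
  df
}

#' Write a synthetic recording to a directory of CSV tables
#'
#' Emits `trials.csv`, `spikes.csv`, `waveforms.csv` and `units.csv` in the
#' formats the readers consume. Identical specs and seeds produce
#' byte-identical files.
#'
#' @param recording A [simulate_recording()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(recording$trials, "trials.csv")
  wr(recording$spikes, "spikes.csv")
  wr(recording$waveforms, "waveforms.csv")
  wr(recording$units, "units.csv")
  invisible(dir)
}

#' Read a recording bundle written by [write_recording()]
#'
#' @param dir Directory containing `trials.csv`, `spikes.csv`,
#'   `waveforms.csv`, `units.csv`.
#' @return A list with tibbles `trials`, `spikes`, `waveforms`, `units`.
#' @export
read_recording <- function(dir) {
  list(trials = read_trial_table(file.path(dir, "trials.csv")),
       spikes = read_spike_table(file.path(dir, "spikes.csv")),
       waveforms = read_waveform_table(file.path(dir, "waveforms.csv")),
       units = read_unit_table(file.path(dir, "units.csv")))
}

#' Pipeline configuration
#'
#' Collects every analysis constant in one place: classification thresholds,
#' PSTH geometry, response-detection multipliers, smoothing, and the
#' Gaussian-fit inclusion threshold.
#'
#' @param psth_window_s,psth_step_s PSTH sliding-window width and step (s).
#' @param fs_max_us,chi_min_us Cell-class boundaries (microseconds).
#' @param excite_sd,suppress_sd Detection multipliers (baseline SDs).
#' @param sd_floor_hz Baseline-SD floor (Hz).
#' @param min_run Minimum supra-threshold run length, in PSTH bins, for a
#'   valid response window. The default (4 bins at a 1-ms step) requires the
#'   crossing to outlast one 3-ms window width, so an isolated spike cluster
#'   inside a single window cannot create a spurious response.
#' @param sg_span,sg_order Savitzky-Golay window (points) and order.
#' @param r2_threshold Gaussian-fit inclusion threshold.
#' @param seed Integer seed for any stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(psth_window_s = 0.003, psth_step_s = 0.001,
                            fs_max_us = 100, chi_min_us = 150,
                            excite_sd = 3, suppress_sd = 2,
                            sd_floor_hz = 0.1, min_run = 4L,
                            sg_span = 5L, sg_order = 2L,
                            r2_threshold = 0.4, seed = 1L) {
  stopifnot(psth_window_s > 0, psth_step_s > 0, fs_max_us > 0,
            chi_min_us > fs_max_us, excite_sd > 0, suppress_sd > 0,
            r2_threshold >= 0, r2_threshold <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full single-unit analysis pipeline
#'
#' For every unit: classify the waveform; determine tone-responsiveness per
#' intensity from control (light-off) trials pooled over frequencies; pick
#' the analysis intensity (60 dB if responsive there, else 70 dB); build
#' baseline-subtracted tuning curves for control and light-on trials using
#' the control-condition response window; fit Gaussians to both; and, for
#' units tuned (R^2 above threshold) in both conditions, decompose the
#' silencing effect into a subtractive offset and a divisive gain. The
#' population result aligns curves to per-condition best frequencies,
#' normalizes to the control peak, and tests the half-octave shoulders.
#'
#' @param data A `recording` (from [simulate_recording()]) or a list with
#'   tibbles `trials`, `spikes`, `waveforms`, `units` (e.g. from
#'   [read_recording()]).
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with tibbles: `units`
#'   (classification + responsiveness + analysis intensity), `responses`
#'   (per unit x intensity response profiles at control trials), `tuning`
#'   (long per-unit curves, both conditions), `fits` (per unit x condition
#'   Gaussian parameters), `transforms` (per-unit offset/scale),
#'   `transform_summary` (population mean +/- SEM), `population` (aligned,
#'   normalized summary), `shoulders`, and `class_summary`.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  trials <- data$trials
  spikes <- data$spikes
  dur <- unique(trials$duration_s)
  stopifnot(length(dur) == 1L)

  units <- classify_units(data$waveforms, data$units,
                          config$fs_max_us, config$chi_min_us)

  spike_by_unit <- split(spikes$spike_time_s, spikes$unit_id)
  has_light <- any(trials$light_on)
  ctrl_trials <- trials[!trials$light_on, , drop = FALSE]

  per_unit <- lapply(units$unit_id, function(uid) {
    sp <- spike_by_unit[[as.character(uid)]]
    if (is.null(sp)) sp <- numeric(0)

    # responsiveness per intensity, control trials pooled over frequency
    resp_by_int <- purrr::map_dfr(sort(unique(ctrl_trials$intensity_db)), function(db) {
      tr <- ctrl_trials[ctrl_trials$intensity_db == db, , drop = FALSE]
      prof <- response_profile(sp, tr$onset_s, dur,
                               window_width_s = config$psth_window_s,
                               step_s = config$psth_step_s,
                               excite_sd = config$excite_sd,
                               suppress_sd = config$suppress_sd,
                               sd_floor_hz = config$sd_floor_hz,
                               min_run = config$min_run)
      dplyr::mutate(prof, unit_id = uid, intensity_db = db, .before = 1)
    })
    intensity <- select_analysis_intensity(resp_by_int)

    tuning <- NULL
    fits <- NULL
    transform <- NULL
    if (!is.na(intensity)) {
      row <- resp_by_int[resp_by_int$intensity_db == intensity, ]
      window <- list(start_s = row$window_start_s[1], end_s = row$window_end_s[1])
      curves <- lapply(c(control = FALSE, light = TRUE), function(light) {
        tr <- trials[trials$light_on == light & trials$intensity_db == intensity, ,
                     drop = FALSE]
        if (nrow(tr) == 0L) return(NULL)
        build_tuning_curve(sp, tr, window, window_width_s = config$psth_window_s)
      })
      tuning <- purrr::imap_dfr(purrr::compact(curves), function(cv, cond) {
        dplyr::mutate(cv, unit_id = uid, condition = cond, .before = 1)
      })
      fits <- purrr::imap_dfr(purrr::compact(curves), function(cv, cond) {
        f <- fit_gaussian(cv, r2_threshold = config$r2_threshold)
        tibble::tibble(unit_id = uid, condition = cond,
                       A = f$A, f0_log2khz = f$f0, sigma_oct = f$sigma, B = f$B,
                       r2 = f$r_squared, included = f$included,
                       best_freq_khz = f$best_freq_khz,
                       tuning_width_oct = tryCatch(
                         as.numeric(tuning_width(smooth_curve(
                           cv, config$sg_span, config$sg_order))),
                         error = function(e) NA_real_))
      })
      if (has_light && !is.null(curves$control) && !is.null(curves$light)) {
        # transform from the shared-shape fit (the decomposition's model)
        sh <- fit_gaussian_shared(curves$control, curves$light,
                                  r2_threshold = config$r2_threshold)
        if (isTRUE(sh$converged) && isTRUE(sh$control$included) &&
            isTRUE(sh$light$included) && sh$light$A > 0) {
          transform <- dplyr::mutate(decompose_gain(sh$control, sh$light),
                                     unit_id = uid, .before = 1)
        }
      }
    }
    list(resp = resp_by_int, intensity = intensity, tuning = tuning,
         fits = fits, transform = transform)
  })

  responses <- purrr::map_dfr(per_unit, "resp")
  units$analysis_intensity_db <- vapply(per_unit, function(x) x$intensity, numeric(1))
  units$responsive <- !is.na(units$analysis_intensity_db)
  tuning <- purrr::map_dfr(per_unit, "tuning")
  fits <- purrr::map_dfr(per_unit, "fits")
  transforms <- purrr::map_dfr(per_unit, "transform")

  transform_summary <- if (nrow(transforms) > 0L) {
    tibble::tibble(
      n_units = nrow(transforms),
      mean_scale = mean(transforms$scale),
      sd_scale = sd(transforms$scale),
      mean_offset_norm = mean(transforms$offset_norm),
      sd_offset_norm = sd(transforms$offset_norm))
  } else tibble::tibble(n_units = 0L, mean_scale = NA_real_, sd_scale = NA_real_,
                        mean_offset_norm = NA_real_, sd_offset_norm = NA_real_)

  population <- NULL
  shoulders <- NULL
  if (has_light && nrow(tuning) > 0L && dplyr::n_distinct(tuning$condition) == 2L) {
    population <- align_and_normalize(tuning)
    shoulders <- tryCatch(shoulder_rates(population), error = function(e) NULL)
  }

  structure(list(units = units, responses = responses, tuning = tuning,
                 fits = fits, transforms = transforms,
                 transform_summary = transform_summary,
                 population = population, shoulders = shoulders,
                 class_summary = class_count_summary(units),
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("striatune pipeline result\n")
  cat("  units:", nrow(x$units), "(", sum(x$units$responsive), "tone-responsive )\n")
  print(x$class_summary)
  if (nrow(x$transforms) > 0L) {
    cat(sprintf("  population transform: scale %.2f +/- %.2f, offset %.3f +/- %.3f (n = %d)\n",
                x$transform_summary$mean_scale,
                x$transform_summary$sd_scale / sqrt(x$transform_summary$n_units),
                x$transform_summary$mean_offset_norm,
                x$transform_summary$sd_offset_norm / sqrt(x$transform_summary$n_units),
                x$transform_summary$n_units))
  }
  invisible(x)
}
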