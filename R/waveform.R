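#' Half-valley width of a spike waveform
#'
#' Width of the waveform trough at half of its depth, in microseconds. The
#' trough is the global minimum; its depth is measured from the pre-trough
#' baseline (the mean of all samples preceding the onset of the descent into
#' the trough, i.e. the nearest point to the left of the minimum where the
#' waveform stops being non-increasing). The two half-depth crossings
#' bracketing the minimum are located with linear interpolation between
#' samples, which resolves widths well below one sample period.
#'
#' @param samples Numeric vector: the mean spike waveform (arbitrary
#'   amplitude units; the measure is amplitude-invariant).
#' @param sample_rate_hz Sampling rate of `samples`, in Hz.
#' @return Width in microseconds (a single positive number).
#' @examples
#' t_us <- seq(-400, 400, by = 10)
#' wf <- -80 * exp(-0.5 * (t_us / 50)^2)   # Gaussian trough, sigma 50 us
#' half_valley_width(wf, 1e5)              # ~ 2 * 50 * sqrt(2 log 2)
#' @export
half_valley_width <- function(samples, sample_rate_hz) {
  stopifnot(is.numeric(samples), length(samples) >= 5, sample_rate_hz > 0)
  m <- which.min(samples)
  if (m <= 1L || m >= length(samples)) {
    abort("no interior trough in waveform.", class = "striatune_no_valley")
  }
  # onset of the descent: walk left while the waveform is non-increasing
  i <- m
  while (i > 1L && samples[i - 1L] >= samples[i]) i <- i - 1L
  baseline <- mean(samples[seq_len(i)])
  depth <- baseline - samples[m]
  if (depth <= 0) {
    abort("waveform has no negative trough relative to its baseline.",
          class = "striatune_no_valley")
  }
  half_level <- baseline - depth / 2

  # left crossing: last sample at/above the half level before the minimum
  j <- m
  while (j > 1L && samples[j] < half_level) j <- j - 1L
  if (samples[j] < half_level) {
    abort("waveform never reaches the half-depth level left of the trough.",
          class = "striatune_no_valley")
  }
  t_left <- j + (samples[j] - half_level) / (samples[j] - samples[j + 1L])

  # right crossing: first sample at/above the half level after the minimum
  k <- m
  while (k < length(samples) && samples[k] < half_level) k <- k + 1L
  if (samples[k] < half_level) {
    abort("trough does not recover to the half-depth level.",
          class = "striatune_no_valley")
  }
  t_right <- k - (samples[k] - half_level) / (samples[k] - samples[k - 1L])

  (t_right - t_left) / sample_rate_hz * 1e6
}

#' Classify a striatal single unit by half-valley width
#'
#' Striatal cell types are assigned from the spike half-valley width:
#' fast-spiking interneurons (`FS`) below 100 microseconds, cholinergic
#' interneurons (`ChI`) above 150 microseconds, and putative medium spiny
#' neurons (`MSN`) in between. "Between 100 and 150" is read as inclusive, so
#' widths of exactly 100 or 150 microseconds are MSN; the outer rules are
#' strict inequalities.
#'
#' @param width_us Numeric vector of half-valley widths in microseconds.
#' @param fs_max_us,chi_min_us Class boundaries (defaults 100 and 150).
#' @return Factor with levels `c("FS", "MSN", "ChI")`.
#' @examples
#' classify_unit(c(90, 100, 120, 150, 160))
#' @export
classify_unit <- function(width_us, fs_max_us = 100, chi_min_us = 150) {
  if (any(!is.finite(width_us)) || any(width_us <= 0)) {
    abort("half-valley widths must be positive and finite.",
          class = "striatune_invalid_parameter")
  }
  cls <- ifelse(width_us < fs_max_us, "FS",
                ifelse(width_us > chi_min_us, "ChI", "MSN"))
  factor(cls, levels = c("FS", "MSN", "ChI"))
}

#' Classify a table of unit waveforms
#'
#' Data-frame interface over [half_valley_width()] and [classify_unit()]:
#' takes long-format waveforms plus per-unit sampling rates and returns one
#' row per unit.
#'
#' @param waveforms Data frame with columns `unit_id`, `sample_index`
#'   (0-based), `amplitude_uv`.
#' @param units Data frame with columns `unit_id`, `sample_rate_hz`.
#' @inheritParams classify_unit
#' @return Tibble with columns `unit_id`, `half_valley_width_us`,
#'   `cell_class`.
#' @export
classify_units <- function(waveforms, units, fs_max_us = 100, chi_min_us = 150) {
  stopifnot(all(c("unit_id", "sample_index", "amplitude_uv") %in% names(waveforms)),
            all(c("unit_id", "sample_rate_hz") %in% names(units)))
  out <- waveforms |>
    dplyr::arrange(.data$unit_id, .data$sample_index) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(samples = list(.data$amplitude_uv), .groups = "drop") |>
    dplyr::inner_join(units[, c("unit_id", "sample_rate_hz")], by = "unit_id")
  out$half_valley_width_us <- purrr::map2_dbl(
    out$samples, out$sample_rate_hz, half_valley_width)
  out$cell_class <- classify_unit(out$half_valley_width_us, fs_max_us, chi_min_us)
  out[, c("unit_id", "half_valley_width_us", "cell_class")]
}

#' Cell-class counts and percentages for a recorded population
#'
#' Tabulates classified units and reports, per class, the count, the percent
#' of all units, the number tone-responsive, and the percent of that class
#' responding — the population summary typically reported for striatal
#' tetrode datasets.
#'
#' @param units Data frame with a `cell_class` column and (optionally) a
#'   logical `responsive` column.
#' @return Tibble with one row per class plus a `total` row.
#' @export
class_count_summary <- function(units) {
  stopifnot("cell_class" %in% names(units))
  if (!"responsive" %in% names(units)) units$responsive <- NA
  by_class <- units |>
    dplyr::group_by(cell_class = factor(.data$cell_class, levels = c("MSN", "FS", "ChI"))) |>
    dplyr::summarise(n = dplyr::n(),
                     n_responsive = sum(.data$responsive),
                     .groups = "drop") |>
    tidyr::complete(.data$cell_class, fill = list(n = 0L, n_responsive = 0L))
  total <- tibble::tibble(cell_class = factor("total"),
                          n = sum(by_class$n),
                          n_responsive = sum(by_class$n_responsive))
  out <- dplyr::bind_rows(by_class |> dplyr::mutate(cell_class = factor(.data$cell_class)),
                          total)
  out$pct_of_all <- 100 * out$n / sum(by_class$n)
  out$pct_responsive <- 100 * out$n_responsive / out$n
  out
}
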