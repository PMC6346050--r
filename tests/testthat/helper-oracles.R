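# Independent brute-force oracles and small constructors shared across tests.
# These deliberately re-implement the detection/taxonomy rules with different
# mechanics (index scans instead of rle) so they can cross-check the package.

# build a psth object directly from a rate vector (window-start indexing)
make_psth <- function(rate_hz, tone_duration_s = 0.1,
                      window_width_s = 0.003, step_s = 0.001,
                      pre_s = 0.1, post_s = 0.2, n_trials = 100L) {
  starts <- seq(-pre_s, tone_duration_s + post_s - window_width_s + 1e-12,
                by = step_s)
  if (length(rate_hz) == 1L) rate_hz <- rep(rate_hz, length(starts))
  stopifnot(length(rate_hz) == length(starts))
  out <- tibble::tibble(time_s = starts, rate_hz = rate_hz)
  structure(out, window_width_s = window_width_s, step_s = step_s,
            n_trials = n_trials, tone_duration_s = tone_duration_s,
            class = c("psth", class(out)))
}

# verbatim threshold scan: earliest contiguous run of bins beyond threshold,
# excitatory (> mean + 3 SD) first, else suppressive (< mean - 2 SD)
oracle_window <- function(time_s, rate_hz, mean_hz, sd_hz, tone_duration_s,
                          excite_sd = 3, suppress_sd = 2, sd_floor_hz = 0.1,
                          min_run = 1L) {
  sde <- max(sd_hz, sd_floor_hz)
  elig <- time_s >= -1e-12 & time_s <= tone_duration_s + 0.2 + 1e-12
  earliest_run <- function(flag) {
    idx <- which(flag & elig)
    if (length(idx) == 0L) return(NULL)
    groups <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    for (g in groups) {
      if (length(g) >= min_run) return(c(g[1L], g[length(g)]))
    }
    NULL
  }
  run <- earliest_run(rate_hz > mean_hz + excite_sd * sde)
  dir <- "excited"
  if (is.null(run)) {
    run <- earliest_run(rate_hz < mean_hz - suppress_sd * sde)
    dir <- "suppressed"
  }
  if (is.null(run)) return(NULL)
  list(start_s = time_s[run[1L]], end_s = time_s[run[2L]], direction = dir)
}

# verbatim four-class taxonomy with the documented precedence
oracle_classify <- function(win, tone_duration_s) {
  if (is.null(win)) return("none")
  if (win$direction == "suppressed") return("suppression")
  if (win$start_s >= tone_duration_s - 1e-12) {
    if (win$start_s < tone_duration_s + 0.020 - 1e-12) return("offset")
    return("sustained")
  }
  if (win$end_s < 0.050 - 1e-12) return("onset")
  "sustained"
}

# random synthetic PSTH for the threshold-crossing cross-check: baseline noise
# plus, with 2/3 probability, an inserted elevation or dip at a random time
random_psth_case <- function(seed) {
  set.seed(seed)
  dur <- sample(c(0.05, 0.1, 0.15), 1)
  starts <- seq(-0.1, dur + 0.2 - 0.003 + 1e-12, by = 0.001)
  m <- runif(1, 2, 20)
  s <- runif(1, 0.3, 3)
  rate <- pmax(rnorm(length(starts), m, s * runif(1, 0.2, 1.1)), 0)
  kind <- sample(c("none", "excite", "suppress"), 1)
  if (kind != "none") {
    t0 <- runif(1, -0.05, dur + 0.15)
    len <- sample(1:40, 1)
    i0 <- which.min(abs(starts - t0))
    idx <- i0:min(i0 + len - 1L, length(starts))
    if (kind == "excite") {
      rate[idx] <- rate[idx] + runif(1, 3, 8) * s
    } else {
      rate[idx] <- pmax(rate[idx] - runif(1, 2.5, 6) * s, 0)
    }
  }
  list(psth = make_psth(rate, tone_duration_s = dur),
       baseline = list(mean_hz = m, sd_hz = s),
       tone_duration_s = dur)
}

# population spec used in the silencing recovery experiments
pathway_population <- function(modulation, seed, n_units = 25L) {
  silencing_population_spec(modulation, seed, n_units = n_units)
}

# peak (offset 0) paired comparison from a pipeline result
peak_comparison <- function(result) {
  pk <- result$population$units
  pk0 <- pk[abs(pk$octave_offset) < 1e-9, ]
  w0 <- tidyr::pivot_wider(pk0, names_from = "condition", values_from = "norm_rate")
  w0 <- tidyr::drop_na(w0)
  compare_sessions(w0$control, w0$light)
}
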