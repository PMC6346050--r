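test_that("PSTH rates equal hand counts in sliding windows", {
  psth <- compute_psth(c(0.001, 0.002), tone_onsets = 0, tone_duration_s = 0.1)
  expect_equal(psth$rate_hz[psth$time_s == 0], 2 / 0.003, tolerance = 1e-9)
  # axis spans -100 ms to tone end + 200 ms in window starts
  expect_equal(min(psth$time_s), -0.1)
  expect_equal(max(psth$time_s), 0.1 + 0.2 - 0.003, tolerance = 1e-9)
  # no spikes -> all-zero PSTH
  z <- compute_psth(numeric(0), tone_onsets = c(0, 2), tone_duration_s = 0.1)
  expect_true(all(z$rate_hz == 0))
  expect_error(compute_psth(1, numeric(0), 0.1), class = "striatune_empty_input")
})

test_that("a homogeneous Poisson train gives a flat PSTH at its rate", {
  set.seed(71)
  onsets <- seq(1, by = 2, length.out = 500)
  spikes <- sort(runif(round(20 * 2 * 500), 0, max(onsets) + 1))  # 20 Hz
  psth <- compute_psth(spikes, onsets, tone_duration_s = 0.1)
  # per-bin SD ~ 3.7 Hz; ~130 independent (non-overlapping) bins -> 3 SE ~ 1 Hz
  expect_lt(abs(mean(psth$rate_hz) - 20), 1)
  # integral conservation: sum(rate) * step ~ spikes per trial over the span
  span_spikes <- sum(vapply(onsets, function(on)
    sum(spikes >= on - 0.1 & spikes < on + 0.3), numeric(1)))
  expect_equal(sum(psth$rate_hz) * attr(psth, "step_s"),
               span_spikes / 500, tolerance = 0.05)
})

test_that("baseline statistics use only fully pre-onset windows", {
  psth <- make_psth(10)
  bl <- baseline_stats(psth)
  expect_equal(bl$mean_hz, 10)
  expect_equal(bl$sd_hz, 0)
  # {8, 10, 12} pattern: textbook mean and SD
  rates <- rep(10, length(psth$time_s))
  base_idx <- which(psth$time_s >= -0.05 & psth$time_s + 0.003 <= 0)
  rates[base_idx] <- rep(c(8, 10, 12), length.out = length(base_idx))
  bl2 <- baseline_stats(make_psth(rates))
  expect_equal(bl2$mean_hz, 10, tolerance = 0.05)
  expect_equal(bl2$sd_hz, sd(rates[base_idx]))
  # every baseline window must end at or before the tone onset
  expect_true(all(psth$time_s[base_idx] + 0.003 <= 0 + 1e-12))
})

test_that("response windows are the earliest post-onset threshold crossing", {
  psth <- make_psth(5)
  t <- psth$time_s
  rates <- rep(5, length(t))
  # elevation 10-40 ms at 10 Hz over baseline mean 5, SD 1 -> threshold 8
  rates[t >= 0.010 - 1e-9 & t <= 0.040 + 1e-9] <- 10
  win <- detect_response_window(make_psth(rates), list(mean_hz = 5, sd_hz = 1))
  expect_equal(win$start_s, 0.010, tolerance = 1e-6)
  expect_equal(win$end_s, 0.040, tolerance = 1e-6)
  expect_equal(win$latency_s, win$start_s)
  expect_equal(win$direction, "excited")

  # flat PSTH -> none
  expect_null(detect_response_window(make_psth(5),
                                     list(mean_hz = 5, sd_hz = 1)))
  # elevation entirely before tone onset -> none
  pre <- rep(5, length(t))
  pre[t >= -0.08 & t <= -0.02] <- 20
  expect_null(detect_response_window(make_psth(pre), list(mean_hz = 5, sd_hz = 1)))
  # SD floor suppresses spurious windows on silent baselines
  tiny <- rep(0, length(t))
  tiny[t >= 0.01 & t <= 0.02] <- 0.2
  expect_null(detect_response_window(make_psth(tiny), list(mean_hz = 0, sd_hz = 0)))
})

test_that("suppressive crossings are found when no excitatory window exists", {
  psth0 <- make_psth(10)
  t <- psth0$time_s
  rates <- rep(10, length(t))
  rates[t >= 0.02 & t <= 0.08] <- 2   # below 10 - 2*2 = 6
  win <- detect_response_window(make_psth(rates), list(mean_hz = 10, sd_hz = 2))
  expect_equal(win$direction, "suppressed")
  expect_equal(classify_response(win, 0.1), "suppression")
  expect_lt(response_rate(make_psth(rates), win, list(mean_hz = 10, sd_hz = 2)), 0)
})

test_that("the four response classes follow the timing rules", {
  mk <- function(a, b) list(start_s = a, end_s = b, direction = "excited",
                            latency_s = a)
  expect_equal(classify_response(mk(0.010, 0.045), 0.1), "onset")
  expect_equal(classify_response(mk(0.020, 0.080), 0.1), "sustained")
  expect_equal(classify_response(mk(0.105, 0.115), 0.1), "offset")
  expect_equal(classify_response(NULL, 0.1), "none")
  # boundaries: end exactly 50 ms -> sustained; start exactly at end + 20 ms
  # -> not offset
  expect_equal(classify_response(mk(0.010, 0.050), 0.1), "sustained")
  expect_equal(classify_response(mk(0.120, 0.130), 0.1), "sustained")
  # suppression wins regardless of timing
  sup <- list(start_s = 0.03, end_s = 0.06, direction = "suppressed",
              latency_s = 0.03)
  expect_equal(classify_response(sup, 0.1), "suppression")
})

test_that("response rate is the baseline-subtracted in-window mean", {
  psth0 <- make_psth(5)
  t <- psth0$time_s
  rates <- rep(5, length(t))
  rates[t >= 0.010 & t <= 0.040] <- 15
  psth <- make_psth(rates)
  bl <- list(mean_hz = 5, sd_hz = 1)
  win <- detect_response_window(psth, bl)
  expect_equal(response_rate(psth, win, bl), 10, tolerance = 1e-9)
})

test_that("detection and taxonomy agree with a brute-force scan on random PSTHs", {
  for (seed in 1:400) {
    cs <- random_psth_case(seed)
    bl <- cs$baseline
    got <- detect_response_window(cs$psth, bl)
    want <- oracle_window(cs$psth$time_s, cs$psth$rate_hz, bl$mean_hz, bl$sd_hz,
                          cs$tone_duration_s)
    if (is.null(want)) {
      expect_null(got, label = sprintf("seed %d", seed))
    } else {
      expect_equal(got[c("start_s", "end_s", "direction")], want,
                   label = sprintf("seed %d", seed))
      expect_equal(classify_response(got, cs$tone_duration_s),
                   oracle_classify(want, cs$tone_duration_s),
                   label = sprintf("seed %d taxonomy", seed))
    }
  }
})

test_that("units simulated with each kernel class are labeled with that class", {
  freqs <- 2 * 2^seq(0, 4.5, by = 0.25)
  set.seed(99)
  n <- 150  # suppression needs enough trials for the 2-SD floor to bite
  trials <- tibble::tibble(
    trial_id = 1:n,
    onset_s = 1 + (0:(n - 1)) * 2,
    freq_khz = sample(freqs[8:12], n, replace = TRUE),  # near default BF
    intensity_db = 60, duration_s = 0.1, light_on = FALSE)
  cases <- list(
    onset = unit_spec(response_kernel = "onset", latency_s = 0.012),
    sustained = unit_spec(response_kernel = "sustained", latency_s = 0.015),
    offset = unit_spec(response_kernel = "offset", latency_s = 0.008),
    suppression = unit_spec(response_kernel = "suppression",
                            baseline_rate_hz = 15, suppression_depth = 0.9))
  n_rep <- 20
  for (kern in names(cases)) {
    hits <- vapply(seq_len(n_rep), function(i) {
      sp <- simulate_unit_trials(cases[[kern]], trials, seed = 7000 + 13 * i)
      prof <- response_profile(sp$spike_time_s, trials$onset_s, 0.1, min_run = 4)
      prof$response_type == kern
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }
})

test_that("latencies fall within the analysis span", {
  set.seed(101)
  freqs <- 2 * 2^seq(0, 4.5, by = 0.25)
  trials <- tibble::tibble(trial_id = 1:60, onset_s = 1 + (0:59) * 2,
                           freq_khz = sample(freqs[7:13], 60, replace = TRUE),
                           intensity_db = 60, duration_s = 0.1, light_on = FALSE)
  sp <- simulate_unit_trials(unit_spec(), trials, seed = 5)
  prof <- response_profile(sp$spike_time_s, trials$onset_s, 0.1, min_run = 4)
  expect_true(prof$responsive)
  expect_gte(prof$latency_s, 0)
  expect_lte(prof$latency_s, 0.1 + 0.2)
})
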