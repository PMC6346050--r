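test_that("analysis intensity is the lower responsive of 60 and 70 dB, never 50", {
  mk <- function(r50, r60, r70) tibble::tibble(intensity_db = c(50, 60, 70),
                                               responsive = c(r50, r60, r70))
  expect_equal(select_analysis_intensity(mk(TRUE, TRUE, TRUE)), 60)
  expect_equal(select_analysis_intensity(mk(FALSE, FALSE, TRUE)), 70)
  expect_true(is.na(select_analysis_intensity(mk(TRUE, FALSE, FALSE))))
})

test_that("best frequency is the argmax with low-frequency tie-break", {
  curve <- tibble::tibble(freq_khz = c(4, 8, 16, 32), rate_hz = c(1, 9, 3, 2))
  expect_equal(best_frequency(curve), 8)
  tie <- tibble::tibble(freq_khz = c(4, 8, 16, 32), rate_hz = c(1, 9, 9, 2))
  expect_equal(best_frequency(tie), 8)
  # invariant under positive rescaling
  expect_equal(best_frequency(dplyr::mutate(curve, rate_hz = rate_hz * 7.3)), 8)
  # seeded noisy curve equals brute-force argmax
  set.seed(55)
  r <- rnorm(19)
  f <- 2 * 2^seq(0, 4.5, by = 0.25)
  expect_equal(best_frequency(r, f), f[which.max(r)])
})

test_that("Savitzky-Golay smoothing reproduces polynomials and the closed-form kernel", {
  expect_equal(smooth_curve(rep(3, 11)), rep(3, 11), tolerance = 1e-10)
  x <- 1:11
  quad <- 2 + 0.5 * x - 0.3 * x^2
  expect_equal(smooth_curve(quad), quad, tolerance = 1e-8)
  # impulse response: central coefficients (-3, 12, 17, 12, -3)/35
  imp <- c(rep(0, 5), 1, rep(0, 5))
  expect_equal(smooth_curve(imp)[4:8], c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-10)
  expect_error(smooth_curve(1:4), class = "striatune_insufficient_coverage")
})

test_that("tuning width matches half-peak geometry", {
  # linear (in log2 f) fall from 10 at the peak to 0 at +-1 octave: width 1
  x <- seq(-1.5, 1.5, by = 0.125)
  rates <- pmax(10 * (1 - abs(x)), 0)
  w <- tuning_width(rates, freqs_khz = 16 * 2^x)
  expect_equal(as.numeric(w), 1, tolerance = 1e-9)
  expect_false(attr(w, "truncated"))

  # rectangular one-octave plateau
  plateau <- ifelse(abs(x) <= 0.5, 10, 0)
  wp <- tuning_width(plateau, freqs_khz = 16 * 2^x)
  expect_equal(as.numeric(wp), 2 * (0.5 + 0.125 / 2), tolerance = 1e-9)

  # Gaussian: width = 2 * sigma * sqrt(2 log 2)
  g <- 10 * exp(-0.5 * (x / 0.5)^2)
  wg <- tuning_width(g, freqs_khz = 16 * 2^x)
  expect_equal(as.numeric(wg), 2 * 0.5 * sqrt(2 * log(2)), tolerance = 0.02)

  # truncation at the grid edge is flagged
  wt <- tuning_width(10 * exp(-0.5 * (x / 5)^2), freqs_khz = 16 * 2^x)
  expect_true(attr(wt, "truncated"))

  # multiplicative rescaling leaves the width unchanged
  expect_equal(as.numeric(tuning_width(3.7 * g, freqs_khz = 16 * 2^x)),
               as.numeric(wg), tolerance = 1e-12)

  # grid refinement changes the width only within interpolation tolerance
  xf <- seq(-1.5, 1.5, by = 0.03125)
  wf <- tuning_width(10 * exp(-0.5 * (xf / 0.5)^2), freqs_khz = 16 * 2^xf)
  expect_equal(as.numeric(wf), as.numeric(wg), tolerance = 0.01)
})

test_that("noiseless Gaussian samples are recovered to high precision", {
  f <- 2 * 2^seq(0, 4.5, by = 0.25)
  x <- log2(f)
  truth <- c(A = 10, f0 = log2(16), sigma = 0.5, B = 2)
  rates <- truth["A"] * exp(-0.5 * (x - truth["f0"])^2 / truth["sigma"]^2) + truth["B"]
  fit <- fit_gaussian(rates, freqs_khz = f)
  expect_true(fit$included)
  expect_gt(fit$r_squared, 0.9999)
  expect_equal(fit$A, 10, tolerance = 1e-4)
  expect_equal(fit$f0, log2(16), tolerance = 1e-4)
  expect_equal(fit$sigma, 0.5, tolerance = 1e-4)
  expect_equal(fit$B, 2, tolerance = 1e-4)
  expect_equal(fit$best_freq_khz, 16, tolerance = 1e-3)
})

test_that("a flat noisy curve is excluded by the R^2 criterion", {
  set.seed(61)
  f <- 2 * 2^seq(0, 4.5, by = 0.25)
  fit <- fit_gaussian(rnorm(19, 0, 1), freqs_khz = f)
  expect_false(fit$included)
})

test_that("fit recovery improves with trials per frequency", {
  freqs <- 2 * 2^seq(0, 4.5, by = 0.25)
  spec <- unit_spec(tuning = c(A = 50, f0 = 3.2, sigma = 0.6, B = 3),
                    response_kernel = "sustained")
  win <- list(start_s = spec$latency_s, end_s = spec$latency_s + 0.085 - 0.003)
  med_err <- vapply(c(5, 20, 80), function(n) {
    errs <- vapply(1:6, function(i) {
      set.seed(3000 + 100 * n + i)
      trials <- tibble::tibble(
        trial_id = seq_len(n * length(freqs)),
        onset_s = 1 + (seq_len(n * length(freqs)) - 1) * 2,
        freq_khz = rep(freqs, n), intensity_db = 60, duration_s = 0.1,
        light_on = FALSE)
      sp <- simulate_unit_trials(spec, trials, seed = 3000 + 100 * n + i)
      fit <- fit_gaussian(build_tuning_curve(sp$spike_time_s, trials, win))
      abs(fit$A - 50) / 50
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(med_err[3], med_err[1])  # monotone improvement, large-n vs small-n
  expect_lt(med_err[2], 0.15)
})

test_that("aligned population normalizes to the control peak", {
  f <- 2 * 2^seq(0, 4.5, by = 0.25)
  x <- log2(f)
  base <- 10 * exp(-0.5 * (x - 2.5)^2 / 0.36)
  curves <- dplyr::bind_rows(
    tibble::tibble(unit_id = 1, condition = "control", freq_khz = f, rate_hz = base),
    tibble::tibble(unit_id = 1, condition = "light", freq_khz = f, rate_hz = base))
  al <- align_and_normalize(curves)
  s <- al$summary
  expect_equal(s$mean_norm_rate[s$condition == "control" & s$octave_offset == 0], 1)
  expect_equal(s$mean_norm_rate[s$condition == "light" & s$octave_offset == 0], 1)
  # halved light condition gives exactly half the control curve
  curves$rate_hz[curves$condition == "light"] <- base / 2
  al2 <- align_and_normalize(curves)
  m <- tidyr::pivot_wider(al2$summary[, c("condition", "octave_offset", "mean_norm_rate")],
                          names_from = "condition", values_from = "mean_norm_rate")
  m <- tidyr::drop_na(m)
  expect_equal(m$light, m$control / 2, tolerance = 1e-10)
  # non-positive control peaks are excluded
  curves$rate_hz[curves$condition == "control"] <- -1
  expect_equal(align_and_normalize(curves)$excluded, 1)
})

test_that("gain decomposition is exact algebra and inverts apply_transform", {
  mk_fit <- function(A, f0, sigma, B) {
    f <- 2 * 2^seq(0, 4.5, by = 0.25)
    rates <- A * exp(-0.5 * (log2(f) - f0)^2 / sigma^2) + B
    fit_gaussian(rates, freqs_khz = f)
  }
  ctrl <- mk_fit(1, 3, 0.5, 0.1)
  light <- mk_fit(0.5, 3, 0.5, 0.05)
  d <- decompose_gain(ctrl, light)
  expect_equal(d$scale, 2, tolerance = 1e-4)
  expect_equal(d$offset, 0, tolerance = 1e-4)
  # identical fits -> identity transform
  d0 <- decompose_gain(ctrl, ctrl)
  expect_equal(d0$scale, 1, tolerance = 1e-9)
  expect_equal(d0$offset, 0, tolerance = 1e-9)
  # round trip: decompose(fit, apply_transform(fit, o, s)) == (o, s), exactly
  for (case in list(c(0.02, 1.8), c(0, 1.2), c(0.05, 3))) {
    tr <- apply_transform(ctrl, offset = case[1], scale = case[2])
    got <- decompose_gain(ctrl, tr)
    expect_equal(got$scale, case[2], tolerance = 1e-9)
    expect_equal(got$offset, case[1], tolerance = 1e-9)
  }
  # degenerate light amplitude
  flat <- ctrl
  flat$A <- 0
  expect_error(decompose_gain(ctrl, flat), class = "striatune_undefined_gain")
})

test_that("joint transform regression recovers offset and scale from curves", {
  f <- 2 * 2^seq(0, 4.5, by = 0.25)
  ctrl <- tibble::tibble(freq_khz = f,
                         rate_hz = 40 * exp(-0.5 * (log2(f) - 3)^2 / 0.4) + 2)
  light <- tibble::tibble(freq_khz = f, rate_hz = (ctrl$rate_hz - 1.5) / 1.8)
  d <- decompose_gain(ctrl, light, method = "joint")
  expect_equal(d$scale, 1.8, tolerance = 1e-9)
  expect_equal(d$offset, 1.5, tolerance = 1e-9)
})

test_that("shoulder rates respond to uniform gain but not to identity", {
  f <- 2 * 2^seq(0, 4.5, by = 0.25)
  x <- log2(f)
  curves <- purrr::map_dfr(1:4, function(u) {
    base <- 30 * exp(-0.5 * (x - (2 + 0.25 * u))^2 / 0.36) + 1
    dplyr::bind_rows(
      tibble::tibble(unit_id = u, condition = "control", freq_khz = f, rate_hz = base),
      tibble::tibble(unit_id = u, condition = "light", freq_khz = f, rate_hz = base / 2))
  })
  # identical unit shapes make the paired differences constant: infinite t
  expect_warning(sh <- shoulder_rates(align_and_normalize(curves)), "variance")
  expect_equal(sh$per_unit$light, sh$per_unit$control / 2, tolerance = 1e-9)
  # identical conditions give exactly zero paired difference
  curves$rate_hz[curves$condition == "light"] <-
    curves$rate_hz[curves$condition == "control"]
  expect_warning(sh0 <- shoulder_rates(align_and_normalize(curves)), "zero")
  expect_equal(sh0$test$mean_diff, 0)
})
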