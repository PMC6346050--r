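test_that("psychometric fit recovers generating parameters from a large session", {
  trials <- simulate_behavior(beta0 = 0.1, beta1 = 0.05, n_trials = 10000, seed = 11)
  fit <- fit_psychometric(trials)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta1 - 0.05) / 0.05, 0.10)
  expect_lt(abs(fit$beta0 - 0.1), 0.1)  # intercept on its own log-odds scale
  td <- tidy(fit)
  expect_equal(td$term, c("beta0", "beta1"))
  expect_equal(td$estimate, c(fit$beta0, fit$beta1))
  expect_equal(glance(fit)$n_trials, fit$n_trials)
})

test_that("choices independent of strength give a slope within its CI of zero", {
  trials <- simulate_behavior(beta0 = 0.3, beta1 = 0, n_trials = 4000, seed = 12)
  fit <- fit_psychometric(trials)
  se <- tidy(fit)$std.error[2]
  expect_lt(abs(fit$beta1), 2.5 * se)
})

test_that("perfect separation is flagged and estimates are capped", {
  trials <- tibble::tibble(
    r = rep(c(-100, -50, 50, 100), each = 30),
    choice = ifelse(rep(c(-100, -50, 50, 100), each = 30) > 0, "right", "left"),
    reported = TRUE)
  expect_warning(fit <- fit_psychometric(trials), "converge")
  expect_false(fit$converged)
  expect_lte(abs(fit$beta1), 1)
  expect_lte(abs(fit$beta0), 20)
})

test_that("fit is invariant to trial order and monotone when beta1 > 0", {
  trials <- simulate_behavior(beta0 = -0.2, beta1 = 0.04, n_trials = 3000, seed = 13)
  f1 <- fit_psychometric(trials)
  f2 <- fit_psychometric(trials[sample.int(nrow(trials)), ])
  expect_equal(f1$beta0, f2$beta0, tolerance = 1e-10)
  expect_equal(f1$beta1, f2$beta1, tolerance = 1e-10)
  p <- predict(f1, seq(-100, 100, by = 5))
  expect_true(all(diff(p) > 0))
})

test_that("estimator bias shrinks as the session grows", {
  err <- vapply(c(500, 5000, 50000), function(n) {
    fits <- vapply(1:4, function(i) {
      fit_psychometric(simulate_behavior(beta0 = 0, beta1 = 0.05, n_trials = n,
                                         seed = 1000 * i + n))$beta1
    }, numeric(1))
    abs(mean(fits) - 0.05)
  }, numeric(1))
  expect_lt(err[3], 0.004)
  expect_lt(err[3], err[1] + 0.002)  # no blow-up; shrinking trend with slack
})

test_that("session metrics count completed/non-reported and summarize by level", {
  trials <- tibble::tibble(
    r = c(100, 100, 100, -100, -100, 50, 50, 0, 0, 0),
    choice = c("right", "right", "none", "left", "right", "right", "none",
               "left", "none", "right"),
    correct = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    reaction_time_s = c(0.3, 0.5, NA, 0.4, 0.6, 0.2, NA, 0.8, NA, 0.4),
    reported = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  m <- session_metrics(trials)
  expect_equal(m$n_completed, 7L)
  expect_equal(m$n_nonreport, 3L)
  at <- function(lev) m$by_strength[m$by_strength$level == lev, ]
  expect_equal(at(100)$accuracy, 1)
  expect_equal(at(100)$median_rt_s, 0.4)
  expect_equal(at(-100)$accuracy, 0.5)
  expect_equal(at(-100)$median_rt_s, 0.5)
  expect_error(session_metrics(trials[0, ]), class = "striatune_empty_input")
})

test_that("session metrics equal a hand count on a seeded synthetic session", {
  trials <- simulate_behavior(n_trials = 500, nonreport_p = 0.07, seed = 21)
  m <- session_metrics(trials)
  expect_equal(m$n_nonreport, sum(!trials$reported))
  expect_equal(m$n_completed, sum(trials$reported))
  done <- trials[trials$reported, ]
  for (lev in unique(done$r)) {
    sub <- done[done$r == lev, ]
    row <- m$by_strength[m$by_strength$level == lev, ]
    expect_equal(row$accuracy, mean(sub$correct))
    expect_equal(row$median_rt_s, median(sub$reaction_time_s))
  }
})

test_that("paired session comparison matches the textbook paired t test", {
  # identical pairs: zero difference, p = 1
  expect_warning(res0 <- compare_sessions(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(res0$mean_diff, 0)
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)
  # constant nonzero differences: infinite textbook statistic
  expect_warning(res1 <- compare_sessions(c(1, 2, 3), c(2, 3, 4)), "variance")
  expect_equal(res1$mean_diff, -1)
  expect_true(is.infinite(res1$t) && res1$t < 0)
  # ordinary case equals the closed form
  x <- c(0.9, 0.8, 0.85, 0.95, 0.7)
  y <- c(0.6, 0.7, 0.6, 0.8, 0.5)
  res <- compare_sessions(x, y)
  d <- x - y
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(res$df, 4)
  # a large shift vs small noise is detected at n = 5
  set.seed(31)
  a <- rnorm(5, 1, 0.05)
  expect_lt(compare_sessions(a + 0.5, a + rnorm(5, 0, 0.05))$p_value, 0.05)
  expect_error(compare_sessions(1, 2), class = "striatune_insufficient_data")
})
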