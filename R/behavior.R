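#' Fit the two-parameter logistic psychometric function
#'
#' Fits `log(p / (1 - p)) = beta0 + r * beta1` by Bernoulli maximum
#' likelihood on trial-level data, where `p` is the probability of choosing
#' the port associated with high frequencies and `r` is the stimulus strength
#' in percent. Only completed (reported) trials enter the fit. `beta0`
#' measures choice bias and `beta1` the psychometric slope per percent of
#' stimulus strength.
#'
#' Perfect separation (e.g. every choice on one side at every strength) is
#' flagged: `converged` is set to `FALSE` and the estimates are capped, with
#' a warning.
#'
#' @param trials A data frame with columns `r` (percent, signed towards the
#'   high side), `choice` (`"left"`, `"right"` or `"none"`), and `reported`
#'   (logical). Rows with `reported == FALSE` (or `choice == "none"`) are
#'   dropped before fitting.
#' @param high_port Which side port is associated with high frequencies
#'   (`"right"` by default).
#' @param beta_cap Absolute caps applied to `(beta0, beta1)` when the fit
#'   does not converge (separation).
#'
#' @return An object of class `psychometric_fit`: a list with elements
#'   `beta0`, `beta1`, `n_trials`, `converged`, and `model` (the underlying
#'   `glm`, or `NULL`). Supports [tidy()], [glance()], [predict()] and
#'   [autoplot()].
#' @examples
#' trials <- simulate_behavior(beta0 = 0, beta1 = 0.05, n_trials = 2000, seed = 1)
#' fit <- fit_psychometric(trials)
#' fit$beta1
#' @export
fit_psychometric <- function(trials, high_port = c("right", "left"),
                             beta_cap = c(20, 1)) {
  high_port <- match.arg(high_port)
  stopifnot(all(c("r", "choice") %in% names(trials)))
  if (!"reported" %in% names(trials)) trials$reported <- trials$choice != "none"
  done <- trials[trials$reported & trials$choice != "none", , drop = FALSE]
  if (length(unique(done$r)) < 2L) {
    abort("need completed trials at >= 2 distinct stimulus strengths.",
          class = "striatune_insufficient_data")
  }
  y <- done$choice == high_port

  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ r, data = data.frame(y = y, r = done$r), family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(coef(fit))
  # a numerically zero residual deviance means every choice is perfectly
  # predicted (complete separation), even when glm() converges quietly;
  # very large coefficients indicate quasi-separation
  if (!fit$converged || fit$deviance < 1e-6 ||
      abs(beta[1]) > beta_cap[1] || abs(beta[2]) > beta_cap[2]) {
    separated <- TRUE
  }
  converged <- fit$converged && !separated
  if (!converged) {
    warn("psychometric fit did not converge (separation); estimates capped.")
    beta[1] <- sign(beta[1]) * min(abs(beta[1]), beta_cap[1])
    beta[2] <- sign(beta[2]) * min(abs(beta[2]), beta_cap[2])
  }
  structure(
    list(beta0 = beta[1], beta1 = beta[2], n_trials = nrow(done),
         converged = converged, high_port = high_port, model = fit),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Logistic psychometric fit (", x$n_trials, " completed trials)\n", sep = "")
  cat(sprintf("  beta0 (bias)  = %8.4f\n  beta1 (slope) = %8.4f per %% r\n",
              x$beta0, x$beta1))
  if (!x$converged) cat("  ** did not converge (separation); estimates capped **\n")
  invisible(x)
}

#' @rdname fit_psychometric
#' @param object,x A `psychometric_fit`.
#' @param ... Unused.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("beta0", "beta1"),
    estimate = c(x$beta0, x$beta1),
    std.error = if (x$converged) unname(sm[, "Std. Error"]) else c(NA_real_, NA_real_),
    statistic = if (x$converged) unname(sm[, "z value"]) else c(NA_real_, NA_real_),
    p.value = if (x$converged) unname(sm[, "Pr(>|z|)"]) else c(NA_real_, NA_real_)
  )
}

#' @rdname fit_psychometric
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    n_trials = x$n_trials,
    converged = x$converged,
    deviance = x$model$deviance,
    null.deviance = x$model$null.deviance,
    AIC = x$model$aic
  )
}

#' @rdname fit_psychometric
#' @param newdata Optional data frame with an `r` column (or a numeric vector
#'   of strengths) at which to evaluate the fitted probability of a
#'   high-side choice.
#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  r <- if (is.null(newdata)) object$model$data$r
       else if (is.data.frame(newdata)) newdata$r else newdata
  plogis(object$beta0 + r * object$beta1)
}

#' Session-level behavioral metrics
#'
#' Counts completed and non-reported trials and summarizes accuracy and
#' reaction time per evidence level. Levels are the task's discrete nominal
#' strengths `r` by default; set `by = "evidence"` to bin by the realized
#' per-trial evidence statistic instead. The reaction-time summary is the
#' median per level.
#'
#' @param trials A data frame with columns `r`, `choice`, `correct`,
#'   `reaction_time_s`, `reported` (and optionally `evidence`).
#' @param by `"r"` (default) or `"evidence"`: the binning variable.
#' @return An object of class `session_metrics`: a list with `n_completed`,
#'   `n_nonreport`, and `by_strength`, a tibble with one row per level
#'   (`level`, `n`, `accuracy`, `median_rt_s`).
#' @export
session_metrics <- function(trials, by = c("r", "evidence")) {
  by <- match.arg(by)
  if (nrow(trials) == 0L) {
    abort("empty session: no trials to summarize.", class = "striatune_empty_input")
  }
  if (!"reported" %in% names(trials)) trials$reported <- trials$choice != "none"
  done <- trials[trials$reported & trials$choice != "none", , drop = FALSE]
  lev <- if (by == "r") done$r else done$evidence
  by_strength <- tibble::tibble(level = lev,
                                correct = done$correct,
                                rt = done$reaction_time_s) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy = mean(.data$correct),
                     median_rt_s = median(.data$rt, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$level)
  structure(
    list(n_completed = nrow(done),
         n_nonreport = nrow(trials) - nrow(done),
         by = by,
         by_strength = by_strength),
    class = "session_metrics"
  )
}

#' @export
print.session_metrics <- function(x, ...) {
  cat("Session metrics: ", x$n_completed, " completed, ",
      x$n_nonreport, " non-reported trials\n", sep = "")
  print(x$by_strength)
  invisible(x)
}

#' Paired comparison of session metrics across treatments
#'
#' Paired t test of one metric measured in matched saline and CNO sessions
#' (or any matched pair of conditions), reporting the mean difference
#' `x - y`, the t statistic, degrees of freedom and the two-sided p value.
#'
#' When the paired differences have zero variance the textbook statistic is
#' degenerate: the test returns `t = 0, p = 1` if all differences are zero
#' and `t = +/-Inf, p = 0` otherwise, with a warning.
#'
#' @param x,y Numeric vectors of equal length (>= 2): the per-animal or
#'   per-pair metric under the two conditions.
#' @return A one-row tibble: `n`, `mean_diff`, `t`, `df`, `p_value`.
#' @examples
#' compare_sessions(c(0.9, 0.85, 0.8), c(0.7, 0.72, 0.65))
#' @export
compare_sessions <- function(x, y) {
  if (length(x) != length(y)) {
    abort("paired samples must have equal length.", class = "striatune_insufficient_data")
  }
  if (length(x) < 2L) {
    abort("need at least 2 pairs for a paired t test.", class = "striatune_insufficient_data")
  }
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      warn("all paired differences are zero; returning t = 0, p = 1.")
      res <- list(t = 0, p = 1)
    } else {
      warn("paired differences have zero variance; t statistic is infinite.")
      res <- list(t = sign(mean(d)) * Inf, p = 0)
    }
    return(tibble::tibble(n = length(x), mean_diff = mean(d),
                          t = res$t, df = length(x) - 1, p_value = res$p))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(n = length(x),
                 mean_diff = unname(tt$estimate),
                 t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' @rdname fit_psychometric
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  dat <- object$model$data
  obs <- dplyr::summarise(dplyr::group_by(dat, .data$r),
                          p_high = mean(.data$y), n = dplyr::n(),
                          .groups = "drop")
  grid <- tibble::tibble(r = seq(min(dat$r), max(dat$r), length.out = 200))
  grid$p_high <- predict(object, grid)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$r, y = .data$p_high)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_line(data = grid, linewidth = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "stimulus strength r (%)",
                  y = sprintf("P(choose %s / high port)", object$high_port),
                  size = "trials") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
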