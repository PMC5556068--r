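# Logistic growth-curve fitting and density-ratio summaries.

#' Fit a three-parameter logistic growth curve
#'
#' Nonlinear least-squares fit of
#' `N(t) = K / (1 + exp(-r (t - tau)))`
#' to a growth table: carrying capacity `K` (the plateau density), growth
#' rate `r` (per unit time), and half-capacity time `tau` (the time at
#' which the fitted curve equals `K/2` exactly). Standard errors come
#' from the Jacobian at the optimum. Starting values: `K` from the data
#' maximum, `tau` from the time nearest half of it, `r` from a log-linear
#' regression of the logit-transformed values.
#'
#' When fitting simulation trajectories, the time axis is Markov steps;
#' step counts and experimental time scales are not interchangeable.
#'
#' @param times Numeric vector of observation times (>= 4 values).
#' @param values Observations (cell counts or densities); noisy values may
#'   dip below zero, but the maximum must be positive and the series
#'   non-constant.
#' @return An object of class `logistic_fit`: list with `K`, `r`, `tau`,
#'   `se` (named vector), `rss`, `fitted`, and `predict(t)`.
#' @examples
#' tab <- synthetic_growth_curve(K = 5000, r = 1.2, tau = 4, times = 0:8)
#' fit <- fit_logistic(tab$time, tab$value)
#' c(fit$K, fit$r, fit$tau)
#' @export
fit_logistic <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (length(times) < 4) stop("fit_logistic: need at least 4 time points")
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("fit_logistic: non-finite inputs")
  }
  if (max(values) <= 0) {
    stop("fit_logistic: values must have a positive maximum")
  }
  if (stats::sd(values) < 1e-12 * max(abs(values))) {
    stop("fit_logistic: degenerate (constant) data cannot identify a logistic curve")
  }
  K0 <- max(values) * 1.05
  tau0 <- times[which.min(abs(values - K0 / 2))]
  frac <- pmin(pmax(values / K0, 1e-6), 1 - 1e-6)
  r0 <- tryCatch({
    co <- stats::coef(stats::lm(stats::qlogis(frac) ~ times))
    max(abs(co[2]), 1e-3)
  }, error = function(e) 1)
  fit <- minpack.lm::nlsLM(
    values ~ K / (1 + exp(-r * (times - tau))),
    start = list(K = K0, r = r0, tau = tau0),
    lower = c(K = 1e-12, r = 1e-9, tau = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  K <- unname(co["K"]); r <- unname(co["r"]); tau <- unname(co["tau"])
  structure(list(
    K = K, r = r, tau = tau,
    se = c(K = unname(se["K"]), r = unname(se["r"]), tau = unname(se["tau"])),
    rss = sum(stats::resid(fit)^2),
    fitted = stats::fitted(fit),
    predict = function(t) K / (1 + exp(-r * (t - tau)))),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("logistic growth fit  N(t) = K / (1 + exp(-r (t - tau)))\n")
  cat(sprintf("  K   = %.6g  (SE %.3g)\n", x$K, x$se["K"]))
  cat(sprintf("  r   = %.6g  (SE %.3g)\n", x$r, x$se["r"]))
  cat(sprintf("  tau = %.6g  (SE %.3g)\n", x$tau, x$se["tau"]))
  cat(sprintf("  RSS = %.6g\n", x$rss))
  invisible(x)
}

#' Density ratio series of a two-type trajectory
#'
#' Elementwise ratio of the type-2 to type-1 densities of a recorded
#' trajectory, optionally smoothed with a centred moving average. Records
#' with zero type-1 density yield `NA` rather than an error.
#'
#' @param trajectory Data frame with columns `step`, `density1`,
#'   `density2` (as produced by [run_simulation()]), or two aligned
#'   numeric vectors via `density2`.
#' @param density2 Optional second vector when `trajectory` is the
#'   type-1 density vector.
#' @param smooth_window Odd moving-average window length (1 = none).
#' @return Data frame `step`, `ratio` (attribute `smooth_window`).
#' @export
density_ratio_series <- function(trajectory, density2 = NULL,
                                 smooth_window = 1L) {
  if (is.data.frame(trajectory)) {
    step <- trajectory$step
    d1 <- trajectory$density1
    d2 <- trajectory$density2
  } else {
    d1 <- trajectory
    d2 <- density2
    if (is.null(d2) || length(d1) != length(d2)) {
      stop("density_ratio_series: misaligned density records")
    }
    step <- seq_along(d1) - 1
  }
  ratio <- ifelse(d1 > 0, d2 / d1, NA_real_)
  if (smooth_window > 1) {
    if (smooth_window %% 2 == 0) stop("smooth_window must be odd")
    ratio <- as.numeric(stats::filter(ratio, rep(1 / smooth_window,
                                                 smooth_window)))
  }
  out <- data.frame(step = step, ratio = ratio)
  attr(out, "smooth_window") <- as.integer(smooth_window)
  out
}

#' Ratio of fitted carrying capacities
#'
#' `K_A / K_B` for two logistic fits, with a first-order (delta-method)
#' standard error propagated from the per-fit standard errors of `K`.
#'
#' @param fitA,fitB Objects from [fit_logistic()].
#' @return Named list `ratio`, `se`.
#' @export
carrying_capacity_ratio <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "logistic_fit"), inherits(fitB, "logistic_fit"))
  ratio <- fitA$K / fitB$K
  se <- abs(ratio) * sqrt((fitA$se["K"] / fitA$K)^2 + (fitB$se["K"] / fitB$K)^2)
  list(ratio = ratio, se = unname(se))
}
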