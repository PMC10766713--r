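# Filamentous overgrowth kinetics. Membranes start clean and end fully
# overgrown, so invasion is modelled as a two-parameter logistic with
# asymptotes fixed at 0 and 100:
#     L(t) = 100 / (1 + exp(-rate * (t - t50))),
# t50 the half-overgrowth time (hours) and rate the steepness (per hour).
# The usable window of a medium is the time before overgrowth crosses the
# countable threshold, clipped to the 168-hour incubation horizon.

#' Logistic invasion curve
#'
#' Percent membrane coverage at the given times for a logistic invasion
#' with midpoint `t50` (hours) and steepness `rate` (per hour); monotone
#' non-decreasing in time.
#'
#' @param times hours, non-negative.
#' @param t50 half-overgrowth time (hours).
#' @param rate steepness per hour (>= 0).
#' @return percent covered in \[0, 100\].
#' @export
invasion_curve <- function(times, t50, rate) {
  if (rate < 0) stop_domain("rate must be non-negative")
  if (any(times < 0)) stop_domain("times must be non-negative")
  100 / (1 + exp(-rate * (times - t50)))
}

#' Fit a logistic invasion curve
#'
#' Least-squares fit of the fixed-asymptote logistic to an observed
#' coverage series: coarse multi-start over a (t50, log rate) grid, then
#' Nelder-Mead refinement. The fit is flagged `converged = FALSE` when the
#' residual sum of squares exceeds half the total sum of squares about the
#' mean (the curve explains less than half the variation), and degenerate
#' constant series are refused.
#'
#' @param times observation hours (>= 3 points).
#' @param coverage percent covered in \[0, 100\], same length.
#' @return a `logistic_fit` list: `t50`, `rate`, `rss`, `converged`,
#'   `degenerate`, `n`.
#' @export
fit_logistic <- function(times, coverage) {
  if (length(times) != length(coverage))
    stop_domain("times and coverage must have equal length")
  if (length(times) < 3) stop_domain("at least 3 time points required")
  if (any(coverage < 0 | coverage > 100))
    stop_domain("coverage must be in [0, 100]")
  if (sd(coverage) == 0)
    return(structure(list(t50 = NA_real_, rate = NA_real_, rss = NA_real_,
                          converged = FALSE, degenerate = TRUE,
                          n = length(times)), class = "logistic_fit"))
  obj <- function(p) {
    sum((coverage - 100 / (1 + exp(-exp(p[2]) * (times - p[1]))))^2)
  }
  starts <- expand.grid(t50 = seq(min(times), max(times), length.out = 15),
                        lr = log(c(0.02, 0.05, 0.1, 0.2, 0.5, 1)))
  vals <- apply(starts, 1, obj)
  best <- as.numeric(starts[which.min(vals), ])
  fit <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 4000))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 4000))
  tss <- sum((coverage - mean(coverage))^2)
  structure(list(t50 = fit$par[1], rate = exp(fit$par[2]), rss = fit$value,
                 converged = fit$value <= 0.5 * tss, degenerate = FALSE,
                 n = length(times)), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$degenerate) cat("Logistic fit: degenerate (constant series)\n")
  else cat(sprintf(
    "Logistic fit: t50 = %.2f h, rate = %.4f /h, rss = %.3g (%sconverged)\n",
    x$t50, x$rate, x$rss, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Time at which invasion crosses a threshold
#'
#' In `"interpolate"` mode, linear interpolation between the bracketing
#' observations of a coverage series (first crossing); in `"model"` mode,
#' analytic inversion of a logistic fit,
#' `t = t50 - log(100/threshold - 1)/rate`. Returns `Inf` if the threshold
#' is never crossed; if the series starts at or above the threshold, the
#' first observation time is returned with attribute `censored = "left"`.
#'
#' @param x either a `logistic_fit`, or a list/data.frame with `times` and
#'   `coverage` components.
#' @param threshold percent in (0, 100].
#' @param mode `"interpolate"` (default for series) or `"model"` (fits a
#'   logistic first if given a series).
#' @return hours (possibly `Inf`), with a `censored` attribute when
#'   left-censored.
#' @export
time_to_threshold <- function(x, threshold,
                              mode = c("interpolate", "model")) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 100)
    stop_domain("threshold must be in (0, 100]")
  if (inherits(x, "logistic_fit") || mode == "model") {
    fit <- if (inherits(x, "logistic_fit")) x
           else fit_logistic(x$times, x$coverage)
    if (isTRUE(fit$degenerate)) stop_domain("degenerate fit has no crossing")
    if (threshold == 100) return(Inf)
    return(fit$t50 - log(100 / threshold - 1) / fit$rate)
  }
  times <- x$times; coverage <- x$coverage
  if (is.unsorted(times, strictly = TRUE))
    stop_domain("times must be strictly increasing")
  if (coverage[1] >= threshold)
    return(structure(times[1], censored = "left"))
  i <- which(coverage >= threshold)[1]
  if (is.na(i)) return(Inf)
  t0 <- times[i - 1]; t1 <- times[i]
  c0 <- coverage[i - 1]; c1 <- coverage[i]
  t0 + (threshold - c0) * (t1 - t0) / (c1 - c0)
}

#' Usable incubation window of a medium
#'
#' The time available for colony picking before overgrowth censors new
#' isolates: [time_to_threshold()] clipped to the incubation horizon
#' (168 h by default). A series that never crosses returns the full
#' horizon; immediate overgrowth returns the first observation time with a
#' left-censoring flag.
#'
#' @inheritParams time_to_threshold
#' @param horizon incubation horizon in hours (default 168).
#' @return hours in \[0, horizon\].
#' @export
usable_window <- function(x, threshold, mode = c("interpolate", "model"),
                          horizon = 168) {
  t <- time_to_threshold(x, threshold, mode)
  structure(min(unclass(t), horizon), censored = attr(t, "censored"))
}
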