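#' Z-normalize a trace on a pre-stimulus window
#'
#' Standardizes a fluorescence trace by the mean and standard deviation of
#' a baseline window (default 1-6 s from record start, before systematic
#' stimulation), `(x - mean_w) / sd_w`. The output is invariant to affine
#' transforms of the input.
#'
#' @param x Numeric trace.
#' @param dt Sample interval, seconds.
#' @param window Baseline window `c(start, end)` in seconds.
#' @return Z-normalized trace.
#' @export
znorm <- function(x, dt, window = c(1, 6)) {
  stopifnot(is.numeric(x), dt > 0, length(window) == 2, window[1] < window[2])
  i0 <- floor(window[1] / dt) + 1L
  i1 <- floor(window[2] / dt)
  if (i0 < 1 || i1 > length(x))
    stop("normalization window outside the record", call. = FALSE)
  w <- x[i0:i1]
  s <- stats::sd(w)
  if (s == 0) stop("zero variance in the normalization window", call. = FALSE)
  (x - mean(w)) / s
}

#' Dark-Light index
#'
#' `DLi = (L - D) / (L + D)` over the light- and dark-flash response
#' amplitudes of a cone: -1 for a purely dark-biased cone, +1 for purely
#' light-biased, 0 for balanced responses.
#'
#' @param L,D Non-negative light- and dark-response amplitudes.
#' @return Index in `[-1, 1]`; `NA` with a warning when `L + D == 0`.
#' @examples
#' dli(3, 1)
#' @export
dli <- function(L, D) {
  stopifnot(all(L >= 0), all(D >= 0))
  out <- (L - D) / (L + D)
  if (any(L + D == 0)) {
    warning("DLi undefined where L + D == 0; returning NA")
    out[L + D == 0] <- NA_real_
  }
  out
}

#' Mode of a set of per-trial response amplitudes
#'
#' Estimates the most common response amplitude across repeated trials as
#' the peak of a Gaussian kernel-density estimate (Silverman's bandwidth).
#' With fewer than 3 trials the median is returned with a warning.
#'
#' @param amplitudes Numeric vector of per-trial amplitudes.
#' @param n_grid Density grid resolution.
#' @return The modal amplitude.
#' @export
amplitude_mode <- function(amplitudes, n_grid = 512) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (length(amplitudes) < 3) {
    warning("fewer than 3 trials; falling back to the median")
    return(stats::median(amplitudes))
  }
  if (stats::sd(amplitudes) == 0) return(amplitudes[1])
  d <- stats::density(amplitudes, bw = "nrd0", n = n_grid)
  d$x[which.max(d$y)]
}

#' Baseline position within the full dynamic range
#'
#' Expresses a cone's resting signal as a fraction of its full dynamic
#' range, measured between the all-lights-off period (maximal calcium) and
#' the all-lights-on period (minimal calcium):
#' `(baseline - min) / (max - min)`, clipped to `[0, 1]`.
#'
#' @param baseline Resting-signal level.
#' @param signal_lights_off Signal with all lights off (range maximum).
#' @param signal_lights_on Signal with all lights on (range minimum).
#' @return Fraction in `[0, 1]`; attribute `clipped` flags out-of-range
#'   inputs.
#' @export
baseline_fraction <- function(baseline, signal_lights_off, signal_lights_on) {
  if (any(signal_lights_off <= signal_lights_on))
    stop("lights-off signal must exceed lights-on signal", call. = FALSE)
  f <- (baseline - signal_lights_on) / (signal_lights_off - signal_lights_on)
  clipped <- f < 0 | f > 1
  out <- pmin(1, pmax(0, f))
  attr(out, "clipped") <- clipped
  out
}

#' Fit a Hill function to a stimulus-response curve
#'
#' Least-squares fit of `A(I) = A_max * I^h / (I^h + I_half^h)` to response
#' amplitudes over stimulus intensities (Levenberg-Marquardt via
#' minpack.lm). The slope `h` is a free parameter.
#'
#' @param intensities Stimulus intensities (> 0), at least 4 levels.
#' @param amplitudes Non-negative response amplitudes (same length, or a
#'   multiple for repeated measures).
#' @return A `hill_fit` object: list with `a_max`, `i_half`, `h`,
#'   `residual_sd`, and the `fit`.
#' @export
hill_fit <- function(intensities, amplitudes) {
  if (length(unique(intensities)) < 4)
    stop("need at least 4 intensity levels", call. = FALSE)
  if (length(amplitudes) %% length(intensities) == 0 &&
      length(amplitudes) > length(intensities))
    intensities <- rep(intensities, length(amplitudes) / length(intensities))
  stopifnot(length(intensities) == length(amplitudes))
  if (any(intensities <= 0)) stop("intensities must be positive", call. = FALSE)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (all(amplitudes == 0))
    stop("all amplitudes are zero; Hill fit is degenerate", call. = FALSE)
  df <- data.frame(I = intensities, A = amplitudes)
  a0 <- max(df$A)
  i0 <- df$I[which.min(abs(df$A - a0 / 2))]
  fit <- try(minpack.lm::nlsLM(
    A ~ a_max * I^h / (I^h + i_half^h), data = df,
    start = list(a_max = a0, i_half = i0, h = 1),
    lower = c(1e-12, 1e-12, 0.05), upper = c(Inf, Inf, 20),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Hill fit failed to converge: ", attr(fit, "condition")$message,
         call. = FALSE)
  co <- stats::coef(fit)
  structure(list(a_max = unname(co["a_max"]), i_half = unname(co["i_half"]),
                 h = unname(co["h"]),
                 residual_sd = stats::sd(stats::resid(fit)), fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> a_max = %.4g, i_half = %.4g, h = %.3g (resid sd %.3g)\n",
              x$a_max, x$i_half, x$h, x$residual_sd))
  invisible(x)
}

#' Predict from a Hill fit
#' @param object A `hill_fit`.
#' @param newdata Intensities.
#' @param ... Unused.
#' @export
predict.hill_fit <- function(object, newdata, ...) {
  I <- if (is.list(newdata)) newdata$I else newdata
  object$a_max * I^object$h / (I^object$h + object$i_half^object$h)
}

#' Equivalent-response sensitivity fold between two Hill curves
#'
#' Fixes the criterion amplitude at half the maximal response of the
#' reference curve, then compares the stimulus intensities at which the
#' reference and the test curve each reach that same absolute amplitude:
#' `fold = I_reference / I_test`. Folds > 1 mean the test cone needs less
#' light, i.e. is more responsive. Invariant to a common rescaling of both
#' intensity axes.
#'
#' @param reference_fit,test_fit [hill_fit()] objects.
#' @return Sensitivity fold (scalar).
#' @export
sensitivity_index <- function(reference_fit, test_fit) {
  stopifnot(inherits(reference_fit, "hill_fit"), inherits(test_fit, "hill_fit"))
  crit <- reference_fit$a_max / 2
  i_ref <- reference_fit$i_half  # half of own max by construction
  if (crit >= test_fit$a_max)
    stop("criterion amplitude exceeds the test curve's maximum; ",
         "curves are non-comparable", call. = FALSE)
  i_test <- test_fit$i_half *
    (crit / (test_fit$a_max - crit))^(1 / test_fit$h)
  i_ref / i_test
}

#' Recovery time constant after a flash response
#'
#' Fits a single exponential `C + A * exp(-(t - t0)/tau)` to the decaying
#' segment of a flash response, from the point where the trace has fallen
#' to 90% of its peak-above-baseline down to the end of the record.
#'
#' @param x Trace (numeric).
#' @param dt Sample interval, seconds.
#' @param fit_start Fraction of peak height at which the fit window opens
#'   (default 0.9).
#' @return List: `tau` (s), `r_squared`, `fit`, `peak_index`.
#' @export
recovery_tau <- function(x, dt, fit_start = 0.9) {
  stopifnot(is.numeric(x), length(x) > 10, dt > 0)
  ip <- which.max(x)
  if (ip >= length(x) - 5)
    stop("no post-peak segment to fit", call. = FALSE)
  base <- stats::median(x[seq(max(1, length(x) - round(0.1 * length(x))),
                              length(x))])
  peak <- x[ip]
  if (peak - base <= 0 || mean(x[ip:length(x)] <= base + 0.5 * (peak - base)) < 0.1)
    stop("trace does not decay after the peak", call. = FALSE)
  thr <- base + fit_start * (peak - base)
  i0 <- ip + which(x[ip:length(x)] <= thr)[1] - 1L
  if (is.na(i0) || i0 >= length(x) - 5)
    stop("trace does not decay after the peak", call. = FALSE)
  seg <- x[i0:length(x)]
  t <- (seq_along(seg) - 1) * dt
  df <- data.frame(t = t, y = seg)
  tau0 <- max(dt, t[which.min(abs(seg - (base + (seg[1] - base) / exp(1))))])
  fit <- try(minpack.lm::nlsLM(
    y ~ C + A * exp(-t / tau), data = df,
    start = list(C = base, A = seg[1] - base, tau = tau0),
    lower = c(-Inf, 1e-12, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("exponential recovery fit failed: ",
         attr(fit, "condition")$message, call. = FALSE)
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((seg - mean(seg))^2)
  list(tau = unname(co["tau"]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       fit = fit, peak_index = ip)
}
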