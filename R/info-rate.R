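#' Welch power spectral density
#'
#' Averaged-periodogram PSD estimate: the record is split into segments of
#' `n_seg` samples with 50% overlap, each segment is mean-detrended,
#' Hann-windowed, and its periodogram computed; segment periodograms are
#' averaged. One-sided density normalization, so that
#' `sum(psd) * df ~ var(x)` for a long stationary record.
#'
#' @param x Numeric record.
#' @param fs Sampling rate, Hz.
#' @param n_seg Segment length in samples; default
#'   `min(floor(length(x)/4), 512)`.
#' @param overlap Fractional segment overlap.
#' @return List: `freq` (Hz, up to Nyquist), `psd`, `n_segments`, `n_seg`.
#' @export
welch_psd <- function(x, fs, n_seg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(n_seg)) n_seg <- min(max(8L, floor(n / 4)), 512L)
  n_seg <- min(n_seg, n)
  if (n_seg < 8) stop("record too short for a Welch estimate", call. = FALSE)
  step <- max(1L, floor(n_seg * (1 - overlap)))
  starts <- seq(1L, n - n_seg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_seg - 1) / (n_seg - 1))  # Hann
  u <- sum(w^2)
  nf <- floor(n_seg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + n_seg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (u * fs)
    p <- p[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist for even n_seg)
    dbl <- seq(2L, nf - if (n_seg %% 2 == 0) 1L else 0L)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / n_seg, psd = acc / length(starts),
       n_segments = length(starts), n_seg = n_seg)
}

#' Set of repeated response trials
#'
#' `n` aligned response traces to an identical stimulus, the unit of
#' SNR/information-rate estimation.
#'
#' @param traces Numeric matrix, time x trials (equal lengths), or a list
#'   of equal-length vectors.
#' @param fs Sampling rate, Hz.
#' @return A `trial_set` object.
#' @export
trial_set <- function(traces, fs) {
  if (is.list(traces)) {
    if (length(unique(lengths(traces))) != 1)
      stop("all trials must have equal length", call. = FALSE)
    traces <- do.call(cbind, traces)
  }
  traces <- as.matrix(traces)
  if (any(!is.finite(traces))) stop("non-finite trial values", call. = FALSE)
  stopifnot(fs > 0)
  structure(list(traces = traces, fs = fs, n = ncol(traces)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %d samples @ %g Hz\n",
              x$n, nrow(x$traces), x$fs))
  invisible(x)
}

#' Linear response kernel by reverse correlation
#'
#' Estimates the per-channel linear filter relating a binary noise stimulus
#' to a response trace: the stimulus is zero-meaned per channel, upsampled
#' to the response sampling grid (zero-order hold), and cross-correlated
#' with the response over the lag window,
#' `K_c(tau) = sum_t s_c(t) r(t + tau) / sum_t s_c(t)^2`.
#' The estimate is linear in the response.
#'
#' @param stim A [make_noise_stimulus()] object (or matrix frames x
#'   channels with attributes `rate`).
#' @param response Numeric response trace sampled at `fs`.
#' @param fs Response sampling rate, Hz.
#' @param lag_window Lag range in seconds, `c(min, max)`.
#' @return A `kernel_estimate`: list with `lags` (s), `kernel` (lags x
#'   channels), `amplitude` (per-channel SD over lags), `channels`.
#' @export
estimate_kernel <- function(stim, response, fs, lag_window = c(-0.2, 1)) {
  sm <- stim$states
  rate <- stim$rate
  n_up <- round(fs / rate)
  if (abs(fs / rate - n_up) > 1e-6)
    stop("response rate must be an integer multiple of the stimulus frame rate",
         call. = FALSE)
  if (length(response) < n_up)
    stop("response shorter than one stimulus frame", call. = FALSE)
  su <- sm[rep(seq_len(nrow(sm)), each = n_up), , drop = FALSE]
  nt <- min(nrow(su), length(response))
  su <- su[seq_len(nt), , drop = FALSE]
  r <- response[seq_len(nt)]
  su <- sweep(su, 2L, colMeans(su))
  lag_idx <- seq(round(lag_window[1] * fs), round(lag_window[2] * fs))
  kern <- matrix(0, length(lag_idx), ncol(su))
  denom <- colSums(su^2)
  for (ci in seq_len(ncol(su))) {
    s <- su[, ci]
    for (j in seq_along(lag_idx)) {
      l <- lag_idx[j]
      if (l >= 0) {
        t0 <- seq_len(nt - l)
        kern[j, ci] <- sum(s[t0] * r[t0 + l]) / denom[ci]
      } else {
        t0 <- seq(1 - l, nt)
        kern[j, ci] <- sum(s[t0] * r[t0 + l]) / denom[ci]
      }
    }
  }
  colnames(kern) <- colnames(sm)
  structure(list(lags = lag_idx / fs, kernel = kern,
                 amplitude = apply(kern, 2L, stats::sd),
                 channels = colnames(sm)),
            class = "kernel_estimate")
}

#' @export
print.kernel_estimate <- function(x, ...) {
  cat("<kernel_estimate> amplitudes:",
      paste(sprintf("%s=%.3g", x$channels, x$amplitude), collapse = ", "),
      "\n")
  invisible(x)
}

#' Kernel-amplitude quality filter
#'
#' Keeps, within each zone, the recordings whose kernel response amplitude
#' (SD over lags of the chosen channel) is at least `threshold` (70% by
#' default) of the maximal amplitude in the same zone. A zone's single
#' recording is always kept (it is its own maximum).
#'
#' @param amplitudes Numeric kernel amplitudes (or a list of
#'   `kernel_estimate`s, in which case `channel` selects the amplitude).
#' @param zones Zone label per recording.
#' @param threshold Fraction of the zone maximum required.
#' @param channel Channel name used when `amplitudes` are kernel estimates.
#' @return Logical keep-vector.
#' @export
quality_filter <- function(amplitudes, zones, threshold = 0.7,
                           channel = "UV") {
  if (is.list(amplitudes) && inherits(amplitudes[[1]], "kernel_estimate"))
    amplitudes <- vapply(amplitudes, function(k) k$amplitude[[channel]], 0)
  stopifnot(length(amplitudes) == length(zones))
  keep <- logical(length(amplitudes))
  for (z in unique(zones)) {
    i <- zones == z
    keep[i] <- amplitudes[i] >= threshold * max(amplitudes[i])
  }
  keep
}

#' Bias-corrected signal-to-noise spectrum from repeated trials
#'
#' Estimates the frequency-resolved SNR of a response from `n >= 2`
#' repeated trials: the signal spectrum `S_hat(f)` is the Welch PSD of the
#' trial mean `S(t) = mean_i X_i(t)`; the noise spectrum `N_hat(f)` is the
#' unbiased residual estimate `sum_i PSD(X_i - S) / (n - 1)`; the
#' finite-trial bias of the mean is removed by
#' `SNR(f) = S_hat(f)/N_hat(f) - 1/n`, and negative values are clamped to
#' zero (clamp fraction reported). With noise-free (identical) trials the
#' SNR is infinite and flagged.
#'
#' @param trials A [trial_set()].
#' @param n_seg,overlap Welch settings (see [welch_psd()]).
#' @return An `snr_spectrum`: list with `freq` (Hz), `snr`, `signal_psd`,
#'   `noise_psd`, `n`, `clamped_fraction`, `infinite` flag.
#' @export
snr_spectrum <- function(trials, n_seg = NULL, overlap = 0.5) {
  stopifnot(inherits(trials, "trial_set"))
  n <- trials$n
  if (n < 2) stop("SNR estimation requires at least 2 trials", call. = FALSE)
  m <- rowMeans(trials$traces)
  sw <- welch_psd(m, trials$fs, n_seg = n_seg, overlap = overlap)
  npsd <- 0
  for (i in seq_len(n)) {
    npsd <- npsd + welch_psd(trials$traces[, i] - m, trials$fs,
                             n_seg = sw$n_seg, overlap = overlap)$psd
  }
  npsd <- npsd / (n - 1)
  infinite <- all(npsd[-1] < .Machine$double.eps * max(sw$psd, 1))
  snr <- sw$psd / npsd - 1 / n
  snr[!is.finite(snr)] <- Inf
  clamped <- mean(snr < 0)
  snr <- pmax(0, snr)
  structure(list(freq = sw$freq, snr = snr, signal_psd = sw$psd,
                 noise_psd = npsd, n = n, clamped_fraction = clamped,
                 infinite = infinite),
            class = "snr_spectrum")
}

#' @export
print.snr_spectrum <- function(x, ...) {
  cat(sprintf("<snr_spectrum> %d bins to %.3g Hz, n = %d trials",
              length(x$freq), max(x$freq), x$n))
  if (x$infinite) cat(" [noise-free: SNR infinite]")
  cat("\n")
  invisible(x)
}

#' Shannon information rate from an SNR spectrum
#'
#' Gaussian-channel information rate `R = integral of log2(1 + SNR(f)) df`
#' from 0 to the cut-off frequency, by the trapezoid rule on the native
#' Welch frequency grid. Photoreceptor signals are low-frequency, hence
#' the conventional 12 Hz cut-off.
#'
#' @param snr An [snr_spectrum()] (or list with `freq`, `snr`).
#' @param f_cut Cut-off frequency, Hz.
#' @return Information rate in bits per second.
#' @export
information_rate <- function(snr, f_cut = 12) {
  f <- snr$freq
  s <- snr$snr
  if (max(f) < f_cut)
    stop("spectrum does not reach the cut-off frequency", call. = FALSE)
  if (any(!is.finite(s)))
    stop("SNR spectrum contains non-finite values (noise-free trials?); ",
         "information rate is unbounded", call. = FALSE)
  keep <- f <= f_cut
  f <- f[keep]; s <- s[keep]
  if (abs(f[length(f)] - f_cut) > 1e-9) {
    # extend to exactly f_cut by linear interpolation
    s_cut <- stats::approx(snr$freq, snr$snr, xout = f_cut)$y
    f <- c(f, f_cut); s <- c(s, s_cut)
  }
  y <- log2(1 + s)
  sum(diff(f) * (y[-1] + y[-length(y)]) / 2)
}
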