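#' Tetrachromatic binary noise stimulus
#'
#' Four statistically independent binary channels (R, G, B, UV), each
#' switching at the frame rate with equal on/off probability, presented in
#' a known (seeded) sequence at 12.8 Hz by default.
#'
#' @param duration Stimulus duration, seconds.
#' @param rate Frame rate, Hz.
#' @param channels Number of channels (named R, G, B, UV for the default 4).
#' @param seed Integer seed.
#' @return A `noise_stimulus`: list with `states` (frames x channels 0/1
#'   matrix), `rate`, `dt = 1/rate`, `seed`.
#' @export
make_noise_stimulus <- function(duration, rate = 12.8, channels = 4,
                                seed = 1) {
  stopifnot(duration > 0, rate > 0, channels >= 1)
  set.seed(seed)
  n <- floor(duration * rate)
  states <- matrix(rbinom(n * channels, 1, 0.5), n, channels)
  colnames(states) <- if (channels == 4) c("R", "G", "B", "UV")
    else paste0("ch", seq_len(channels))
  structure(list(states = states, rate = rate, dt = 1 / rate, seed = seed),
            class = "noise_stimulus")
}

#' Synthetic trial set with known spectral SNR
#'
#' Builds `n` repeated response trials as signal + independent noise with a
#' requested flat spectral SNR: each trial is `s(t) + e_i(t)` where the
#' shared signal `s` and the per-trial noise `e_i` are Gaussian white
#' processes with variance ratio `snr`. When a `kernel` and `stimulus` are
#' supplied the signal is instead the kernel-convolved stimulus, rescaled
#' so the band-averaged SNR equals `snr`.
#'
#' @param n Number of trials (>= 1).
#' @param duration Trial duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param snr Target flat signal-to-noise power ratio (0 = pure noise;
#'   `Inf` = noise-free, all trials identical).
#' @param kernel Optional response kernel (numeric vector at `fs`).
#' @param stimulus Optional [make_noise_stimulus()] driving the kernel
#'   (its UV channel by default).
#' @param channel Stimulus channel convolved with the kernel.
#' @param seed Integer seed.
#' @return A [trial_set()] with attribute `ground_truth` (list: `snr`,
#'   `signal`, `seed`).
#' @export
make_trial_set <- function(n, duration, fs = 62.5, snr = 1, kernel = NULL,
                           stimulus = NULL, channel = "UV", seed = 1) {
  stopifnot(n >= 1, duration > 0, fs > 0, snr >= 0)
  set.seed(seed)
  nt <- floor(duration * fs)
  if (!is.null(kernel)) {
    if (is.null(stimulus))
      stimulus <- make_noise_stimulus(duration, seed = seed + 1L)
    n_up <- round(fs / stimulus$rate)
    su <- rep(stimulus$states[, channel], each = n_up)
    su <- su[seq_len(min(nt, length(su)))] - 0.5
    nt <- length(su)
    sig <- stats::convolve(su, rev(kernel), type = "open")[seq_len(nt)]
  } else {
    sig <- stats::rnorm(nt)
  }
  sig <- sig - mean(sig)
  if (is.finite(snr)) {
    noise_sd <- 1
    target_sig_sd <- sqrt(snr) * noise_sd
    s_sd <- stats::sd(sig)
    sig <- if (s_sd > 0) sig * target_sig_sd / s_sd else sig
    traces <- sig + matrix(stats::rnorm(nt * n, sd = noise_sd), nt, n)
  } else {
    traces <- matrix(rep(sig, n), nt, n)
  }
  out <- trial_set(traces, fs)
  attr(out, "ground_truth") <- list(snr = snr, signal = sig, seed = seed)
  out
}

#' Synthetic recording stack with planted ROIs
#'
#' Builds an imaging stack containing flickering elliptical terminals
#' ("blobs") on a noisy background, with known masks, for validating
#' [detect_rois()]. Blobs modulate strongly over time so they stand out in
#' the temporal-SD projection; planted blobs must not overlap.
#'
#' @param roi_spec Data.frame with columns `x`, `y` (centers, pixels),
#'   `area_um2`, and optional `elongation` (major/minor ratio, default 1).
#' @param dim_px Stack height/width in pixels, `c(h, w)`.
#' @param n_frames Number of frames.
#' @param pixel_size Pixel size, micrometers.
#' @param noise_sd Background noise SD.
#' @param blob_sd Temporal modulation SD of blob pixels.
#' @param seed Integer seed.
#' @return Array h x w x frames with attribute `ground_truth` (list:
#'   `masks`, `roi_spec`, `pixel_size`).
#' @export
make_recording_stack <- function(roi_spec, dim_px = c(64, 64), n_frames = 100,
                                 pixel_size = 0.5, noise_sd = 1,
                                 blob_sd = 20, seed = 1) {
  set.seed(seed)
  h <- dim_px[1]; w <- dim_px[2]
  stack <- array(stats::rnorm(h * w * n_frames, sd = noise_sd),
                 c(h, w, n_frames))
  masks <- list()
  occupied <- matrix(FALSE, h, w)
  nr <- if (is.null(roi_spec)) 0L else nrow(roi_spec)
  for (i in seq_len(nr)) {
    a_px <- roi_spec$area_um2[i] / pixel_size^2
    el <- if ("elongation" %in% names(roi_spec)) roi_spec$elongation[i] else 1
    # ellipse with area a_px and axis ratio el
    b <- sqrt(a_px / (pi * el))
    a <- el * b
    rr <- row(occupied) - roi_spec$y[i]
    cc <- col(occupied) - roi_spec$x[i]
    mask <- (cc / a)^2 + (rr / b)^2 <= 1
    if (any(mask & occupied))
      stop("planted ROIs overlap", call. = FALSE)
    occupied <- occupied | mask
    idx <- which(mask, arr.ind = TRUE)
    flick <- stats::rnorm(n_frames, sd = blob_sd)
    for (f in seq_len(n_frames))
      stack[cbind(idx, f)] <- stack[cbind(idx, f)] + 50 + flick[f]
    masks[[i]] <- idx
  }
  attr(stack, "ground_truth") <- list(masks = masks, roi_spec = roi_spec,
                                      pixel_size = pixel_size)
  stack
}

#' Synthetic gene-count table with planted fold changes
#'
#' Negative-binomial counts for paired strike-zone (SZ) and non-SZ samples
#' (4 + 4 by default), including a highly expressed UV-opsin row, with
#' known per-gene SZ/non-SZ fold changes planted on the opsin-normalized
#' scale.
#'
#' @param n_genes Number of genes beside the opsin row.
#' @param fold_changes Planted SZ/non-SZ fold change per gene (recycled).
#' @param base_mean Baseline mean count per gene (recycled).
#' @param opsin_level Mean opsin count per sample.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param n_pairs Number of SZ/non-SZ sample pairs.
#' @param seed Integer seed.
#' @return A `count_table`: integer matrix genes x samples with columns
#'   `SZ_1..` / `nonSZ_1..`, rownames `opsin`, `gene_1..`; attribute
#'   `ground_truth` (fold changes, pairing).
#' @export
make_count_table <- function(n_genes = 50, fold_changes = 1, base_mean = 200,
                             opsin_level = 5000, dispersion = 0.05,
                             n_pairs = 4, seed = 1) {
  stopifnot(all(fold_changes > 0), n_pairs >= 1)
  set.seed(seed)
  fc <- rep_len(fold_changes, n_genes)
  bm <- rep_len(base_mean, n_genes)
  size <- 1 / dispersion
  draw <- function(mu) stats::rnbinom(length(mu), mu = mu, size = size)
  counts <- matrix(0L, n_genes + 1L, 2L * n_pairs)
  colnames(counts) <- c(paste0("SZ_", seq_len(n_pairs)),
                        paste0("nonSZ_", seq_len(n_pairs)))
  rownames(counts) <- c("opsin", paste0("gene_", seq_len(n_genes)))
  counts["opsin", ] <- pmax(1L, draw(rep(opsin_level, 2L * n_pairs)))
  for (g in seq_len(n_genes)) {
    counts[g + 1L, seq_len(n_pairs)] <- draw(rep(bm[g] * fc[g], n_pairs))
    counts[g + 1L, n_pairs + seq_len(n_pairs)] <- draw(rep(bm[g], n_pairs))
  }
  structure(counts, class = c("count_table", class(counts)),
            pairing = data.frame(sz = paste0("SZ_", seq_len(n_pairs)),
                                 nonsz = paste0("nonSZ_", seq_len(n_pairs))),
            ground_truth = list(fold_changes = fc, opsin_level = opsin_level,
                                dispersion = dispersion, seed = seed))
}

#' Synthetic flash-response traces with planted kinetics
#'
#' Generates per-intensity flash-response traces whose peak amplitudes
#' follow a planted Hill curve and whose post-peak decay is a single
#' exponential with a planted time constant, for closed-loop validation of
#' [hill_fit()], [recovery_tau()], [sensitivity_index()] and [dli()].
#'
#' @param intensities Flash intensities.
#' @param a_max,i_half,h Planted Hill parameters of the amplitude curve.
#' @param tau Planted recovery time constant, seconds.
#' @param fs Sampling rate, Hz.
#' @param duration Trace duration, seconds.
#' @param t_flash Flash time, seconds.
#' @param noise_sd Additive white-noise SD.
#' @param n_trials Trials per intensity.
#' @param seed Integer seed.
#' @return List of `traces` (list over intensities of time x trials
#'   matrices), `amplitudes` (planted peak per intensity), `t` (time axis),
#'   with attribute `ground_truth`.
#' @export
make_flash_response_set <- function(intensities, a_max = 2, i_half = 300,
                                    h = 1.5, tau = 0.5, fs = 62.5,
                                    duration = 8, t_flash = 1,
                                    noise_sd = 0, n_trials = 1, seed = 1) {
  stopifnot(all(intensities > 0), tau > 0)
  set.seed(seed)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amp <- a_max * intensities^h / (intensities^h + i_half^h)
  shape <- ifelse(t < t_flash, 0, exp(-(t - t_flash) / tau))
  traces <- lapply(seq_along(intensities), function(i) {
    m <- matrix(rep(amp[i] * shape, n_trials), ncol = n_trials)
    if (noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m))
    m
  })
  structure(list(traces = traces, amplitudes = amp, t = t,
                 intensities = intensities),
            ground_truth = list(a_max = a_max, i_half = i_half, h = h,
                                tau = tau, noise_sd = noise_sd, seed = seed))
}
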