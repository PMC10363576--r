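# Acoustic featurization: Gaussian-window log spectrogram, modulation
# power spectrum (MPS) and its deviations, and 20 bioacoustic features.

#' Gaussian-window log spectrogram
#'
#' Short-time Fourier transform with a Gaussian taper whose frequency-
#' domain SD is `window_freq_std_hz` (50 Hz default, equivalently a
#' time-domain SD of 1/(2*pi*50) = 3.18 ms), a total window of 6 SD
#' (~19 ms), and a 1 ms hop.  Magnitudes are normalized to the spectrogram
#' maximum (so playback level does not enter downstream representations)
#' and expressed in dB, floored at `-db_floor`.
#'
#' @param waveform Numeric vector of sound-pressure samples.
#' @param sample_rate_hz Sample rate (Hz), >= 20 kHz for the default
#'   10 kHz analysis ceiling.
#' @param window_freq_std_hz Gaussian window SD in the frequency domain (Hz).
#' @param hop_ms Frame hop (ms); the analysis grid is 1 ms.
#' @param freq_ceiling_hz Highest analysis frequency (Hz).
#' @param db_floor Dynamic range (dB) below the maximum retained.
#' @return Object of class `voc_spectrogram`: `times_ms`, `freqs_hz`,
#'   `log_amplitude` (freq x time, dB in `[-db_floor, 0]`), `params`.
#' @export
compute_spectrogram <- function(waveform, sample_rate_hz,
                                window_freq_std_hz = 50, hop_ms = 1,
                                freq_ceiling_hz = 10000, db_floor = 80) {
  if (any(!is.finite(waveform)))
    voc_stop("waveform contains non-finite samples", "vocnet_input_error")
  fs <- sample_rate_hz
  t_std_s <- 1 / (2 * pi * window_freq_std_hz)
  n_win <- round(6 * t_std_s * fs)
  if (n_win %% 2 == 0) n_win <- n_win + 1L
  if (length(waveform) < n_win)
    voc_stop("waveform shorter than one analysis window", "vocnet_input_error")
  half <- (n_win - 1L) / 2L
  w <- exp(-0.5 * ((seq_len(n_win) - 1L - half) / (t_std_s * fs))^2)
  hop <- round(hop_ms * 1e-3 * fs)
  centers <- seq(1L, length(waveform), by = hop)
  x <- c(numeric(half), waveform, numeric(half))
  frames <- vapply(centers, function(c0) x[c0:(c0 + n_win - 1L)] * w,
                   numeric(n_win))
  nfft <- max(nextn(n_win, 2), 512L)
  frames <- rbind(frames, matrix(0, nfft - n_win, ncol(frames)))
  spec <- Mod(mvfft(frames))
  freqs <- (seq_len(nfft) - 1L) * fs / nfft
  keep <- freqs <= freq_ceiling_hz & freqs <= fs / 2
  spec <- spec[keep, , drop = FALSE]
  mx <- max(spec)
  logamp <- if (mx > 0) 20 * log10(pmax(spec / mx, 10^(-db_floor / 20)))
            else matrix(-db_floor, nrow(spec), ncol(spec))
  structure(list(times_ms = (centers - 1L) / fs * 1e3,
                 freqs_hz = freqs[keep], log_amplitude = logamp,
                 params = list(window_std_ms = t_std_s * 1e3,
                               window_total_ms = n_win / fs * 1e3,
                               hop_ms = hop_ms,
                               freq_ceiling_hz = freq_ceiling_hz,
                               db_floor = db_floor, sample_rate_hz = fs)),
            class = "voc_spectrogram")
}

#' Time-domain Gaussian window SD for a given frequency-domain SD
#'
#' For a Gaussian taper, SDs in the two domains satisfy
#' `sigma_t = 1 / (2 * pi * sigma_f)`; a 50 Hz frequency SD corresponds
#' to 3.18 ms in the time domain.
#'
#' @param freq_std_hz Frequency-domain SD (Hz).
#' @return Time-domain SD in milliseconds.
#' @export
gaussian_window_time_std_ms <- function(freq_std_hz) {
  1e3 / (2 * pi * freq_std_hz)
}

#' Modulation power spectrum of a spectrogram
#'
#' Windows the log spectrogram with a Gaussian taper (SD 16.7 ms, total
#' 100 ms, shifted by 33 ms), takes the 2D Fourier power of each segment
#' within the first `analysis_window_ms` of the stimulus, and averages
#' across segments.  The redundant half-plane is folded so spectral
#' modulations are nonnegative and temporal modulations signed.  Only
#' complete segments are used.
#'
#' @param spec A `voc_spectrogram`.
#' @param seg_window_std_ms,seg_window_total_ms,seg_shift_ms Segment
#'   Gaussian taper SD, total segment length, and shift (ms).
#' @param analysis_window_ms Analysis window from stimulus onset (ms).
#' @param pad_t,pad_f Zero-padded FFT lengths along the temporal (frames)
#'   and spectral (frequency-bin) axes; `NULL` keeps the native lengths.
#'   See [mps_paper_grid()] for the 103 x 192 preset.
#' @return Object of class `voc_mps`: `spectral_mod` (cycles/kHz,
#'   nonnegative, rows), `temporal_mod` (Hz, signed, columns), `power`
#'   (nonnegative matrix), `params`.
#' @export
compute_mps <- function(spec, seg_window_std_ms = 16.7,
                        seg_window_total_ms = 100, seg_shift_ms = 33,
                        analysis_window_ms = 500, pad_t = 101L, pad_f = NULL) {
  stopifnot(inherits(spec, "voc_spectrogram"))
  M <- spec$log_amplitude
  n_frames <- ncol(M)
  seg_len <- round(seg_window_total_ms)          # frames are on a 1 ms grid
  if (n_frames < seg_len)
    voc_stop("spectrogram shorter than one MPS segment", "vocnet_input_error")
  lim <- min(n_frames, round(analysis_window_ms))
  starts <- seq(1L, lim - seg_len + 1L, by = round(seg_shift_ms))
  w <- exp(-0.5 * ((seq_len(seg_len) - (seg_len + 1) / 2) / seg_window_std_ms)^2)
  n_f <- nrow(M)
  if (is.null(pad_f)) pad_f <- n_f
  if (is.null(pad_t)) pad_t <- seg_len
  if (pad_f < n_f || pad_t < seg_len)
    voc_stop("FFT padding smaller than the segment", "vocnet_input_error")
  acc <- matrix(0, floor(pad_f / 2) + 1L, pad_t)
  for (s0 in starts) {
    seg <- M[, s0:(s0 + seg_len - 1L), drop = FALSE]
    seg <- seg - mean(seg)                          # remove DC before 2D FFT
    seg <- sweep(seg, 2, w, `*`)
    padded <- matrix(0, pad_f, pad_t)
    padded[seq_len(n_f), seq_len(seg_len)] <- seg
    P <- Mod(fft(padded))^2
    acc <- acc + P[seq_len(floor(pad_f / 2) + 1L), , drop = FALSE]
  }
  power <- acc / length(starts)
  # temporal modulation axis (Hz): frames sampled at 1 kHz, fftshifted
  ft <- (seq_len(pad_t) - 1L)
  ft[ft > pad_t / 2] <- ft[ft > pad_t / 2] - pad_t
  ord <- order(ft)
  power <- power[, ord, drop = FALSE]
  temporal_mod <- ft[ord] * 1000 / pad_t
  # spectral modulation axis (cycles/kHz): frequency bins spaced df Hz
  df_khz <- (spec$freqs_hz[2] - spec$freqs_hz[1]) / 1000
  spectral_mod <- (seq_len(nrow(power)) - 1L) / (pad_f * df_khz)
  structure(list(spectral_mod = spectral_mod, temporal_mod = temporal_mod,
                 power = power,
                 params = list(seg_window_std_ms = seg_window_std_ms,
                               seg_window_total_ms = seg_window_total_ms,
                               seg_shift_ms = seg_shift_ms,
                               analysis_window_ms = analysis_window_ms,
                               pad_t = pad_t, pad_f = pad_f)),
            class = "voc_mps")
}

#' FFT padding preset reproducing a 103 x 192 modulation grid
#'
#' Returns `pad_t`/`pad_f` values for [compute_mps()] that yield 103
#' signed temporal-modulation bins and 192 nonnegative spectral-modulation
#' bins, i.e. 19,776 dimensions per flattened MPS (or MRF component).
#' The exact padding behind the published grid is not stated; this preset
#' documents one reconstruction that pins the bin counts.
#'
#' @return List with `pad_t = 103` and `pad_f = 382`.
#' @export
mps_paper_grid <- function() list(pad_t = 103L, pad_f = 382L)

#' Compute MPS for every stimulus in a set
#'
#' @param stimuli A `voc_stimulus_set` (or named list of `voc_stimulus`).
#' @param ... Passed to [compute_spectrogram()] / [compute_mps()]
#'   (arguments are routed by name).
#' @details Waveforms are zero-padded to the analysis window (500 ms by
#'   default) before the spectrogram so that every stimulus - including
#'   calls shorter than one 100 ms MPS segment - contributes the same
#'   number of full segments, analyzed in its natural silence context.
#' @return Named list of `voc_mps`, one per stimulus, on a common grid.
#' @export
mps_set <- function(stimuli, ...) {
  stims <- if (inherits(stimuli, "voc_stimulus_set")) stimuli$stimuli else stimuli
  dots <- list(...)
  spec_args <- dots[names(dots) %in% names(formals(compute_spectrogram))]
  mps_args <- dots[names(dots) %in% names(formals(compute_mps))]
  win_ms <- if (!is.null(mps_args$analysis_window_ms))
    mps_args$analysis_window_ms else 500
  lapply(stims, function(s) {
    x <- s$waveform
    need <- ceiling(win_ms * 1e-3 * s$sample_rate_hz)
    if (length(x) < need) x <- c(x, numeric(need - length(x)))
    sg <- do.call(compute_spectrogram,
                  c(list(x, s$sample_rate_hz), spec_args))
    do.call(compute_mps, c(list(sg), mps_args))
  })
}

#' MPS deviation from a reference mean
#'
#' Elementwise difference between a stimulus MPS and the mean MPS across
#' the stimulus set; deviations across the full set sum to zero.
#'
#' @param mps A `voc_mps`.
#' @param reference_mean Reference `voc_mps` (or plain matrix) on the same
#'   grid, usually the grand mean from [mps_mean()].
#' @return Matrix of deviations (may be negative) on the MPS grid.
#' @export
mps_deviation <- function(mps, reference_mean) {
  ref <- if (inherits(reference_mean, "voc_mps")) reference_mean$power
         else reference_mean
  if (!identical(dim(mps$power), dim(ref)))
    voc_stop("MPS grids do not match", "vocnet_shape_error")
  mps$power - ref
}

#' Mean MPS across a set
#' @param mps_list Named list of `voc_mps` on a common grid.
#' @return A `voc_mps` whose power is the elementwise mean.
#' @export
mps_mean <- function(mps_list) {
  out <- mps_list[[1]]
  out$power <- Reduce(`+`, lapply(mps_list, `[[`, "power")) / length(mps_list)
  out
}

#' Per-stimulus MPS deviations from the set mean
#' @param mps_list Named list of `voc_mps`.
#' @return Named list of deviation matrices (zero-mean across the set).
#' @export
mps_deviations <- function(mps_list) {
  ref <- mps_mean(mps_list)
  lapply(mps_list, mps_deviation, reference_mean = ref)
}

# internal: distribution moments of a nonnegative weight vector over x
.dist_moments <- function(x, wgt) {
  p <- wgt / sum(wgt)
  m <- sum(p * x)
  v <- sum(p * (x - m)^2)
  s <- if (v > 0) sum(p * (x - m)^3) / v^1.5 else 0
  k <- if (v > 0) sum(p * (x - m)^4) / v^2 else 0
  ent <- -sum(ifelse(p > 0, p * log2(p), 0))
  list(mean = m, sd = sqrt(v), skew = s, kurt = k, entropy = ent)
}

# internal: amplitude envelope = |analytic signal| low-passed at 50 Hz
.envelope <- function(x, fs, lp_hz = 50) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  env <- Mod(fft(X * h, inverse = TRUE) / n)
  env <- .fft_filter(env, fs, function(f) as.numeric(f <= lp_hz))
  pmax(env, 0)
}

#' Twenty predefined bioacoustic features
#'
#' Describes a vocalization with 7 temporal-envelope features (meanT,
#' stdT, skewT, kurtT, entropyT, rms, maxAmp), 8 spectral-envelope
#' features (meanS, stdS, skewS, kurtS, entropyS and the cumulative
#' quartiles Q1, Q2, Q3 in Hz) and 5 pitch features (saliency, meanF0,
#' maxF0, minF0, cvF0).  Envelope moments treat the normalized amplitude
#' envelope as a distribution over time (seconds); spectral moments treat
#' the normalized power spectrum as a distribution over frequency (Hz).
#' F0 and saliency come from framewise normalized autocorrelation
#' (25 ms frames, search band `f0_range_hz`); frames whose peak height is
#' below `voicing_threshold` are unvoiced, and fully unvoiced stimuli get
#' `NA` F0 statistics (mean-imputed later, see [cluster_acoustic()]).
#'
#' @param waveform Numeric samples.
#' @param sample_rate_hz Sample rate (Hz).
#' @param f0_range_hz Fundamental-frequency search band (Hz).
#' @param voicing_threshold Minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @return One-row data.frame with the 20 named features.
#' @export
bioacoustic_features <- function(waveform, sample_rate_hz,
                                 f0_range_hz = c(80, 1500),
                                 voicing_threshold = 0.5) {
  fs <- sample_rate_hz
  if (sum(waveform^2) == 0)
    voc_stop("zero-energy waveform", "vocnet_input_error")
  # temporal envelope on a 1 ms grid
  env <- .envelope(waveform, fs)
  step <- max(1L, round(fs / 1000))
  env_ms <- env[seq(1L, length(env), by = step)]
  t_s <- (seq_along(env_ms) - 1L) / 1000
  tm <- .dist_moments(t_s, env_ms)
  # spectral envelope: periodogram up to 10 kHz
  nfft <- nextn(length(waveform), 2)
  pw <- Mod(fft(c(waveform, numeric(nfft - length(waveform)))))^2
  freqs <- (seq_len(nfft) - 1L) * fs / nfft
  keep <- freqs <= min(10000, fs / 2)
  pw <- pw[keep]; freqs <- freqs[keep]
  sm <- .dist_moments(freqs, pw)
  cum <- cumsum(pw) / sum(pw)
  qs <- vapply(c(0.25, 0.5, 0.75), function(q) freqs[which(cum >= q)[1]], 0)
  # pitch track: 25 ms frames, 10 ms hop
  n_frame <- round(0.025 * fs)
  hop <- round(0.010 * fs)
  starts <- seq(1L, length(waveform) - n_frame + 1L, by = hop)
  lag_min <- max(2L, floor(fs / f0_range_hz[2]))
  lag_max <- ceiling(fs / f0_range_hz[1])
  f0s <- sal <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    fr <- waveform[starts[i]:(starts[i] + n_frame - 1L)]
    fr <- fr - mean(fr)
    if (sum(fr^2) == 0) next
    ac <- acf(fr, lag.max = min(lag_max, n_frame - 1L), plot = FALSE,
              demean = FALSE)$acf[, 1, 1]
    lags <- lag_min:min(lag_max, length(ac) - 1L)
    if (length(lags) < 3) next
    v <- ac[lags + 1L]
    pk <- which.max(v)
    sal[i] <- max(0, v[pk])
    f0s[i] <- fs / lags[pk]
  }
  ok <- !is.na(sal)
  saliency <- if (any(ok)) mean(sal[ok]) else 0
  voiced <- ok & sal >= voicing_threshold
  if (any(voiced)) {
    fv <- f0s[voiced]
    meanF0 <- mean(fv); maxF0 <- max(fv); minF0 <- min(fv)
    cvF0 <- if (meanF0 > 0) sd(fv) / meanF0 else 0
    if (is.na(cvF0)) cvF0 <- 0
  } else {
    meanF0 <- maxF0 <- minF0 <- cvF0 <- NA_real_
  }
  data.frame(meanT = tm$mean, stdT = tm$sd, skewT = tm$skew, kurtT = tm$kurt,
             entropyT = tm$entropy, rms = sqrt(mean(waveform^2)),
             maxAmp = max(env),
             meanS = sm$mean, stdS = sm$sd, skewS = sm$skew, kurtS = sm$kurt,
             entropyS = sm$entropy, Q1 = qs[1], Q2 = qs[2], Q3 = qs[3],
             saliency = saliency, meanF0 = meanF0, maxF0 = maxF0,
             minF0 = minF0, cvF0 = cvF0)
}

#' Feature table for a stimulus set
#' @param stimuli A `voc_stimulus_set`.
#' @param ... Passed to [bioacoustic_features()].
#' @return data.frame with `stimulus_id`, `call_type` and the 20 features.
#' @export
bioacoustic_feature_table <- function(stimuli, ...) {
  rows <- lapply(names(stimuli$stimuli), function(sid) {
    s <- stimuli$stimuli[[sid]]
    cbind(data.frame(stimulus_id = sid, call_type = s$call_type,
                     stringsAsFactors = FALSE),
          bioacoustic_features(s$waveform, s$sample_rate_hz, ...))
  })
  do.call(rbind, rows)
}
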