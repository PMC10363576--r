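# Synthetic vocalizations and tuned spiking units with known ground truth.
#
# The generator emulates the structure of a 10-call-type repertoire:
# call types differ in pitch saliency (harmonic-to-noise mixing), fundamental
# frequency, formant band, duration and amplitude modulation; units carry
# heterogeneous tuning in the modulation-power domain, onset/sustained
# temporal profiles, baseline firing and trial-to-trial Poisson noise.

#' Construct a call-type specification
#'
#' A parametric description of one vocalization category.  Waveforms are
#' synthesized as a mixture of a harmonic stack (weight = pitch saliency)
#' and band-limited noise (weight = 1 - saliency), shaped by a Gaussian
#' formant-band emphasis filter and an amplitude-modulation envelope.
#'
#' @param label Call-type label (one of [CALL_TYPES] for the standard
#'   repertoire, but any string is accepted).
#' @param f0_hz,f0_sd_hz Fundamental frequency mean and between-rendition
#'   SD (Hz); `f0_hz = 0` means unvoiced.
#' @param saliency Pitch saliency in `[0, 1]`: mixing weight of the
#'   harmonic stack versus the noise carrier.
#' @param formant_center_hz,formant_bw_hz Center and bandwidth (SD, Hz) of
#'   the Gaussian formant-band emphasis filter.
#' @param duration_s,duration_sd_s Duration mean and SD (s); mean must be
#'   positive.
#' @param am_rate_hz Amplitude-modulation rate (Hz); 0 disables AM.
#' @param level_db,level_sd_db Playback level mean and SD (dB).
#' @return An object of class `voc_call_spec`.
#' @export
call_type_spec <- function(label, f0_hz, f0_sd_hz = 0, saliency,
                           formant_center_hz, formant_bw_hz,
                           duration_s, duration_sd_s = 0,
                           am_rate_hz = 0, level_db = 70, level_sd_db = 0) {
  if (!is.numeric(saliency) || saliency < 0 || saliency > 1)
    voc_stop("saliency must lie in [0, 1]", "vocnet_parameter_error")
  if (duration_s <= 0)
    voc_stop("duration_s mean must be positive", "vocnet_parameter_error")
  if (f0_hz < 0)
    voc_stop("f0_hz must be nonnegative", "vocnet_parameter_error")
  structure(list(label = as.character(label), f0_hz = f0_hz,
                 f0_sd_hz = f0_sd_hz, saliency = saliency,
                 formant_center_hz = formant_center_hz,
                 formant_bw_hz = formant_bw_hz,
                 duration_s = duration_s, duration_sd_s = duration_sd_s,
                 am_rate_hz = am_rate_hz, level_db = level_db,
                 level_sd_db = level_sd_db),
            class = "voc_call_spec")
}

#' Default 10-call-type repertoire
#'
#' Parameter values are qualitative reconstructions of the zebra finch
#' repertoire: tonal contact calls (Te, DC, LT) with salient pitch around
#' 550--800 Hz, noisy calls (Be, Ag) with low pitch saliency and formant
#' bands above 4 kHz (Be) or near 2 kHz (Ag), the long modulated distress
#' call (Di), the tonal whine (Wh), soft nest (Ne) and short thuk (Th)
#' calls, and song (So) as a single long heterogeneous syllable string.
#' Exact per-type acoustic distributions are not published; see the
#' methods vignette for how these defaults were chosen.
#'
#' @return Named list of 10 `voc_call_spec` objects in [CALL_TYPES] order.
#' @export
default_repertoire <- function() {
  sp <- list(
    call_type_spec("Be", 500, 60, 0.20, 4600, 1200, 0.25, 0.05, 5, 70, 2),
    call_type_spec("LT", 700, 50, 0.85, 2500, 2000, 0.20, 0.04, 0, 65, 2),
    call_type_spec("Th", 900, 100, 0.50, 3000, 2500, 0.10, 0.02, 0, 68, 2),
    call_type_spec("Di", 1500, 150, 0.70, 3500, 2000, 0.40, 0.08, 20, 75, 2),
    call_type_spec("Ag", 600, 80, 0.20, 2000, 1200, 0.30, 0.06, 10, 70, 2),
    call_type_spec("Wh", 1000, 100, 0.80, 2000, 2500, 0.25, 0.05, 0, 60, 2),
    call_type_spec("Ne", 600, 60, 0.60, 2800, 2500, 0.12, 0.03, 0, 55, 2),
    call_type_spec("Te", 620, 40, 0.90, 3000, 2500, 0.15, 0.03, 0, 58, 2),
    call_type_spec("DC", 800, 80, 0.90, 3200, 2000, 0.18, 0.03, 30, 72, 2),
    call_type_spec("So", 750, 150, 0.50, 3500, 3000, 0.80, 0.10, 12, 68, 2))
  names(sp) <- vapply(sp, `[[`, "", "label")
  sp
}

# internal: raised-cosine onset/offset ramps
.apply_ramps <- function(x, fs, ramp_s = 0.01) {
  n <- length(x)
  nr <- min(round(ramp_s * fs), floor(n / 2))
  if (nr > 1) {
    r <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
    x[seq_len(nr)] <- x[seq_len(nr)] * r
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(r)
  }
  x
}

# internal: FFT-domain filter with a real, frequency-symmetric gain function
.fft_filter <- function(x, fs, gain_fun) {
  n <- length(x)
  nfft <- nextn(n, 2)
  f <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * fs / nfft
  g <- gain_fun(abs(f))
  y <- Re(fft(fft(c(x, numeric(nfft - n))) * g, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Synthesize one vocalization
#'
#' Draws rendition parameters (F0, duration, level) from the spec, builds
#' a waveform as `saliency * harmonic stack + (1 - saliency) * noise`,
#' applies the formant-band emphasis filter, the AM envelope and
#' onset/offset ramps, and scales to the sampled level.  All synthesis is
#' band-limited below 10 kHz.
#'
#' @param spec A `voc_call_spec`.
#' @param seed Integer seed; the same seed reproduces the waveform exactly.
#' @param sample_rate_hz Sample rate (Hz), default 24414.
#' @return An object of class `voc_stimulus`: list with `waveform`,
#'   `sample_rate_hz`, `call_type`, `duration_s`, `f0_hz`, `level_db`.
#' @export
synth_call <- function(spec, seed, sample_rate_hz = 24414) {
  if (!inherits(spec, "voc_call_spec"))
    voc_stop("spec must be a voc_call_spec", "vocnet_parameter_error")
  fs <- sample_rate_hz
  with_seed(seed, {
    dur <- max(0.05, rnorm(1, spec$duration_s, spec$duration_sd_s))
    f0 <- if (spec$f0_hz > 0) max(80, rnorm(1, spec$f0_hz, spec$f0_sd_hz)) else 0
    level <- rnorm(1, spec$level_db, spec$level_sd_db)
    n <- round(dur * fs)
    t <- seq_len(n) / fs
    f_max <- min(9800, fs / 2 * 0.98)

    harm <- numeric(n)
    if (f0 > 0 && spec$saliency > 0) {
      ks <- seq_len(floor(f_max / f0))
      ph <- runif(length(ks), 0, 2 * pi)
      for (j in seq_along(ks))
        harm <- harm + (1 / ks[j]) * cos(2 * pi * ks[j] * f0 * t + ph[j])
      harm <- harm / sqrt(mean(harm^2))
    }
    noise <- rnorm(n)
    noise <- .fft_filter(noise, fs, function(f) as.numeric(f > 100 & f < f_max))
    noise <- noise / sqrt(mean(noise^2))

    x <- spec$saliency * harm + (1 - spec$saliency) * noise
    fc <- spec$formant_center_hz; bw <- spec$formant_bw_hz
    x <- .fft_filter(x, fs, function(f)
      (0.1 + exp(-(f - fc)^2 / (2 * bw^2))) * (f < f_max))
    if (spec$am_rate_hz > 0)
      x <- x * (1 - 0.4 * (1 - cos(2 * pi * spec$am_rate_hz * t)))
    x <- .apply_ramps(x, fs)
    x <- x * 10^((level - 70) / 20) / sqrt(mean(x^2))
    structure(list(waveform = x, sample_rate_hz = fs,
                   call_type = spec$label, duration_s = dur,
                   f0_hz = f0, level_db = level),
              class = "voc_stimulus")
  })
}

#' Synthesize a labeled stimulus set
#'
#' Generates `n_renditions_per_type` renditions of each call type with
#' within-type variability (F0, duration and level resampled per
#' rendition).  The default configuration (10 types x 11 renditions)
#' reproduces a 110-stimulus playback set.
#'
#' @param specs List of 10 `voc_call_spec` with distinct labels
#'   (default [default_repertoire()]).
#' @param n_renditions_per_type Renditions per call type, in `[5, 15]`
#'   for the standard design (values outside are allowed with a warning).
#' @param seed Integer seed.
#' @param sample_rate_hz Sample rate (Hz).
#' @return An object of class `voc_stimulus_set`: list with `stimuli`
#'   (named list of `voc_stimulus`) and `table` (data.frame with
#'   `stimulus_id`, `call_type`, `rendition`, `duration_s`).
#' @export
synth_repertoire <- function(specs = default_repertoire(),
                             n_renditions_per_type = 11, seed = 1,
                             sample_rate_hz = 24414) {
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels))
    voc_stop("duplicate call-type labels", "vocnet_parameter_error")
  if (n_renditions_per_type < 5 || n_renditions_per_type > 15)
    warning("n_renditions_per_type outside the standard [5, 15] design")
  stimuli <- list()
  rows <- list()
  idx <- 0L
  for (i in seq_along(specs)) {
    for (r in seq_len(n_renditions_per_type)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", labels[i], r)
      stim <- synth_call(specs[[i]], seed = seed * 100003L + idx)
      stim$stimulus_id <- sid
      stimuli[[sid]] <- stim
      rows[[idx]] <- data.frame(stimulus_id = sid, call_type = labels[i],
                                rendition = r, duration_s = stim$duration_s,
                                stringsAsFactors = FALSE)
    }
  }
  structure(list(stimuli = stimuli, table = do.call(rbind, rows),
                 sample_rate_hz = sample_rate_hz),
            class = "voc_stimulus_set")
}

#' Construct a synthetic unit specification
#'
#' @param unit_id Unit identifier (string).
#' @param baseline_rate_hz Spontaneous rate (Hz), nonnegative.
#' @param gain Response gain (Hz per unit of rectified filter drive).
#' @param tuning_template Matrix on the MPS grid: the unit's ground-truth
#'   modulation-domain filter.
#' @param temporal_profile Nonnegative weight curve over the 0--500 ms
#'   response window (1 ms grid); normalized internally to mean 1.
#' @param noise_sd SD of the multiplicative (lognormal) trial gain.
#' @return An object of class `voc_unit_spec`.
#' @export
unit_spec <- function(unit_id, baseline_rate_hz, gain, tuning_template,
                      temporal_profile, noise_sd = 0) {
  if (baseline_rate_hz < 0)
    voc_stop("baseline_rate_hz must be nonnegative", "vocnet_parameter_error")
  if (any(temporal_profile < 0))
    voc_stop("temporal_profile must be nonnegative", "vocnet_parameter_error")
  tp <- temporal_profile / mean(temporal_profile)
  structure(list(unit_id = as.character(unit_id),
                 baseline_rate_hz = baseline_rate_hz, gain = gain,
                 tuning_template = tuning_template,
                 temporal_profile = tp, noise_sd = noise_sd),
            class = "voc_unit_spec")
}

#' Generate a heterogeneous population of tuned units
#'
#' Each unit's tuning template is a mixture of the mean MPS deviation of
#' one (randomly assigned) preferred call type and a smooth random filter:
#' `purity * type_mean + (1 - purity) * random`, unit-normalized.  Temporal
#' profiles are random onset/sustained mixtures (exponential-decay onset,
#' time constant ~60 ms, plus a flat sustained component).
#'
#' @param n_units Number of units.
#' @param deviations Named list of MPS deviation matrices per stimulus
#'   (from [mps_deviation()]), all on one grid.
#' @param stim_table Stimulus table with `stimulus_id` and `call_type`.
#' @param seed Integer seed.
#' @param baseline_range Range of spontaneous rates (Hz).
#' @param gain_range Range of response gains (Hz).
#' @param noise_sd Trial gain SD passed to every unit.
#' @param purity Mixing weight of the preferred-type template in `[0, 1]`.
#' @param preferred Optional vector of preferred call types (recycled to
#'   `n_units`); `NULL` assigns preferences at random.
#' @return List of `voc_unit_spec`.
#' @export
synth_units <- function(n_units, deviations, stim_table, seed = 1,
                        baseline_range = c(2, 10), gain_range = c(2, 7),
                        noise_sd = 1.2, purity = 0.4, preferred = NULL) {
  types <- unique(stim_table$call_type)
  type_means <- lapply(types, function(ct) {
    ids <- stim_table$stimulus_id[stim_table$call_type == ct]
    Reduce(`+`, deviations[ids]) / length(ids)
  })
  names(type_means) <- types
  dims <- dim(deviations[[1]])
  n_t <- 500L
  if (!is.null(preferred)) {
    preferred <- rep(preferred, length.out = n_units)
    if (!all(preferred %in% types))
      voc_stop("preferred types not present in the stimulus set",
               "vocnet_parameter_error")
  }
  with_seed(seed, {
    lapply(seq_len(n_units), function(i) {
      ct <- if (is.null(preferred)) sample(types, 1) else preferred[i]
      rnd <- matrix(rnorm(prod(dims)), dims[1], dims[2])
      # smooth the random component so templates resemble MPS structure
      k <- dnorm(-3:3); k <- k / sum(k)
      rnd <- apply(rnd, 2, function(col) as.numeric(stats::filter(col, k, circular = TRUE)))
      rnd <- t(apply(rnd, 1, function(row) as.numeric(stats::filter(row, k, circular = TRUE))))
      tm <- type_means[[ct]] / sqrt(sum(type_means[[ct]]^2))
      rnd <- rnd / sqrt(sum(rnd^2))
      tpl <- purity * tm + (1 - purity) * rnd
      tpl <- tpl / sqrt(sum(tpl^2))
      w_on <- runif(1)
      tt <- seq_len(n_t)
      prof <- w_on * exp(-tt / 60) + (1 - w_on) * 1
      unit_spec(sprintf("u%03d", i),
                baseline_rate_hz = runif(1, baseline_range[1], baseline_range[2]),
                gain = runif(1, gain_range[1], gain_range[2]),
                tuning_template = tpl, temporal_profile = prof,
                noise_sd = noise_sd)
    })
  })
}

#' Simulate spiking responses to a stimulus set
#'
#' Rate model: `rate(t) = baseline + gain * max(0, drive) * profile(t) * g`,
#' where `drive` is the inner product of the unit's tuning template with
#' the stimulus MPS deviation (standardized per unit across the stimulus
#' set), `profile(t)` covers the 0--500 ms response window, and `g` is a
#' lognormal trial gain with SD `noise_sd`.  Spikes are drawn as an
#' inhomogeneous Poisson process in 1 ms bins over
#' `[-0.5, duration + 0.5]` s relative to stimulus onset.
#'
#' @param units List of `voc_unit_spec`.
#' @param stimuli A `voc_stimulus_set`.
#' @param n_trials Trials per (unit, stimulus); at least 1.
#' @param seed Integer seed.
#' @param deviations Optional precomputed MPS deviations (named list per
#'   stimulus); computed with default parameters when omitted.
#' @return List with `spikes` (data.table: `unit_id`, `stimulus_id`,
#'   `trial`, `spike_time_s`), `trials` (complete trial index table) and
#'   `drives` (ground-truth rectified drive per unit x stimulus, for
#'   recovery tests).
#' @export
simulate_responses <- function(units, stimuli, n_trials, seed = 1,
                               deviations = NULL) {
  if (n_trials < 1) voc_stop("n_trials must be >= 1", "vocnet_parameter_error")
  if (is.null(deviations))
    deviations <- mps_deviations(mps_set(stimuli))
  st <- stimuli$table
  dev_flat <- vapply(deviations[st$stimulus_id], as.numeric,
                     numeric(length(deviations[[1]])))
  dt_bin <- 0.001
  resp_bins <- 500L
  spikes_list <- list()
  drives_list <- list()
  with_seed(seed, {
    for (u in units) {
      raw <- as.numeric(crossprod(dev_flat, as.numeric(u$tuning_template)))
      s <- sd(raw)
      drive <- pmax(0, if (s > 0) (raw - mean(raw)) / s else raw)
      drives_list[[u$unit_id]] <- data.table::data.table(
        unit_id = u$unit_id, stimulus_id = st$stimulus_id, drive = drive)
      for (si in seq_len(nrow(st))) {
        dur <- st$duration_s[si]
        n_bins <- floor((dur + 1.0) / dt_bin)
        t0 <- -0.5
        base <- rep(u$baseline_rate_hz, n_bins)
        evoked <- numeric(n_bins)
        post_idx <- seq.int(round(0.5 / dt_bin) + 1L,
                            min(n_bins, round(0.5 / dt_bin) + resp_bins))
        evoked[post_idx] <- u$gain * drive[si] *
          u$temporal_profile[seq_along(post_idx)]
        g <- if (u$noise_sd > 0)
          rlnorm(n_trials, -u$noise_sd^2 / 2, u$noise_sd) else rep(1, n_trials)
        for (tr in seq_len(n_trials)) {
          rate <- base + evoked * g[tr]
          if (any(!is.finite(rate)) || any(rate < 0))
            voc_stop("non-finite or negative rate", "vocnet_simulation_error")
          cnt <- rpois(n_bins, rate * dt_bin)
          tot <- sum(cnt)
          if (tot > 0) {
            bins <- rep.int(seq_len(n_bins), cnt)
            times <- t0 + (bins - 1L) * dt_bin + runif(tot) * dt_bin
            spikes_list[[length(spikes_list) + 1L]] <- data.table::data.table(
              unit_id = u$unit_id, stimulus_id = st$stimulus_id[si],
              trial = tr, spike_time_s = times)
          }
        }
      }
    }
  })
  trials <- data.table::CJ(unit_id = vapply(units, `[[`, "", "unit_id"),
                           stimulus_id = st$stimulus_id,
                           trial = seq_len(n_trials))
  spikes <- if (length(spikes_list))
    data.table::rbindlist(spikes_list)
  else
    data.table::data.table(unit_id = character(), stimulus_id = character(),
                           trial = integer(), spike_time_s = numeric())
  list(spikes = spikes, trials = trials,
       drives = data.table::rbindlist(drives_list))
}

#' Shuffle stimulus-to-call-type assignments (chance-level null)
#'
#' Permutes the call-type labels across stimuli so that neural responses
#' carry no class information while every marginal spike statistic is
#' unchanged.  Used to verify that the decoder performs at chance
#' (1/n_classes) under the null.
#'
#' @param stim_table Stimulus table with `stimulus_id` and `call_type`.
#' @param seed Integer seed (ignored when `perm` is given).
#' @param perm Optional explicit permutation of `seq_len(nrow(stim_table))`;
#'   the identity permutation returns the input unchanged.
#' @return The stimulus table with permuted `call_type`.
#' @export
shuffle_tuning <- function(stim_table, seed = 1, perm = NULL) {
  n <- nrow(stim_table)
  if (is.null(perm)) perm <- with_seed(seed, sample.int(n))
  out <- stim_table
  out$call_type <- stim_table$call_type[perm]
  out
}
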