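# Neural featurization: response strength Z, smoothed PSTHs and their
# principal components, selectivity and noise metrics, spike-train quality.

#' Per-trial response strength (Z)
#'
#' For each trial, the difference between the spike count in the 500 ms
#' after stimulus onset and the count in the 500 ms before, z-scored per
#' unit using the mean and SD of that difference across all trials and
#' all stimuli for the unit.  The population (1/n) SD is used so that the
#' standardization identities mean(Z) = 0 and SD(Z) = 1 hold exactly.
#'
#' @param spikes data.table/data.frame with `unit_id`, `stimulus_id`,
#'   `trial`, `spike_time_s` (onset-relative seconds).
#' @param trials Complete trial index table (`unit_id`, `stimulus_id`,
#'   `trial`) including zero-spike trials.
#' @param pre_window,post_window Count windows in seconds.
#' @return data.table with `unit_id`, `stimulus_id`, `trial`, `count_diff`,
#'   `Z`.  Units whose count differences have zero SD are dropped with a
#'   warning (degenerate units).
#' @export
response_strength <- function(spikes, trials,
                              pre_window = c(-0.5, 0),
                              post_window = c(0, 0.5)) {
  sp <- data.table::as.data.table(spikes)
  tr <- data.table::as.data.table(trials)
  if (nrow(tr) < 2)
    voc_stop("need at least 2 trials", "vocnet_input_error")
  spike_time_s <- unit_id <- stimulus_id <- trial <- NULL # NSE bindings
  cnt <- sp[, list(
    post = sum(spike_time_s >= post_window[1] & spike_time_s < post_window[2]),
    pre  = sum(spike_time_s >= pre_window[1] & spike_time_s < pre_window[2])),
    by = list(unit_id, stimulus_id, trial)]
  out <- merge(tr, cnt, by = c("unit_id", "stimulus_id", "trial"),
               all.x = TRUE)
  out[is.na(out$post), c("post", "pre")] <- 0
  out[, "count_diff"] <- out$post - out$pre
  out[, c("post", "pre")] <- NULL
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  count_diff <- NULL
  stats <- out[, list(mu = mean(count_diff), sigma = pop_sd(count_diff)),
               by = "unit_id"]
  degen <- stats$unit_id[stats$sigma == 0]
  if (length(degen)) {
    warning(sprintf("dropping %d degenerate unit(s) with zero-SD response: %s",
                    length(degen), paste(head(degen, 5), collapse = ", ")))
    out <- out[!out$unit_id %in% degen, ]
    stats <- stats[!stats$unit_id %in% degen, ]
  }
  out <- merge(out, stats, by = "unit_id")
  out[, "Z"] <- (out$count_diff - out$mu) / out$sigma
  out[, c("mu", "sigma")] <- NULL
  out[]
}

#' Smoothed peri-stimulus time histogram
#'
#' Trial-averaged firing rate on a 1 ms grid over the response window,
#' smoothed by kernel density estimation with a Gaussian kernel
#' (default SD 30 ms).  Kernel mass falling outside the window is
#' renormalized so the curve integral equals the mean in-window spike
#' count per trial.
#'
#' @param spike_times_s Spike times (s) pooled over trials.
#' @param n_trials Number of trials the spikes came from.
#' @param kernel_std_ms Gaussian kernel SD (ms).
#' @param window Response window (s).
#' @param bin_s Grid step (s).
#' @return Numeric rate curve (Hz) on the grid of bin centers; attribute
#'   `"times_s"` holds the centers.
#' @export
psth <- function(spike_times_s, n_trials, kernel_std_ms = 30,
                 window = c(0, 0.5), bin_s = 0.001) {
  grid <- seq(window[1] + bin_s / 2, window[2] - bin_s / 2, by = bin_s)
  n <- length(grid)
  counts <- numeric(n)
  st <- spike_times_s[spike_times_s >= window[1] & spike_times_s < window[2]]
  if (length(st)) {
    idx <- pmin(n, pmax(1L, floor((st - window[1]) / bin_s) + 1L))
    tab <- tabulate(idx, nbins = n)
    counts <- tab
  }
  sd_bins <- kernel_std_ms / (bin_s * 1e3)
  half <- ceiling(4 * sd_bins)
  k <- dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  padded <- c(numeric(half), counts, numeric(half))
  sm <- stats::filter(padded, k, sides = 2)[(half + 1):(half + n)]
  # edge correction: renormalize by in-window kernel mass
  mass <- stats::filter(c(numeric(half), rep(1, n), numeric(half)), k,
                        sides = 2)[(half + 1):(half + n)]
  rate <- as.numeric(sm / mass) / (n_trials * bin_s)
  attr(rate, "times_s") <- grid
  rate
}

#' PSTH matrix over (unit, stimulus) pairs
#'
#' One row per (unit, stimulus) with at least `min_trials` trials; rows
#' are smoothed PSTHs from [psth()].
#'
#' @inheritParams response_strength
#' @param min_trials Minimum trials for a (unit, stimulus) row.
#' @param ... Passed to [psth()].
#' @return List with `rates` (matrix rows x time), `index` (data.frame of
#'   `unit_id`, `stimulus_id`), `times_s`.
#' @export
psth_matrix <- function(spikes, trials, min_trials = 5, ...) {
  sp <- data.table::as.data.table(spikes)
  tr <- data.table::as.data.table(trials)
  unit_id <- stimulus_id <- trial <- NULL
  nt <- tr[, list(n_trials = length(unique(trial))),
           by = list(unit_id, stimulus_id)]
  nt <- nt[nt$n_trials >= min_trials, ]
  key <- paste(sp$unit_id, sp$stimulus_id)
  sp_split <- split(sp$spike_time_s, key)
  rows <- vector("list", nrow(nt))
  for (i in seq_len(nrow(nt))) {
    k <- paste(nt$unit_id[i], nt$stimulus_id[i])
    st <- if (k %in% names(sp_split)) sp_split[[k]] else numeric()
    rows[[i]] <- psth(st, nt$n_trials[i], ...)
  }
  rates <- do.call(rbind, rows)
  list(rates = rates, index = as.data.frame(nt[, c("unit_id", "stimulus_id")]),
       times_s = attr(rows[[1]], "times_s"))
}

#' Principal components of the population of PSTHs
#'
#' Centered PCA of the (unit, stimulus) x time PSTH matrix; one PCA per
#' dataset.  The first components capture onset/sustained/offset temporal
#' structure; single-trial spike trains are later projected onto them.
#'
#' @param psths Output of [psth_matrix()] (or a plain matrix).
#' @param n_components Number of temporal PCs to keep (default 5).
#' @return Object of class `voc_psth_basis`: `mean_psth`, `components`
#'   (time x n_components, orthonormal), `explained` (variance fractions),
#'   `times_s`.
#' @export
fit_temporal_pcs <- function(psths, n_components = 5) {
  X <- if (is.list(psths)) psths$rates else psths
  if (nrow(X) < n_components + 1)
    voc_stop("too few PSTH rows for the PCA", "vocnet_input_error")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(mean_psth = pc$center,
                 components = pc$rotation[, seq_len(n_components), drop = FALSE],
                 explained = expl[seq_len(n_components)],
                 times_s = if (is.list(psths)) psths$times_s else NULL),
            class = "voc_psth_basis")
}

#' Project a single trial onto the temporal PC basis
#'
#' Bins the spike train on the basis grid (rate units), subtracts the
#' basis centering vector and takes inner products with each component.
#' A numeric vector already on the grid (e.g. a PSTH row) is projected
#' directly.
#'
#' @param trial_spikes_s Spike times (s) of one trial, or a numeric rate
#'   vector on the basis grid.
#' @param basis A `voc_psth_basis`.
#' @param window,bin_s Binning grid, matching the basis fit.
#' @return Numeric vector of PC coefficients (length n_components).
#' @export
project_trial <- function(trial_spikes_s, basis, window = c(0, 0.5),
                          bin_s = 0.001) {
  n <- length(basis$mean_psth)
  if (length(trial_spikes_s) == n) {
    # already a curve on the basis grid (e.g. a PSTH row)
    v <- as.numeric(trial_spikes_s)
  } else {
    st <- trial_spikes_s[trial_spikes_s >= window[1] & trial_spikes_s < window[2]]
    v <- numeric(n)
    if (length(st)) {
      idx <- pmin(n, floor((st - window[1]) / bin_s) + 1L)
      v <- tabulate(idx, nbins = n) / bin_s
    }
  }
  as.numeric(crossprod(basis$components, v - basis$mean_psth))
}

#' Per-trial feature table (Z and temporal PC coefficients)
#'
#' Combines [response_strength()] and [project_trial()] into the decoder's
#' input: one row per (unit, stimulus, trial) with `Z` and `T1..Tn`.
#'
#' @inheritParams response_strength
#' @param basis A `voc_psth_basis` from [fit_temporal_pcs()].
#' @return data.table with `unit_id`, `stimulus_id`, `trial`, `Z`,
#'   `T1`..`Tn`.
#' @export
trial_features <- function(spikes, trials, basis,
                           pre_window = c(-0.5, 0), post_window = c(0, 0.5)) {
  z <- response_strength(spikes, trials, pre_window, post_window)
  sp <- data.table::as.data.table(spikes)
  n <- length(basis$mean_psth)
  bin_s <- 0.001
  key_all <- paste(z$unit_id, z$stimulus_id, z$trial, sep = "\r")
  in_win <- sp$spike_time_s >= post_window[1] & sp$spike_time_s < post_window[2]
  spw <- sp[in_win, ]
  idx <- floor((spw$spike_time_s - post_window[1]) / bin_s) + 1L
  idx <- pmin(n, pmax(1L, idx))
  key_sp <- paste(spw$unit_id, spw$stimulus_id, spw$trial, sep = "\r")
  row_of <- match(key_sp, key_all)
  keep <- !is.na(row_of)
  # project binned spike vectors without materializing the dense matrix:
  # T = (counts / bin_s) %*% components - proj(mean_psth)
  Tmat <- matrix(0, nrow(z), ncol(basis$components))
  if (any(keep)) {
    contrib <- basis$components[idx[keep], , drop = FALSE] / bin_s
    acc <- rowsum(contrib, group = row_of[keep])
    Tmat[as.integer(rownames(acc)), ] <- acc
  }
  Tmat <- Tmat - matrix(as.numeric(crossprod(basis$components, basis$mean_psth)),
                        nrow(z), ncol(Tmat), byrow = TRUE)
  colnames(Tmat) <- paste0("T", seq_len(ncol(Tmat)))
  cbind(z[, c("unit_id", "stimulus_id", "trial", "Z")], as.data.frame(Tmat))
}

#' Rate-based selectivity index
#'
#' `SI = (1 - mean(z_CT)^2 / mean(z_CT^2)) / (1 - 1/n)`, where `z_CT` is
#' the average response strength per call type.  SI is 0 when all call
#' types have the same average response strength and 1 when exactly one
#' call type has a nonzero average.
#'
#' @param z_ct Numeric vector of per-call-type mean response strengths.
#' @param n Number of classes (default `length(z_ct)`).
#' @return SI; `NA` with a warning when all `z_ct` are zero.  Because the
#'   class means are signed z-scores, the printed formula can exceed 1
#'   (its supremum is `1/(1 - 1/n)`, approached when the class means
#'   cancel); such values are returned raw with attribute
#'   `"out_of_range" = TRUE` rather than clamped.
#' @export
selectivity_index <- function(z_ct, n = length(z_ct)) {
  if (n < 2) voc_stop("need at least 2 classes", "vocnet_input_error")
  if (all(z_ct == 0)) {
    warning("selectivity index undefined: all class means are zero")
    return(NA_real_)
  }
  si <- (1 - mean(z_ct)^2 / mean(z_ct^2)) / (1 - 1 / n)
  if (si < -1e-9 || si > 1 + 1e-9) attr(si, "out_of_range") <- TRUE
  si
}

#' Within-call-type response noise
#'
#' The SD of the Z response strength across all trials and vocalizations
#' belonging to the same call type, averaged over call types.  Computed
#' with the population SD so that pooling all vocalizations into a single
#' group returns exactly 1 (the Z standardization).
#'
#' @param z Per-trial Z values.
#' @param call_type Call-type label per trial (same length as `z`).
#' @return Mean within-type SD; singleton groups are skipped with a
#'   warning.
#' @export
within_calltype_noise <- function(z, call_type) {
  groups <- split(z, call_type)
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    warning("skipping singleton call-type group(s)")
    groups <- groups[sizes >= 2]
  }
  if (!length(groups))
    voc_stop("no call-type group with >= 2 trials", "vocnet_input_error")
  mean(vapply(groups, function(g) sqrt(mean((g - mean(g))^2)), 0))
}

#' Snippet signal-to-noise ratio
#'
#' `(max - min)` of the average spike snippet divided by the mean
#' per-snippet rms.  A threshold of 5 is the conventional cutoff for
#' labeling a unit as a potential single unit.
#'
#' @param snippets Matrix, one spike waveform per row (e.g. 48 samples /
#'   2 ms, peak-centered).
#' @return Nonnegative SNR.
#' @export
snippet_snr <- function(snippets) {
  if (!is.matrix(snippets) || nrow(snippets) < 2)
    voc_stop("need >= 2 equal-length snippets", "vocnet_input_error")
  rms <- sqrt(rowMeans(snippets^2))
  if (any(rms == 0)) voc_stop("zero-rms snippet", "vocnet_input_error")
  m <- colMeans(snippets)
  (max(m) - min(m)) / mean(rms)
}

# internal: MLE rate of an exponential truncated to [a, b]
.trunc_exp_rate <- function(x, a, b) {
  xs <- x[x >= a & x <= b] - a
  if (length(xs) < 10) return(NA_real_)
  m <- mean(xs); L <- b - a
  if (m <= 0) return(Inf)
  f <- function(lam) 1 / lam - L * exp(-lam * L) / (1 - exp(-lam * L)) - m
  lo <- 1e-3; hi <- 1e4
  if (f(lo) * f(hi) > 0) return(1 / m)
  uniroot(f, c(lo, hi))$root
}

#' Refractory-period contamination quality indices
#'
#' Two indices compare the number of inter-event intervals shorter than a
#' 2 ms refractory period with the number expected from a homogeneous
#' Poisson train of matched rate.  `q_isi` estimates the rate by fitting
#' an exponential to the inter-spike-interval distribution between 10 and
#' 100 ms (maximum likelihood on the truncated window).  `q_aca`
#' estimates the rate from the spike autocorrelation in two windows
#' (10--50 ms and 250--500 ms) and uses the larger of the two.  The `p`
#' values are the Poisson tail probabilities of observing that few or
#' fewer refractory events.  Well-isolated units have q near 0; q near 1
#' is consistent with Poisson contamination; merged units exceed 1.
#'
#' @param spike_times_s Sorted or unsorted spike times (s) of one unit.
#' @param refractory_s Refractory period (s), default 2 ms.
#' @return List with `q_isi`, `p_isi`, `q_aca`, `p_aca` (`NA`s when fewer
#'   than 100 spikes).
#' @export
quality_indices <- function(spike_times_s, refractory_s = 0.002) {
  st <- sort(spike_times_s)
  n <- length(st)
  if (n < 100) {
    warning("fewer than 100 spikes: quality indices not computed")
    return(list(q_isi = NA_real_, p_isi = NA_real_,
                q_aca = NA_real_, p_aca = NA_real_))
  }
  isi <- diff(st)
  obs <- sum(isi < refractory_s)
  lam <- .trunc_exp_rate(isi, 0.010, 0.100)
  if (is.na(lam)) {
    q_isi <- p_isi <- NA_real_
  } else {
    expected <- length(isi) * (1 - exp(-lam * refractory_s))
    q_isi <- obs / expected
    p_isi <- ppois(obs, expected)
  }
  # autocorrelation-based rate: one-sided lag counts per spike per second
  pair_count <- function(a, b) {
    cnt <- 0L
    for (shift in seq_len(n - 1L)) {
      d <- st[(shift + 1L):n] - st[seq_len(n - shift)]
      if (min(d) > b) break
      cnt <- cnt + sum(d >= a & d <= b)
    }
    cnt
  }
  r1 <- pair_count(0.010, 0.050) / (n * 0.040)
  r2 <- pair_count(0.250, 0.500) / (n * 0.250)
  r <- max(r1, r2)
  obs_aca <- pair_count(0, refractory_s)
  if (r > 0) {
    expected_aca <- n * refractory_s * r
    q_aca <- obs_aca / expected_aca
    p_aca <- ppois(obs_aca, expected_aca)
  } else {
    q_aca <- p_aca <- NA_real_
  }
  list(q_isi = q_isi, p_isi = p_isi, q_aca = q_aca, p_aca = p_aca)
}

#' Screen units for auditory responsiveness
#'
#' A unit counts as auditory when at least one call type's mean response
#' strength differs from zero at `p < alpha` by a t-test across that call
#' type's trials.  (The published criterion references earlier work; this
#' reconstruction is configurable.)
#'
#' @param z_table Output of [response_strength()].
#' @param stim_table Stimulus table mapping `stimulus_id` to `call_type`.
#' @param alpha Significance level (default 0.01).
#' @return Character vector of auditory unit ids.
#' @export
screen_auditory_units <- function(z_table, stim_table, alpha = 0.01) {
  z <- merge(data.table::as.data.table(z_table),
             data.table::as.data.table(stim_table)[, c("stimulus_id", "call_type")],
             by = "stimulus_id")
  Z <- unit_id <- call_type <- NULL
  res <- z[, {
    ps <- vapply(split(Z, call_type), function(v) {
      if (length(v) < 2 || sd(v) == 0) return(1)
      stats::t.test(v)$p.value
    }, 0)
    list(p_min = min(ps))
  }, by = "unit_id"]
  res$unit_id[res$p_min < alpha]
}
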