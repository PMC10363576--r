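make_spike_table <- function(diffs) {
  # build a 1-unit spike table whose (post - pre) count differences are diffs
  trials <- data.frame(unit_id = "u", stimulus_id = "s",
                       trial = seq_along(diffs))
  rows <- lapply(seq_along(diffs), function(i) {
    k <- diffs[i]
    if (k == 0) return(NULL)
    data.frame(unit_id = "u", stimulus_id = "s", trial = i,
               spike_time_s = seq(0.01, 0.49, length.out = k))
  })
  list(spikes = do.call(rbind, rows), trials = trials)
}

test_that("response strength standardizes count differences exactly", {
  d <- make_spike_table(c(2, 4))
  z <- response_strength(d$spikes, d$trials)
  expect_equal(sort(z$Z), c(-1, 1))
  d2 <- make_spike_table(c(0, 0, 0, 4))
  z2 <- response_strength(d2$spikes, d2$trials)
  expect_equal(sort(z2$Z), c(rep(-1 / sqrt(3), 3), sqrt(3)),
               tolerance = 1e-12)
  ds <- small_dataset()
  zz <- ds$features
  for (u in unique(zz$unit_id)) {
    zu <- zz$Z[zz$unit_id == u]
    expect_equal(mean(zu), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean(zu^2)), 1, tolerance = 1e-10)
  }
})

test_that("degenerate units with zero response SD are flagged and dropped", {
  d <- make_spike_table(c(3, 3, 3))
  expect_warning(z <- response_strength(d$spikes, d$trials), "degenerate")
  expect_equal(nrow(z), 0)
})

test_that("the PSTH is a mass-preserving Gaussian smoother", {
  p0 <- psth(numeric(0), n_trials = 4)
  expect_true(all(p0 == 0))
  p1 <- psth(0.25, n_trials = 1)
  tt <- attr(p1, "times_s")
  expect_lt(abs(tt[which.max(p1)] - 0.25), 0.002)
  expect_equal(sum(p1) * 0.001, 1, tolerance = 1e-6)   # one spike
  expect_equal(max(p1), dnorm(0, sd = 0.030), tolerance = 0.02)
  # homogeneous Poisson at 20 Hz: curve within 3 SE of 20 Hz everywhere
  set.seed(33)
  n_tr <- 100
  st <- runif(rpois(1, 20 * 0.5 * n_tr), 0, 0.5)
  p <- psth(st, n_trials = n_tr)
  se <- sqrt(20 / (n_tr * 2 * sqrt(pi) * 0.030))   # KDE variance at rate 20
  expect_true(all(abs(p - 20) < 3.5 * se + 1))
})

test_that("temporal PCs capture low-dimensional PSTH structure", {
  grid <- seq(0.0005, 0.4995, by = 0.001)
  onset <- exp(-grid / 0.05)
  sustained <- rep(1, length(grid))
  # rank-1 family
  X1 <- outer(runif(20, 0.5, 2), onset)
  b1 <- fit_temporal_pcs(X1, n_components = 2)
  expect_gt(b1$explained[1], 1 - 1e-10)
  # two-template family plus small noise
  set.seed(4)
  W <- cbind(runif(60), runif(60))
  X2 <- W %*% rbind(onset, sustained) + matrix(rnorm(60 * length(grid), 0, 0.01),
                                               60)
  b2 <- fit_temporal_pcs(X2, n_components = 5)
  expect_gt(sum(b2$explained[1:2]), 0.95)
  expect_true(all(diff(b2$explained) <= 1e-12))
  # orthonormality
  G <- crossprod(b2$components)
  expect_equal(G, diag(5), tolerance = 1e-10, ignore_attr = TRUE)
  # reconstruction error is non-increasing with more components
  ctr <- sweep(X2, 2, colMeans(X2))
  err <- vapply(4:5, function(k) {
    P <- b2$components[, 1:k]
    sum((ctr - ctr %*% P %*% t(P))^2)
  }, 0)
  expect_lte(err[2], err[1] + 1e-12)
  expect_error(fit_temporal_pcs(X1[1:3, ], n_components = 5),
               class = "vocnet_input_error")
})

test_that("trial projection is exact on basis curves and linear", {
  ds <- small_dataset()
  pm <- psth_matrix(ds$responses$spikes, ds$responses$trials, min_trials = 5)
  basis <- fit_temporal_pcs(pm)
  # mean + c * component_k projects to c on axis k, 0 elsewhere
  curve <- basis$mean_psth + 2.5 * basis$components[, 3]
  tv <- project_trial(curve, basis)
  expect_equal(tv, c(0, 0, 2.5, 0, 0), tolerance = 1e-10)
  # zero-spike trial projects the negated mean
  t0 <- project_trial(numeric(0), basis)
  expect_equal(t0, as.numeric(crossprod(basis$components, -basis$mean_psth)),
               tolerance = 1e-10)
  # round-trip: PSTH rows recover their PCA scores
  ctr <- sweep(pm$rates, 2, basis$mean_psth)
  scores <- ctr %*% basis$components
  for (i in c(1, 10, 25)) {
    expect_equal(project_trial(pm$rates[i, ], basis), as.numeric(scores[i, ]),
                 tolerance = 1e-8)
  }
})

test_that("per-trial T averages approximate the projected trial-average PSTH", {
  ds <- small_dataset()
  ft <- ds$features
  pm <- psth_matrix(ds$responses$spikes, ds$responses$trials, min_trials = 5)
  i <- 17
  u <- pm$index$unit_id[i]; s <- pm$index$stimulus_id[i]
  rows <- ft[ft$unit_id == u & ft$stimulus_id == s, ]
  t_mean <- colMeans(as.matrix(rows[, paste0("T", 1:5)]))
  t_curve <- project_trial(pm$rates[i, ], ds$basis)
  # PSTH smoothing discards some mass at the edges, so agreement is loose
  expect_gt(cor(t_mean, t_curve), 0.95)
})

test_that("selectivity index matches its closed form and scale invariance", {
  expect_equal(selectivity_index(rep(0.7, 10)), 0)
  expect_equal(selectivity_index(c(2, rep(0, 9))), 1)
  expect_equal(selectivity_index(c(1, 1, rep(0, 8))), 8 / 9, tolerance = 1e-12)
  z <- c(0.3, -0.2, 1.4, 0, 0.1, -0.5, 0.9, 0.2, -0.1, 0.6)
  expect_equal(selectivity_index(z), selectivity_index(7.3 * z),
               tolerance = 1e-12)
  expect_warning(si <- selectivity_index(rep(0, 10)))
  expect_true(is.na(si))
  expect_error(selectivity_index(1, n = 1), class = "vocnet_input_error")
})

test_that("within-call-type noise reduces to known values", {
  ds <- small_dataset()
  zt <- merge(ds$features, ds$stimuli$table[, c("stimulus_id", "call_type")],
              by = "stimulus_id")
  zu <- zt[zt$unit_id == zt$unit_id[1], ]
  # pooling all vocalizations into one group returns exactly 1
  expect_equal(within_calltype_noise(zu$Z, rep("all", nrow(zu))), 1,
               tolerance = 1e-12)
  expect_equal(within_calltype_noise(c(5, 5, 5, 2, 2), c("a", "a", "a", "b", "b")), 0)
  # population SDs 0.5 and 1.5 average to 1
  expect_equal(within_calltype_noise(c(0, 1, 0, 3), c("a", "a", "b", "b")), 1)
  expect_warning(within_calltype_noise(c(1, 2, 3), c("a", "a", "b")),
                 "singleton")
})

test_that("snippet SNR matches its definition and is scale invariant", {
  base <- c(rep(0, 10), 4, rep(0, 10), -6, rep(0, 10))
  base <- base / sqrt(mean(base^2)) * 2        # rms 2, peak-to-peak scaled
  snips <- matrix(rep(base, 20), nrow = 20, byrow = TRUE)
  expect_equal(snippet_snr(snips), (max(base) - min(base)) / 2)
  expect_equal(snippet_snr(3 * snips), snippet_snr(snips), tolerance = 1e-12)
  set.seed(5)
  noise <- matrix(rnorm(500 * 48), 500)
  expect_lt(snippet_snr(noise), 0.7)
  expect_error(snippet_snr(matrix(1, 1, 10)), class = "vocnet_input_error")
})

test_that("quality indices separate Poisson, refractory and merged trains", {
  set.seed(12)
  pois <- cumsum(rexp(4000, rate = 20))
  qp <- quality_indices(pois)
  expect_gt(qp$q_isi, 0.7); expect_lt(qp$q_isi, 1.3)
  refr <- cumsum(0.003 + rexp(3000, rate = 25))
  qr <- quality_indices(refr)
  expect_equal(qr$q_isi, 0)
  expect_lt(qr$p_isi, 1e-4)
  expect_equal(qr$q_aca, 0)
  # merging two refractory units re-introduces short cross-unit intervals
  merged <- sort(c(cumsum(0.003 + rexp(2000, 20)), cumsum(0.003 + rexp(2000, 20))))
  qm <- quality_indices(merged)
  expect_gt(qm$q_isi, qr$q_isi)
  expect_gt(qm$q_isi, 0.2)
  expect_gt(qm$p_isi, qr$p_isi)
  expect_warning(qs <- quality_indices(1:50 * 0.01), "fewer than 100")
  expect_true(is.na(qs$q_isi))
})

test_that("the truncated-exponential ISI rate matches a direct likelihood oracle", {
  set.seed(3)
  isi <- rexp(5000, rate = 15)
  lam_pkg <- vocnet:::.trunc_exp_rate(isi, 0.010, 0.100)
  xs <- isi[isi >= 0.010 & isi <= 0.100] - 0.010
  loglik <- function(lam)
    sum(log(lam) - lam * xs - log(1 - exp(-lam * 0.090)))
  lam_opt <- optimize(loglik, c(0.1, 500), maximum = TRUE)$maximum
  expect_equal(lam_pkg, lam_opt, tolerance = 1e-3)
  expect_equal(lam_pkg, 15, tolerance = 0.15 * 15)
})

test_that("auditory screening keeps driven units and drops silent ones", {
  ds <- small_dataset()
  aud <- screen_auditory_units(ds$features, ds$stimuli$table)
  expect_gt(length(aud), 6)   # tuned fixture units respond
  stimuli <- synth_repertoire(n_renditions_per_type = 5, seed = 77)
  dev <- mps_deviations(mps_set(stimuli))
  units <- synth_units(4, dev, stimuli$table, seed = 2, noise_sd = 0)
  for (i in seq_along(units)) units[[i]]$gain <- 0
  resp <- simulate_responses(units, stimuli, 8, seed = 3, deviations = dev)
  z <- response_strength(resp$spikes, resp$trials)
  aud0 <- screen_auditory_units(z, stimuli$table)
  expect_lte(length(aud0), 1)  # at alpha 0.01 false positives are rare
})
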