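test_that("the MRF estimator equals a brute-force weighted average on a toy grid", {
  set.seed(1)
  devs <- lapply(1:5, function(i) matrix(rnorm(16), 4, 4))
  names(devs) <- paste0("s", 1:5)
  w <- data.frame(stimulus_id = names(devs), Z = rnorm(5), T1 = rnorm(5))
  mrf <- compute_mrf(w, devs)
  brute_z <- Reduce(`+`, Map(`*`, devs, w$Z)) / 5
  brute_t <- Reduce(`+`, Map(`*`, devs, w$T1)) / 5
  expect_equal(mrf$components$Z, brute_z, tolerance = 1e-12)
  expect_equal(mrf$components$T1, brute_t, tolerance = 1e-12)
  # zero weights give a zero MRF
  w0 <- data.frame(stimulus_id = names(devs), Z = 0)
  expect_true(all(compute_mrf(w0, devs)$components$Z == 0))
  expect_error(compute_mrf(data.frame(stimulus_id = "nope", Z = 1), devs),
               class = "vocnet_input_error")
})

test_that("indicator weights recover a call type's mean MPS deviation", {
  ds <- small_dataset()
  devs <- ds$deviations
  st <- ds$stimuli$table
  ind <- as.numeric(st$call_type == "Di")
  w <- data.frame(stimulus_id = st$stimulus_id, Z = ind)
  mrf <- compute_mrf(w, devs)
  di_mean <- Reduce(`+`, devs[st$stimulus_id[st$call_type == "Di"]]) / sum(ind)
  # proportionality: MRF = (n_Di / N) * type mean
  expect_equal(mrf$components$Z, di_mean * sum(ind) / nrow(st),
               tolerance = 1e-12)
})

test_that("MRF_Z recovers ground-truth templates, improving as noise vanishes", {
  recover_cor <- function(ds) {
    zt <- ds$features
    vapply(seq_along(ds$units), function(i) {
      u <- ds$units[[i]]
      w <- unit_mean_weights(zt, u$unit_id)[, c("stimulus_id", "Z")]
      mrf <- compute_mrf(w, ds$deviations)
      cor(as.numeric(mrf$components$Z), as.numeric(u$tuning_template))
    }, 0)
  }
  r_mod <- recover_cor(recovery_dataset())        # noise_sd = 0.5, 110 stimuli
  r_zero <- recover_cor(recovery_dataset_noiseless())
  r_high <- recover_cor(get_fixture("recovery_high", function()
    synth_dataset(n_units = 20, n_renditions = 11, n_trials = 10, seed = 7,
                  noise_sd = 1.5, purity = 0.7, gain_range = c(15, 30))))
  expect_gt(median(r_mod), 0.5)
  expect_gt(median(r_zero), median(r_high))       # recovery improves as noise falls
  expect_gt(min(r_zero), 0.3)
})

test_that("LDA recovers the closed-form two-class discriminant direction", {
  set.seed(2)
  n <- 200
  mu1 <- c(3, 0); mu2 <- c(-3, 0)
  S <- matrix(c(1, 0.4, 0.4, 2), 2)
  L <- chol(S)
  X1 <- matrix(rnorm(n * 2), n) %*% L + matrix(mu1, n, 2, byrow = TRUE)
  X2 <- matrix(rnorm(n * 2), n) %*% L + matrix(mu2, n, 2, byrow = TRUE)
  devs <- c(lapply(seq_len(n), function(i) matrix(X1[i, ], 1)),
            lapply(seq_len(n), function(i) matrix(X2[i, ], 1)))
  names(devs) <- paste0("s", seq_along(devs))
  labels <- rep(c("A", "B"), each = n)
  sp <- fit_lda(devs, labels, n_dims = 1, var_capture = 1)
  # closed form: W^-1 (mu1 - mu2), using the empirical within covariance
  W <- (cov(X1) + cov(X2)) / 2
  d_ref <- solve(W, colMeans(X1) - colMeans(X2))
  cosine <- abs(sum(sp$axes * d_ref)) /
    (sqrt(sum(sp$axes^2)) * sqrt(sum(d_ref^2)))
  expect_gt(cosine, 0.99)
  expect_error(fit_lda(devs, labels, n_dims = 3), class = "vocnet_input_error")
  expect_error(fit_lda(devs[1:3], c("A", "A", "B"), 1),
               class = "vocnet_fit_error")
})

test_that("shuffled labels give no class separation on the discriminant axes", {
  ds <- small_dataset()
  st <- ds$stimuli$table
  set.seed(9)
  sh_labels <- sample(st$call_type)
  sp <- fit_lda(ds$deviations, sh_labels, n_dims = 2)
  proj <- t(vapply(ds$deviations, function(d)
    as.numeric(crossprod(sp$axes, as.numeric(d))), numeric(2)))
  true_sp <- fit_lda(ds$deviations, st$call_type, n_dims = 2)
  proj_true <- t(vapply(ds$deviations, function(d)
    as.numeric(crossprod(true_sp$axes, as.numeric(d))), numeric(2)))
  sep <- function(p, lab) {
    mu <- apply(p, 2, tapply, lab, mean)
    sum(apply(mu, 2, var)) / sum(apply(p, 2, var))
  }
  # true labels separate centroids far better than shuffled ones
  expect_gt(sep(proj_true, st$call_type), 2 * sep(proj, sh_labels))
})

test_that("refitting LDA on its own projections changes axes only within span", {
  ds <- small_dataset()
  st <- ds$stimuli$table
  sp <- fit_lda(ds$deviations, st$call_type, n_dims = 3)
  proj <- lapply(ds$deviations, function(d)
    matrix(as.numeric(crossprod(sp$axes, as.numeric(d))), 1))
  sp2 <- fit_lda(proj, st$call_type, n_dims = 3, var_capture = 1)
  # map the refitted axes back to the ambient space and compare subspaces
  axes2 <- sp$axes %*% sp2$axes
  angles <- svd(crossprod(qr.Q(qr(sp$axes)), qr.Q(qr(axes2))))$d
  expect_true(all(angles > 1 - 1e-6))   # cosines of principal angles
})

test_that("MRF projection is exact on axes and linear", {
  ds <- small_dataset()
  sp <- fit_lda(ds$deviations, ds$stimuli$table$call_type, n_dims = 3)
  dims <- dim(ds$deviations[[1]])
  zero <- matrix(0, dims[1], dims[2])
  expect_equal(as.numeric(project_mrf(zero, sp)), c(0, 0, 0))
  ax2 <- matrix(sp$axes[, 2], dims[1], dims[2])
  expect_equal(as.numeric(project_mrf(ax2, sp)), c(0, 1, 0), tolerance = 1e-9)
  m1 <- matrix(rnorm(prod(dims)), dims[1])
  m2 <- matrix(rnorm(prod(dims)), dims[1])
  lin <- project_mrf(2.5 * m1 - 4 * m2, sp)
  expect_equal(as.numeric(lin),
               as.numeric(2.5 * project_mrf(m1, sp) - 4 * project_mrf(m2, sp)),
               tolerance = 1e-10)
  expect_error(project_mrf(matrix(0, 2, 2), sp), class = "vocnet_shape_error")
})

test_that("ensemble volume obeys determinant scaling and rotation invariance", {
  set.seed(3)
  X <- matrix(rnorm(60 * 3), 60)
  X <- sweep(X, 2, colMeans(X))
  # whiten so the sample covariance is exactly the identity
  X <- X %*% solve(chol(cov(X)))
  expect_equal(ensemble_volume(X), 1, tolerance = 1e-9)
  expect_equal(ensemble_volume(2 * X), 2^6, tolerance = 1e-6)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(ensemble_volume(X %*% Q), ensemble_volume(X), tolerance = 1e-9)
  expect_equal(ensemble_volume(matrix(1, 10, 3)), 0)
  expect_error(ensemble_volume(X[1:3, ]), class = "vocnet_input_error")
})

test_that("diversely tuned ensembles span more volume than redundant ones", {
  ds <- get_fixture("volume_ds", function()
    synth_dataset(n_units = 20, n_renditions = 5, n_trials = 6, seed = 13,
                  noise_sd = 0.3, purity = 0.9, gain_range = c(8, 20),
                  preferred = c(CALL_TYPES, rep("Di", 10))))
  st <- ds$stimuli$table
  sp <- fit_lda(ds$deviations, st$call_type, n_dims = 3)
  mrfs <- lapply(ds$units, function(u)
    compute_mrf(unit_mean_weights(ds$features, u$unit_id), ds$deviations))
  names(mrfs) <- vapply(ds$units, `[[`, "", "unit_id")
  ids <- names(mrfs)
  div <- ensemble_tuning_summary(ids[1:10], mrfs, sp)$volume   # 10 types
  red <- ensemble_tuning_summary(ids[11:20], mrfs, sp)$volume  # all Di
  expect_gt(div, red)
})

test_that("tuning-performance regression recovers exact linear structure", {
  set.seed(4)
  n <- 100
  summaries <- data.frame(volume = runif(n), mean_noise = runif(n),
                          mean_si = runif(n), mean_gs = runif(n))
  pcc <- 12 + 30 * summaries$volume
  reg <- tuning_vs_performance_regression(summaries, pcc, ns = 100, ne = 20)
  expect_equal(reg$bivariate$r2_adj, 1, tolerance = 1e-8)
  expect_equal(as.numeric(reg$bivariate$coefficients["volume"]), 30,
               tolerance = 1e-8)
  # 4 regressors + intercept from a pool of 100 with ensembles of 20: df 76
  expect_equal(reg$full$df, c(4, 76))
  expect_equal(reg$bivariate$df, c(1, 79))
  # permuted regressor: adjusted R2 hovers near zero
  pcc_perm <- sample(pcc)
  reg0 <- tuning_vs_performance_regression(summaries, pcc_perm, 100, 20)
  expect_lt(abs(reg0$bivariate$r2_adj), 0.1)
})
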