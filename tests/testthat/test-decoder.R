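test_that("naive-Bayes parameter counts scale as 2 x features x classes", {
  set.seed(1)
  y <- rep(CALL_TYPES, each = 4)
  X2 <- matrix(rnorm(40 * 12), 40)       # 2 units, Z + 5 PCs each
  expect_equal(fit_gnb(X2, y)$n_params, 240)
  X20 <- matrix(rnorm(40 * 120), 40)     # 20 units, Z + 5 PCs each
  expect_equal(fit_gnb(X20, y)$n_params, 2400)
  # a class with fewer than 2 training trials cannot be fitted
  expect_error(fit_gnb(X2[1:9, ], y[1:9]), class = "vocnet_fit_error")
})

test_that("uninformative likelihoods return the class priors", {
  set.seed(2)
  y <- rep(c("a", "b", "c"), times = c(10, 20, 30))
  X <- matrix(rep(c(1, 2), 30), 60, 2, byrow = TRUE)  # identical across classes
  m <- fit_gnb(X, y)
  p <- posterior(m, c(1, 2))
  expect_equal(as.numeric(p), c(10, 20, 30) / 60, tolerance = 1e-9)
})

test_that("posteriors follow the Gaussian product rule", {
  # symmetric two-class model, query at the midpoint
  m <- structure(list(means = matrix(c(-1, 1), 2, 1), vars = matrix(1, 2, 1),
                      priors = c(0.5, 0.5), classes = c("lo", "hi"),
                      n_params = 4L), class = "voc_gnb")
  expect_equal(as.numeric(posterior(m, 0)), c(0.5, 0.5))
  m2 <- structure(list(means = matrix(c(-10, 10), 2, 1), vars = matrix(1, 2, 1),
                       priors = c(0.5, 0.5), classes = c("lo", "hi"),
                       n_params = 4L), class = "voc_gnb")
  expect_gt(posterior(m2, 10)[, "hi"], 1 - 1e-8)
  # brute-force product-formula oracle, 3 features x 3 classes
  set.seed(3)
  y <- rep(c("a", "b", "c"), each = 7)
  X <- matrix(rnorm(21 * 3), 21)
  m3 <- fit_gnb(X, y)
  x <- rnorm(3)
  brute <- vapply(seq_len(3), function(j)
    m3$priors[j] * prod(dnorm(x, m3$means[j, ], sqrt(m3$vars[j, ]))), 0)
  expect_equal(as.numeric(posterior(m3, x)), brute / sum(brute),
               tolerance = 1e-10)
  expect_error(posterior(m3, c(1, NA, 2)), class = "vocnet_input_error")
  expect_error(posterior(m3, c(1, 2)), class = "vocnet_input_error")
})

test_that("cross-validation decodes separable features perfectly", {
  # class-specific means, tiny variance: near-identity confusion
  set.seed(4)
  st <- data.frame(stimulus_id = sprintf("s%02d", 1:30),
                   call_type = rep(CALL_TYPES, 3))
  class_mean <- setNames(seq_along(CALL_TYPES) * 10, CALL_TYPES)
  ft <- do.call(rbind, lapply(1:30, function(i)
    data.frame(unit_id = "u1", stimulus_id = st$stimulus_id[i], trial = 1:4,
               Z = rnorm(4, class_mean[st$call_type[i]], 0.01))))
  r <- cross_validate(ft, st, "u1", feature_mode = "z", n_folds = 2, seed = 5)
  expect_gt(r$pcc, 99)
  expect_equal(r$pcc_hard, 100)
  expect_equal(rowSums(r$confusion), setNames(rep(1, 10), CALL_TYPES),
               tolerance = 1e-9)
  expect_equal(r$pcc, mean(diag(r$confusion)) * 100, tolerance = 1e-12)
  expect_gt(r$mutual_information_bits, 3)
  # a call type with a single exemplar cannot be cross-validated
  drop_ids <- st$stimulus_id[st$call_type == "Be"][2:3]
  st_one <- st[!st$stimulus_id %in% drop_ids, ]
  expect_error(cross_validate(ft[!ft$stimulus_id %in% drop_ids, ],
                              st_one, "u1", feature_mode = "z"),
               class = "vocnet_cv_error")
})

test_that("ensemble sampling enumerates small sizes and caps large requests", {
  pool <- sprintf("u%03d", 1:100)
  expect_length(sample_ensembles(pool, 1), 100)
  e2 <- sample_ensembles(pool, 2)
  expect_length(e2, 4950)
  expect_warning(e_all <- sample_ensembles(pool, 100, n_samples = 5), "capped")
  expect_length(e_all, 1)
  e5 <- sample_ensembles(pool, 5, n_samples = 200, seed = 6)
  expect_length(e5, 200)
  keys <- vapply(e5, paste, "", collapse = "|")
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(sample_ensembles(pool, 5, 50, seed = 9),
                   sample_ensembles(pool, 5, 50, seed = 9))
  expect_warning(sample_ensembles(pool[1:5], 3, n_samples = 1000), "capped")
  expect_error(sample_ensembles(pool[1:5], 6), class = "vocnet_input_error")
})

test_that("re-scoring the top fraction removes selection bias on label-free data", {
  # pure-noise features: first-round top scores regress to the mean
  set.seed(7)
  st <- data.frame(stimulus_id = sprintf("s%02d", 1:30),
                   call_type = rep(CALL_TYPES, 3))
  units <- sprintf("u%02d", 1:12)
  ft <- do.call(rbind, lapply(units, function(u)
    do.call(rbind, lapply(1:30, function(i)
      data.frame(unit_id = u, stimulus_id = st$stimulus_id[i], trial = 1:3,
                 Z = rnorm(3))))))
  ens <- sample_ensembles(units, 4, n_samples = 60, seed = 8)
  res <- lapply(seq_along(ens), function(i)
    cross_validate(ft, st, ens[[i]], feature_mode = "z", seed = 100 + i))
  pcc1 <- vapply(res, `[[`, 0, "pcc")
  res2 <- refit_top_fraction(res, ft, st, fraction = 0.1, seed2 = 11)
  pcc2 <- vapply(res2, `[[`, 0, "pcc")
  top <- order(pcc1, decreasing = TRUE)[1:6]
  expect_lt(mean(pcc2[top]), mean(pcc1[top]))
  # deterministic given both seeds
  res3 <- refit_top_fraction(res, ft, st, fraction = 0.1, seed2 = 11)
  expect_equal(vapply(res3, `[[`, 0, "pcc"), pcc2)
  # fraction 1 re-scores everything
  res4 <- refit_top_fraction(res, ft, st, fraction = 1, seed2 = 11)
  expect_true(all(vapply(res4, function(r) isTRUE(attr(r, "refit")), TRUE)))
})

test_that("mutual information matches closed forms", {
  expect_equal(mutual_information(diag(10)), log2(10), tolerance = 1e-12)
  expect_equal(mutual_information(matrix(0.1, 10, 10)), 0, tolerance = 1e-12)
  bsc <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(mutual_information(bsc), 1 - h(0.9), tolerance = 1e-12)
})

test_that("entropy selectivity follows the printed formula including its domain edge", {
  expect_equal(entropy_selectivity(rep(0.1, 10)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(entropy_selectivity(c(1, rep(0, 9)))), 1)
  gs <- entropy_selectivity(rep(0.5, 10))
  expect_equal(as.numeric(gs), 1 - 5 / log2(10), tolerance = 1e-12)
  expect_lt(as.numeric(gs), 0)
  expect_true(isTRUE(attr(gs, "out_of_range")))
  expect_error(entropy_selectivity(c(0.5, 1.2)), class = "vocnet_input_error")
})

test_that("the decoder agrees with an independent naive-Bayes implementation", {
  skip_if_not_installed("e1071")
  set.seed(10)
  y <- factor(rep(c("a", "b", "c"), each = 20))
  X <- matrix(rnorm(60 * 4), 60) + as.integer(y)
  colnames(X) <- paste0("f", 1:4)
  m <- fit_gnb(X, as.character(y), var_smoothing = 0)
  ref <- e1071::naiveBayes(X, y)
  xq <- X[7, , drop = FALSE]
  p_ref <- predict(ref, xq, type = "raw")
  # e1071 uses sample variance; refit our model with matching variances
  m$vars <- t(vapply(levels(y), function(cl)
    apply(X[y == cl, ], 2, var), numeric(4)))
  expect_equal(as.numeric(posterior(m, xq)), as.numeric(p_ref),
               tolerance = 1e-6)
})
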