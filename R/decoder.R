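# Gaussian naive-Bayes call-type decoding: model fit, posteriors,
# leave-one-exemplar cross-validation, ensemble sampling, confusion
# matrices, PCC, mutual information and entropy selectivity.

#' Fit a Gaussian naive-Bayes decoder
#'
#' Per class and feature, estimates the mean and variance of a univariate
#' Gaussian; features are assumed independent within and across units.
#' Class priors are the empirical training frequencies.  A smoothing term
#' `var_smoothing * max(feature variance)` is added to every variance to
#' prevent singular likelihoods.  The fit estimates
#' `2 * n_features * n_classes` parameters (means + variances).
#'
#' @param X Numeric matrix, trials x features.
#' @param y Class label per trial.
#' @param var_smoothing Relative variance smoothing (default 1e-9).
#' @return Object of class `voc_gnb` with `means`, `vars` (class x
#'   feature), `priors`, `classes`, `n_params`.
#' @export
fit_gnb <- function(X, y, var_smoothing = 1e-9) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- unique(y)
  counts <- table(y)[classes]
  if (any(counts < 2))
    voc_stop("every class needs >= 2 training trials", "vocnet_fit_error")
  p <- ncol(X)
  means <- vars <- matrix(0, length(classes), p,
                          dimnames = list(classes, colnames(X)))
  for (i in seq_along(classes)) {
    Xi <- X[y == classes[i], , drop = FALSE]
    means[i, ] <- colMeans(Xi)
    vars[i, ] <- colMeans(Xi^2) - colMeans(Xi)^2   # population variance
  }
  eps <- var_smoothing * max(apply(X, 2, function(col) mean(col^2) - mean(col)^2),
                             .Machine$double.eps)
  vars <- vars + eps
  structure(list(means = means, vars = vars,
                 priors = as.numeric(counts) / length(y),
                 classes = classes, n_params = 2L * p * length(classes)),
            class = "voc_gnb")
}

#' Posterior class probabilities
#'
#' `p(y | x)` proportional to `P(y) * prod_i p(x_i | y)` with Gaussian
#' class-conditional likelihoods, evaluated in log space and normalized.
#'
#' @param model A `voc_gnb`.
#' @param X Numeric vector (one trial) or matrix (trials x features).
#' @return Matrix of posteriors, trials x classes, rows summing to 1.
#' @export
posterior <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(model$means))
    voc_stop("feature count does not match the model", "vocnet_input_error")
  if (any(!is.finite(X)))
    voc_stop("non-finite feature value", "vocnet_input_error")
  n <- nrow(X); k <- nrow(model$means)
  ll <- matrix(0, n, k, dimnames = list(NULL, model$classes))
  for (j in seq_len(k)) {
    mu <- model$means[j, ]; v <- model$vars[j, ]
    centered <- sweep(X, 2, mu)
    ll[, j] <- -0.5 * sum(log(2 * pi * v)) -
      0.5 * rowSums(sweep(centered^2, 2, v, `/`)) + log(model$priors[j])
  }
  mx <- apply(ll, 1, max)
  w <- exp(ll - mx)
  w / rowSums(w)
}

# internal: wide feature matrix for an ensemble.
# rows = (stimulus_id, trial), columns = per-unit feature blocks.
.ensemble_matrix <- function(features, units, feature_mode = c("zt", "z")) {
  feature_mode <- match.arg(feature_mode)
  ft <- data.table::as.data.table(features)
  ft <- ft[ft$unit_id %in% units, ]
  cols <- if (feature_mode == "z") "Z"
          else c("Z", grep("^T[0-9]+$", names(ft), value = TRUE))
  f <- data.table::dcast(ft, stimulus_id + trial ~ unit_id,
                         value.var = cols)
  if (anyNA(f))
    voc_stop("missing (unit, stimulus, trial) feature rows", "vocnet_input_error")
  fd <- as.data.frame(f)
  X <- as.matrix(fd[, setdiff(names(fd), c("stimulus_id", "trial")),
                    drop = FALSE])
  list(X = X, stimulus_id = fd$stimulus_id, trial = fd$trial)
}

#' Leave-one-exemplar cross-validated ensemble decoding
#'
#' For each fold, one exemplar stimulus per call type is held out (all of
#' its trials form the test set), the decoder is fitted on the remaining
#' stimuli, and test-trial posteriors are averaged into the confusion-
#' matrix row of the true call type.  The percent correct classification
#' (PCC) is the mean of the confusion diagonal x 100.
#'
#' @param features Per-trial feature table (`unit_id`, `stimulus_id`,
#'   `trial`, `Z`, `T1..Tn`), e.g. from [trial_features()].
#' @param stim_table Stimulus table with `stimulus_id` and `call_type`
#'   (every call type needs >= 2 exemplars).
#' @param units Ensemble unit ids.
#' @param feature_mode `"zt"` (Z plus temporal PCs) or `"z"` (rate only).
#' @param n_folds Number of random held-out-exemplar draws (default 1,
#'   matching the size-scan protocol; use more for per-ensemble
#'   precision).
#' @param seed Integer seed for the fold draws.
#' @param var_smoothing Passed to [fit_gnb()].
#' @return Object of class `voc_ensemble_result`: `units`, `k`,
#'   `feature_mode`, `confusion` (rows = true class, averaged posteriors),
#'   `pcc` (soft, percent), `pcc_hard` (argmax, percent),
#'   `mutual_information_bits`, `n_folds`.
#' @export
cross_validate <- function(features, stim_table, units,
                           feature_mode = c("zt", "z"), n_folds = 1,
                           seed = 1, var_smoothing = 1e-9) {
  feature_mode <- match.arg(feature_mode)
  st <- as.data.frame(stim_table)[, c("stimulus_id", "call_type")]
  classes <- intersect(CALL_TYPES, unique(st$call_type))
  if (!length(classes)) classes <- sort(unique(st$call_type))
  by_class <- split(st$stimulus_id, st$call_type)[classes]
  if (any(lengths(by_class) < 2))
    voc_stop("every call type needs >= 2 exemplar stimuli", "vocnet_cv_error")
  em <- .ensemble_matrix(features, units, feature_mode)
  y_all <- st$call_type[match(em$stimulus_id, st$stimulus_id)]
  k <- length(classes)
  conf <- matrix(0, k, k, dimnames = list(classes, classes))
  folds <- with_seed(seed, lapply(seq_len(n_folds), function(f)
    vapply(by_class, function(ids) sample(ids, 1), "")))
  for (f in seq_len(n_folds)) {
    held <- folds[[f]]
    test_idx <- em$stimulus_id %in% held
    model <- fit_gnb(em$X[!test_idx, , drop = FALSE], y_all[!test_idx],
                     var_smoothing = var_smoothing)
    post <- posterior(model, em$X[test_idx, , drop = FALSE])
    post <- post[, classes, drop = FALSE]
    y_test <- y_all[test_idx]
    for (cl in classes)
      conf[cl, ] <- conf[cl, ] + colMeans(post[y_test == cl, , drop = FALSE])
  }
  conf <- conf / n_folds
  hard <- mean(vapply(seq_len(k), function(i)
    as.numeric(which.max(conf[i, ]) == i), 0))
  structure(list(units = units, k = length(units),
                 feature_mode = feature_mode, confusion = conf,
                 pcc = mean(diag(conf)) * 100, pcc_hard = hard * 100,
                 mutual_information_bits = mutual_information(conf),
                 n_folds = n_folds),
            class = "voc_ensemble_result")
}

#' Sample unit ensembles from a pool
#'
#' Returns all combinations for ensembles of size 1 or 2 and `n_samples`
#' distinct random subsets (unique as sets, sampled without replacement
#' within an ensemble) for larger sizes.
#'
#' @param pool Character or integer vector of available unit ids.
#' @param k Ensemble size.
#' @param n_samples Number of random ensembles for `k > 2`.
#' @param seed Integer seed.
#' @return List of ensembles (vectors of unit ids).
#' @export
sample_ensembles <- function(pool, k, n_samples = 10000, seed = 1) {
  if (k > length(pool))
    voc_stop("k exceeds the pool size", "vocnet_input_error")
  if (k <= 2) {
    cmb <- combn(pool, k, simplify = FALSE)
    return(cmb)
  }
  total <- choose(length(pool), k)
  if (n_samples > total) {
    warning("n_samples exceeds the number of distinct ensembles; capped")
    n_samples <- total
  }
  with_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- vector("list", n_samples)
    got <- 0L
    while (got < n_samples) {
      e <- sort(sample(pool, k))
      key <- paste(e, collapse = "|")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[[got]] <- e
      }
    }
    out
  })
}

#' Re-score the top fraction of ensembles with fresh held-out exemplars
#'
#' Guards against selection bias in the upper tail of the first-round
#' decoder scores: ensembles in the top `fraction` by PCC are re-fitted
#' and re-tested with an independently drawn held-out exemplar per call
#' type, and the refreshed scores replace the first-round scores.
#'
#' @param results List of `voc_ensemble_result` from [cross_validate()].
#' @param features,stim_table As in [cross_validate()].
#' @param fraction Fraction of ensembles to re-score (default 0.05).
#' @param seed2 Seed for the second-round exemplar draws (independent of
#'   the first round).
#' @return The input list with top-fraction entries replaced by their
#'   re-scored versions (attribute `"refit"` marks them).
#' @export
refit_top_fraction <- function(results, features, stim_table,
                               fraction = 0.05, seed2 = 2) {
  pccs <- vapply(results, `[[`, 0, "pcc")
  n_top <- max(1L, ceiling(fraction * length(results)))
  top <- order(pccs, decreasing = TRUE)[seq_len(n_top)]
  for (i in seq_along(top)) {
    r <- results[[top[i]]]
    r2 <- cross_validate(features, stim_table, r$units,
                         feature_mode = r$feature_mode, n_folds = r$n_folds,
                         seed = seed2 * 100003L + i)
    attr(r2, "refit") <- TRUE
    results[[top[i]]] <- r2
  }
  results
}

#' Mutual information of a confusion matrix
#'
#' Treats the confusion matrix rows as the channel `p(decoded | true)`
#' with a prior over true classes (uniform by default) and returns the
#' mutual information of the joint distribution in bits.
#'
#' @param confusion Square matrix with rows summing to 1.
#' @param priors Prior over true classes (default uniform).
#' @return Mutual information (bits).
#' @export
mutual_information <- function(confusion, priors = NULL) {
  conf <- if (inherits(confusion, "voc_ensemble_result")) confusion$confusion
          else as.matrix(confusion)
  k <- nrow(conf)
  if (is.null(priors)) priors <- rep(1 / k, k)
  joint <- conf * priors
  pd <- colSums(joint)
  mi <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log2(joint[i, j] / (priors[i] * pd[j]))
  }
  mi
}

#' Entropy selectivity (GS) from a confusion-matrix diagonal
#'
#' `GS = 1 - Hobs / Hmax` with `Hobs = sum(-PCC_c * log2(PCC_c))` over
#' the per-class correct-classification probabilities and
#' `Hmax = log2(n_classes)`.  GS is 0 for a uniform diagonal at chance
#' and 1 for a one-hot diagonal.  The printed formula can produce values
#' below 0 when the diagonal entropies exceed `Hmax`; such values are
#' returned raw with attribute `"out_of_range" = TRUE` rather than
#' silently clamped.
#'
#' @param diag_pcc Per-class correct probabilities (confusion diagonal),
#'   each in `[0, 1]`.
#' @param n_classes Number of classes (default `length(diag_pcc)`).
#' @return GS value (attribute flags out-of-range results).
#' @export
entropy_selectivity <- function(diag_pcc, n_classes = length(diag_pcc)) {
  if (any(diag_pcc < 0 | diag_pcc > 1))
    voc_stop("diagonal probabilities must lie in [0, 1]", "vocnet_input_error")
  h <- function(p) ifelse(p > 0, -p * log2(p), 0)
  hobs <- sum(h(diag_pcc))
  gs <- 1 - hobs / log2(n_classes)
  if (gs < -1e-9 || gs > 1 + 1e-9) attr(gs, "out_of_range") <- TRUE
  gs
}
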