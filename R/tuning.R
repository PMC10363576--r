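# Modulation receptive fields, the call-type discriminant space over MPS
# features, MRF projection, and the ensemble volume-spanned metric.

#' Modulation receptive fields of one unit
#'
#' Response-weighted averages of the stimulus MPS deviations:
#' `MRF_w = (1/N) * sum_s w_s * dMPS_s` for each weighting
#' `w in {Z, T1..T5}` (trial-averaged per stimulus).  Analogous to a
#' spike-triggered average; no whitening by the stimulus autocovariance
#' is applied, so the MRFs live in the same space as the MPS and can be
#' projected onto acoustic discriminant axes directly.
#'
#' @param weights data.frame with `stimulus_id` and one column per
#'   weighting component (e.g. `Z`, `T1`..`T5`), one row per stimulus
#'   (trial-averaged).
#' @param deviations Named list of MPS deviation matrices per stimulus on
#'   a common grid.
#' @return Object of class `voc_mrf`: named list of matrices in
#'   `components`, plus `dim`.
#' @export
compute_mrf <- function(weights, deviations) {
  ids <- weights$stimulus_id
  if (!all(ids %in% names(deviations)))
    voc_stop("missing MPS deviations for some stimuli", "vocnet_input_error")
  dims <- dim(deviations[[1]])
  if (!all(vapply(deviations[ids], function(d) identical(dim(d), dims), TRUE)))
    voc_stop("MPS deviation grids do not match", "vocnet_shape_error")
  flat <- vapply(deviations[ids], as.numeric, numeric(prod(dims)))
  comp_names <- setdiff(names(weights), "stimulus_id")
  comps <- lapply(comp_names, function(nm) {
    w <- weights[[nm]]
    matrix(as.numeric(flat %*% w) / length(ids), dims[1], dims[2])
  })
  names(comps) <- comp_names
  structure(list(components = comps, dim = dims), class = "voc_mrf")
}

#' Trial-averaged response weights per stimulus for one unit
#'
#' @param features Per-trial feature table from [trial_features()].
#' @param unit Unit id.
#' @return data.frame with `stimulus_id` and mean `Z`, `T1..Tn`.
#' @export
unit_mean_weights <- function(features, unit) {
  ft <- data.table::as.data.table(features)
  ft <- ft[ft$unit_id == unit, ]
  cols <- c("Z", grep("^T[0-9]+$", names(ft), value = TRUE))
  out <- ft[, lapply(.SD, mean), by = "stimulus_id", .SDcols = cols]
  as.data.frame(out)
}

#' Fisher discriminant space over MPS features
#'
#' Estimates the eigenvectors of the between-class covariance (covariance
#' of call-type mean MPS) divided by the within-class covariance (average
#' of the per-type covariances of single-stimulus MPS).  Because the
#' ambient MPS dimensionality far exceeds the stimulus count, the data
#' are first reduced to the leading principal components capturing
#' `var_capture` of the variance; the generalized eigenproblem is solved
#' there (with a small ridge on the within matrix) and the axes are
#' Gram-Schmidt orthonormalized and mapped back to the ambient space.
#'
#' @param deviations Named list of MPS deviation matrices per stimulus.
#' @param labels Call-type label per stimulus (same order as
#'   `deviations`).
#' @param n_dims Number of discriminant axes (<= n_classes - 1).
#' @param var_capture Variance fraction kept in the PCA reduction.
#' @return Object of class `voc_lda`: `axes` (ambient x n_dims,
#'   orthonormal), `centroids` (class x n_dims), `eigenvalues`, `center`,
#'   `dim`.
#' @export
fit_lda <- function(deviations, labels, n_dims = 3, var_capture = 0.99) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (n_dims > length(classes) - 1)
    voc_stop("n_dims must be <= n_classes - 1", "vocnet_input_error")
  if (any(table(labels) < 2))
    voc_stop("every class needs >= 2 stimuli", "vocnet_fit_error")
  dims <- dim(deviations[[1]])
  X <- t(vapply(deviations, as.numeric, numeric(prod(dims))))
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0)
  varfrac <- cumsum(sv$d^2) / sum(sv$d^2)
  r <- min(which(varfrac >= var_capture))
  r <- min(r, nrow(X) - length(classes))   # keep within-class cov nonsingular
  V <- sv$v[, seq_len(r), drop = FALSE]
  Y <- Xc %*% V
  mu_c <- do.call(rbind, lapply(classes, function(cl)
    colMeans(Y[labels == cl, , drop = FALSE])))
  B <- cov(mu_c)
  W <- Reduce(`+`, lapply(classes, function(cl)
    cov(Y[labels == cl, , drop = FALSE]))) / length(classes)
  ridge <- 1e-8 * mean(diag(W))
  eg <- eigen(solve(W + ridge * diag(r), B))
  ord <- order(Re(eg$values), decreasing = TRUE)
  A <- Re(eg$vectors[, ord[seq_len(n_dims)], drop = FALSE])
  A <- qr.Q(qr(A))                          # orthonormalize in reduced space
  axes <- V %*% A
  centroids <- mu_c %*% A
  rownames(centroids) <- classes
  structure(list(axes = axes, centroids = centroids,
                 eigenvalues = Re(eg$values[ord[seq_len(n_dims)]]),
                 center = center, dim = dims),
            class = "voc_lda")
}

#' Project MRF components into the discriminant space
#'
#' Inner products of each (flattened) MRF component with each
#' discriminant axis.  MRFs are built from centered MPS deviations, so no
#' additional centering is applied.
#'
#' @param mrf A `voc_mrf` (or a single matrix/vector in the ambient
#'   space).
#' @param space A `voc_lda`.
#' @return Matrix of coordinates, components x n_dims.
#' @export
project_mrf <- function(mrf, space) {
  mats <- if (inherits(mrf, "voc_mrf")) mrf$components else list(mrf)
  D <- nrow(space$axes)
  out <- t(vapply(mats, function(m) {
    v <- as.numeric(m)
    if (length(v) != D)
      voc_stop("MRF dimensionality does not match the space", "vocnet_shape_error")
    as.numeric(crossprod(space$axes, v))
  }, numeric(ncol(space$axes))))
  rownames(out) <- names(mats)
  out
}

#' Volume spanned by an ensemble's MRF coordinates
#'
#' Determinant of the 3x3 (or `n_dims` x `n_dims`) covariance of the
#' projected MRF coordinates; for an ensemble of k units with 6 MRF
#' components each, the covariance is computed from 6k vectors.  Tiny
#' negative determinants from floating point are clipped to 0.
#'
#' @param coords Matrix of projected coordinates (>= 4 rows).
#' @return Nonnegative volume (determinant of the coordinate covariance).
#' @export
ensemble_volume <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4)
    voc_stop("need >= 4 projected vectors", "vocnet_input_error")
  max(0, det(cov(coords)))
}

#' Per-ensemble tuning summary
#'
#' Projects every unit's 6 MRF components into the discriminant space and
#' assembles the volume spanned plus ensemble means of the unit
#' selectivity/noise metrics.
#'
#' @param units Ensemble unit ids.
#' @param mrfs Named list of `voc_mrf` per unit.
#' @param space A `voc_lda`.
#' @param unit_stats Optional data.frame with `unit_id` and columns
#'   `si`, `gs`, `noise` (unit metrics to average).
#' @return One-row data.frame: `volume`, `log10_volume`, and `mean_si`/
#'   `mean_gs`/`mean_noise` when `unit_stats` is given.
#' @export
ensemble_tuning_summary <- function(units, mrfs, space, unit_stats = NULL) {
  coords <- do.call(rbind, lapply(units, function(u)
    project_mrf(mrfs[[u]], space)))
  vol <- ensemble_volume(coords)
  # raw determinant (arbitrary MPS units) plus its log for regressions
  out <- data.frame(volume = vol,
                    log10_volume = if (vol > 0) log10(vol) else NA_real_)
  if (!is.null(unit_stats)) {
    us <- unit_stats[match(units, unit_stats$unit_id), ]
    for (col in intersect(c("si", "gs", "noise"), names(us)))
      out[[paste0("mean_", col)]] <- mean(us[[col]], na.rm = TRUE)
  }
  out
}

#' Regress decoder performance on ensemble tuning metrics
#'
#' Fits the bivariate model `PCC ~ volume` and the 4-regressor model
#' `PCC ~ volume + mean_noise + mean_si + mean_gs` by ordinary least
#' squares, with inference corrected for the overlap between ensembles
#' drawn from a finite unit pool ([corrected_f_test()]): the F statistic
#' uses the effective sample size `neff = ns - ne + 1` and denominator
#' df `neff - k`.
#'
#' @param summaries data.frame of ensemble summaries (one row per
#'   ensemble) containing the regressor columns.
#' @param pcc Decoder PCC per ensemble (aligned with `summaries`).
#' @param ns Unit pool size.
#' @param ne Ensemble size.
#' @param regressors Character vector of regressor column names for the
#'   full model.
#' @return List with `bivariate` and `full`, each a `voc_corrected_stat`
#'   augmented with `coefficients` and `r2_adj`.
#' @export
tuning_vs_performance_regression <- function(summaries, pcc, ns, ne,
                                             regressors = c("volume", "mean_noise",
                                                            "mean_si", "mean_gs")) {
  regressors <- intersect(regressors, names(summaries))
  n <- length(pcc)
  fit_one <- function(vars) {
    k <- length(vars) + 1L
    if (n < k + 1) voc_stop("fewer ensembles than parameters", "vocnet_fit_error")
    df <- data.frame(pcc = pcc, summaries[vars])
    fit <- lm(pcc ~ ., data = df)
    SSe <- sum(fit$residuals^2)
    SSt <- sum((pcc - mean(pcc))^2)
    ft <- corrected_f_test(SSt, SSe, k, n, effective_n(ns, ne))
    ft$r2_adj <- r2_adjusted(SSe, SSt, n, k)
    ft$coefficients <- stats::coef(fit)
    ft
  }
  full <- if (effective_n(ns, ne) > length(regressors) + 1) {
    fit_one(regressors)
  } else {
    warning("effective sample size too small for the full model; skipped")
    NULL
  }
  list(bivariate = fit_one(regressors[1]), full = full)
}
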