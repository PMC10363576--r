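# Ensemble-corrected inference for overlapping ensembles sampled from a
# finite unit pool.  Ensembles of size ne drawn from ns units share units,
# so the usual SEM over the number of sampled ensembles is far too small;
# the corrected variance, effective sample size neff = ns - ne + 1 and the
# corrected degrees of freedom restore approximately nominal coverage.

#' Corrected sample variance for overlapping ensembles
#'
#' `sc2 = ns / (ns - ne) * snc2`, where `snc2` is the ordinary sample
#' variance across the sampled ensembles.
#'
#' @param snc2 Naive sample variance across ensembles (>= 0).
#' @param ns Unit pool size.
#' @param ne Ensemble size (`1 <= ne < ns`).
#' @return Corrected variance.
#' @export
corrected_variance <- function(snc2, ns, ne) {
  if (ne >= ns) voc_stop("requires ne < ns", "vocnet_domain_error")
  if (snc2 < 0) voc_stop("variance must be nonnegative", "vocnet_domain_error")
  ns / (ns - ne) * snc2
}

#' Effective sample size for overlapping ensembles
#'
#' `neff = ns - ne + 1`.
#'
#' @param ns Unit pool size.
#' @param ne Ensemble size (`1 <= ne <= ns`).
#' @return Effective sample size.
#' @export
effective_n <- function(ns, ne) {
  if (ne > ns || ne < 1) voc_stop("requires 1 <= ne <= ns", "vocnet_domain_error")
  ns - ne + 1
}

#' Corrected standard error of an ensemble-mean estimate
#'
#' `sem = sqrt(sc2) / sqrt(neff)`.
#'
#' @param sc2 Corrected variance from [corrected_variance()].
#' @param neff Effective sample size from [effective_n()].
#' @return Standard error.
#' @export
corrected_sem <- function(sc2, neff) {
  if (neff < 1) voc_stop("neff must be >= 1", "vocnet_domain_error")
  sqrt(sc2) / sqrt(neff)
}

#' Ensemble-corrected F test for a linear model
#'
#' `F = (neff / n) * ((SSt - SSe) / (k - 1)) / se2` with
#' `se2 = SSe / (n - k)`, tested on `df = (k - 1, neff - k)`.  The naive
#' and corrected mean squares are inflated by the same ensemble-overlap
#' factor, so only the effective sample size enters the statistic and
#' the degrees of freedom.  Reduces to the classical F test when
#' `neff = n`.
#'
#' @param SSt Total sum of squares (>= SSe).
#' @param SSe Residual sum of squares (>= 0).
#' @param k Number of fitted parameters (intercept + regressors), >= 2.
#' @param n Number of sampled ensembles (> k).
#' @param neff Effective sample size (> k).
#' @return Object of class `voc_corrected_stat` with `statistic`,
#'   `df` (numerator, denominator), `p_value`, `neff`, `n`, `k`.
#' @export
corrected_f_test <- function(SSt, SSe, k, n, neff) {
  if (SSe < 0 || SSt < SSe)
    voc_stop("requires SSt >= SSe >= 0", "vocnet_domain_error")
  if (n <= k || k < 2)
    voc_stop("requires n > k >= 2", "vocnet_domain_error")
  if (neff <= k) voc_stop("requires neff > k", "vocnet_df_error")
  se2 <- SSe / (n - k)
  Fstat <- (neff / n) * ((SSt - SSe) / (k - 1)) / se2
  df1 <- k - 1
  df2 <- neff - k
  structure(list(statistic = Fstat, df = c(df1, df2),
                 p_value = pf(Fstat, df1, df2, lower.tail = FALSE),
                 neff = neff, n = n, k = k, SSt = SSt, SSe = SSe),
            class = "voc_corrected_stat")
}

#' Ensemble-corrected t tests
#'
#' Paired (`df = neff - 1`) or two-sample (`df = neff1 + neff2 - 2`)
#' t tests whose standard errors use the corrected variance and effective
#' sample size rather than the number of sampled ensembles.
#'
#' @param x Ensemble values (first sample).
#' @param y Second sample (paired partner or second group); omit for a
#'   one-sample test of `mean(x) = mu`.
#' @param ns,ne Pool and ensemble sizes for `x` (and for `y` unless
#'   `ns2`/`ne2` are given).
#' @param ns2,ne2 Pool/ensemble sizes for `y` in a two-sample test with
#'   unequal designs.
#' @param paired Paired test on `x - y`.
#' @param mu Null value for the (paired or one-sample) mean.
#' @return Object of class `voc_corrected_stat` with `estimate`, `sem`,
#'   `statistic`, `df`, `p_value` (two-sided), `neff`.
#' @export
corrected_t_test <- function(x, y = NULL, ns, ne, ns2 = ns, ne2 = ne,
                             paired = FALSE, mu = 0) {
  neff <- effective_n(ns, ne)
  if (paired || is.null(y)) {
    d <- if (is.null(y)) x else x - y
    snc2 <- var(d)
    if (!is.finite(snc2) || snc2 == 0) {
      warning("degenerate variance in corrected t test")
      est <- mean(d) - mu
      return(structure(list(estimate = est, sem = 0,
                            statistic = if (est == 0) 0 else sign(est) * Inf,
                            df = neff - 1,
                            p_value = if (est == 0) 1 else 0,
                            neff = neff),
                       class = "voc_corrected_stat"))
    }
    sc2 <- corrected_variance(snc2, ns, ne)
    sem <- corrected_sem(sc2, neff)
    tstat <- (mean(d) - mu) / sem
    df <- neff - 1
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    return(structure(list(estimate = mean(d) - mu, sem = sem,
                          statistic = tstat, df = df, p_value = p,
                          neff = neff),
                     class = "voc_corrected_stat"))
  }
  neff2 <- effective_n(ns2, ne2)
  sc2_x <- corrected_variance(var(x), ns, ne)
  sc2_y <- corrected_variance(var(y), ns2, ne2)
  df <- neff + neff2 - 2
  sp2 <- ((neff - 1) * sc2_x + (neff2 - 1) * sc2_y) / df
  sem <- sqrt(sp2 * (1 / neff + 1 / neff2))
  tstat <- (mean(x) - mean(y)) / sem
  structure(list(estimate = mean(x) - mean(y), sem = sem,
                 statistic = tstat, df = df,
                 p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE),
                 neff = c(neff, neff2)),
            class = "voc_corrected_stat")
}

#' Adjusted R-squared from sums of squares
#'
#' `R2adj = 1 - (SSe / (n - k)) / (SSt / (n - 1))`; unbiased as an effect
#' size for ensemble analyses because numerator and denominator are
#' inflated by the same overlap factor.  May be negative.
#'
#' @param SSe Residual sum of squares.
#' @param SSt Total sum of squares (> 0).
#' @param n Number of sampled ensembles.
#' @param k Number of fitted parameters.
#' @return Adjusted R-squared.
#' @export
r2_adjusted <- function(SSe, SSt, n, k) {
  if (n <= k) voc_stop("requires n > k", "vocnet_domain_error")
  if (SSt <= 0) {
    warning("SSt is zero: adjusted R-squared undefined")
    return(NA_real_)
  }
  1 - (SSe / (n - k)) / (SSt / (n - 1))
}

#' @export
print.voc_corrected_stat <- function(x, ...) {
  if (length(x$df) == 2)
    cat(sprintf("ensemble-corrected F(%d, %d) = %.4g, p = %.4g\n",
                x$df[1], x$df[2], x$statistic, x$p_value))
  else
    cat(sprintf("ensemble-corrected t(%d) = %.4g, p = %.4g (sem = %.4g)\n",
                x$df, x$statistic, x$p_value, x$sem))
  invisible(x)
}
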