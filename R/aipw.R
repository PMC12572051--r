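# The augmented inverse-probability-weighting (AIPW) ATE estimator with
# cross-fitting and repeated sample splitting. Per observation,
#   psi_i = [ T_i Y_i / pi_i - (T_i - pi_i)/pi_i * g1_i ]
#         - [ (1-T_i) Y_i / (1-pi_i) + (T_i - pi_i)/(1-pi_i) * g0_i ],
# tau_hat = mean(psi). Dropping the (T - pi) adjustment terms gives the
# pure IPW estimator; with zero outcome residuals only the outcome model
# matters (g-computation) -- both identities are tested exactly.
#
# Repeated splitting: R independent partitions; the reported estimate is
# the median of the R per-resample estimates, with variance aggregated
# by the median rule var = median_r(var_r + (tau_r - tau)^2) so that the
# interval accounts for partition-to-partition spread.

#' AIPW influence summands
#'
#' @param sample a \code{shockdml_sample} (needs \code{y}, \code{treated}).
#' @param predictions data.table with \code{pi}, \code{g1}, \code{g0}
#'   aligned with the sample rows (as from
#'   \code{\link{fit_predict_crossfit}}).
#' @return numeric vector psi with \code{mean(psi)} the ATE estimate.
#' @export
aipw_summands <- function(sample, predictions) {
  t_vec <- sample$treated
  y <- sample$y
  pi <- predictions$pi
  g1 <- predictions$g1
  g0 <- predictions$g0
  if (length(pi) != length(y)) {
    abort_fmt("predictions do not cover the sample (%d vs %d rows)",
              length(pi), length(y))
  }
  if (any(pi <= 0 | pi >= 1)) {
    abort_fmt("propensity scores must lie strictly inside (0, 1)")
  }
  (t_vec * y / pi - (t_vec - pi) / pi * g1) -
    ((1 - t_vec) * y / (1 - pi) + (t_vec - pi) / (1 - pi) * g0)
}

#' Pure inverse-probability-weighting ATE
#'
#' @param sample a \code{shockdml_sample}.
#' @param pi propensity scores in (0, 1).
#' @return the IPW estimate \code{mean(T*Y/pi - (1-T)*Y/(1-pi))}.
#' @export
ipw_ate <- function(sample, pi) {
  if (any(pi <= 0 | pi >= 1)) {
    abort_fmt("propensity scores must lie strictly inside (0, 1)")
  }
  mean(sample$treated * sample$y / pi -
         (1 - sample$treated) * sample$y / (1 - pi))
}

new_ate_estimate <- function(estimate, se, per_resample, psi_matrix,
                             n, n_treated, K, learner, seed, timing = NULL) {
  z <- qnorm(0.95)
  structure(list(
    estimate = estimate, se = se,
    ci_lower = estimate - z * se, ci_upper = estimate + z * se,
    per_resample = per_resample, psi_matrix = psi_matrix,
    n = n, n_treated = n_treated, K = K, R = nrow(per_resample),
    learner = learner, seed = seed, timing = timing),
    class = "shockdml_ate")
}

#' @export
print.shockdml_ate <- function(x, ...) {
  tm <- x$timing
  if (!is.null(tm)) {
    cat(sprintf("ATE of %s shock on %s at lag %d\n", tm$domain, tm$outcome,
                tm$lag))
  }
  cat(sprintf("  estimate %.4f (se %.4f), 90%% CI [%.4f, %.4f]\n",
              x$estimate, x$se, x$ci_lower, x$ci_upper))
  cat(sprintf("  n = %d (treated %d), K = %d, R = %d, learner = %s\n",
              x$n, x$n_treated, x$K, x$R, x$learner))
  invisible(x)
}

# median-rule aggregation of per-resample (tau_r, sigma2_r)
aggregate_resamples <- function(taus, sigma2s) {
  tau <- median(taus)
  se <- sqrt(median(sigma2s + (taus - tau)^2))
  list(estimate = tau, se = se)
}

#' Cross-fitted AIPW ATE with repeated sample splitting
#'
#' Runs the full double/debiased procedure: R independent partitions into
#' K splits, per-split nuisance estimation and prediction, the AIPW
#' estimate per resample, and median aggregation across resamples.
#'
#' @param sample a \code{shockdml_sample}.
#' @param spec a \code{\link{learner_spec}}.
#' @param K number of cross-fitting splits (default 5).
#' @param R number of resamples (reference configuration: 15).
#' @param seed master seed; resample and fold seeds are derived from it.
#' @return a \code{shockdml_ate} with the median estimate, median-rule
#'   standard error, 90% confidence interval, per-resample results and
#'   the N x R matrix of AIPW summands.
#' @export
ddml_ate <- function(sample, spec = learner_spec(), K = 5L, R = 15L,
                     seed = 1L) {
  if (R < 1) abort_fmt("R must be >= 1")
  n <- nrow(sample)
  n_treated <- sum(sample$treated)
  if (n_treated == 0L || n_treated == n) {
    abort_fmt("sample needs both treated and control rows (treated = %d)",
              n_treated)
  }
  seeds_r <- child_seeds(seed, R)
  psi_matrix <- matrix(NA_real_, n, R)
  taus <- sigma2s <- numeric(R)
  for (r in seq_len(R)) {
    preds <- fit_predict_crossfit(sample, spec, K = K, seed = seeds_r[r])
    psi <- aipw_summands(sample, preds)
    psi_matrix[, r] <- psi
    taus[r] <- mean(psi)
    sigma2s[r] <- sum((psi - taus[r])^2) / n^2
  }
  agg <- aggregate_resamples(taus, sigma2s)
  per_resample <- data.table::data.table(r = seq_len(R), tau = taus,
                                         sigma2 = sigma2s,
                                         seed = seeds_r)
  new_ate_estimate(agg$estimate, agg$se, per_resample, psi_matrix,
                   n, n_treated, K, spec$kind, seed,
                   timing = attr(sample, "timing"))
}

#' Individual-level effect estimates
#'
#' The per-row AIPW summand averaged over resamples (arithmetic mean, so
#' subgroup averages of individual effects reproduce subgroup means of
#' the per-resample estimates).
#'
#' @param ate a \code{shockdml_ate} from \code{\link{ddml_ate}}.
#' @return numeric vector, one entry per sample row.
#' @export
individual_effects <- function(ate) {
  rowMeans(ate$psi_matrix)
}

#' Subgroup ATE from stored summands
#'
#' Averages the AIPW summands over a row subset per resample, then
#' aggregates across resamples exactly as the full estimate does.
#'
#' @param ate a \code{shockdml_ate}.
#' @param mask logical vector over sample rows (non-empty subset).
#' @return a \code{shockdml_ate} for the subgroup.
#' @export
subgroup_ate <- function(ate, mask) {
  mask <- as.logical(mask)
  if (length(mask) != nrow(ate$psi_matrix)) {
    abort_fmt("mask length %d does not match sample size %d",
              length(mask), nrow(ate$psi_matrix))
  }
  m <- sum(mask)
  if (m == 0L) abort_fmt("subgroup mask is empty")
  sub <- ate$psi_matrix[mask, , drop = FALSE]
  taus <- colMeans(sub)
  sigma2s <- vapply(seq_len(ncol(sub)), function(r) {
    sum((sub[, r] - taus[r])^2) / m^2
  }, numeric(1))
  agg <- aggregate_resamples(taus, sigma2s)
  per_resample <- data.table::data.table(r = seq_len(ncol(sub)), tau = taus,
                                         sigma2 = sigma2s,
                                         seed = ate$per_resample$seed)
  new_ate_estimate(agg$estimate, agg$se, per_resample, sub, m, NA_integer_,
                   ate$K, ate$learner, ate$seed, timing = ate$timing)
}

#' Naive group-mean difference (descriptive benchmark)
#'
#' @param sample a \code{shockdml_sample}.
#' @return list with \code{estimate}, \code{se} (two-sample), and the
#'   90% confidence bounds.
#' @export
naive_difference <- function(sample) {
  y1 <- sample$y[sample$treated == 1L]
  y0 <- sample$y[sample$treated == 0L]
  if (!length(y1) || !length(y0)) abort_fmt("both arms must be non-empty")
  est <- mean(y1) - mean(y0)
  se <- sqrt(var(y1) / length(y1) + var(y0) / length(y0))
  z <- qnorm(0.95)
  list(estimate = est, se = se, ci_lower = est - z * se,
       ci_upper = est + z * se, n = nrow(sample), n_treated = length(y1))
}
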