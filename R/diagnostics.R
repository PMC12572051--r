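# Balance, descriptive, sensitivity and attrition diagnostics around the
# main estimates.

#' Absolute standardized mean differences (covariate balance)
#'
#' ASMD per covariate: |mean_1 - mean_0| / sqrt((s1^2 + s0^2)/2), where
#' for a binary covariate the variance is p(1-p). Values above 0.1 are
#' flagged as imbalanced. Zero pooled variance yields ASMD 0 when the
#' means agree and an incomputable flag otherwise.
#'
#' @param sample a \code{shockdml_sample} with both arms non-empty.
#' @return data.table (covariate, asmd, imbalanced, incomputable),
#'   sorted by descending ASMD.
#' @export
asmd <- function(sample) {
  if (!all(c(0L, 1L) %in% sample$treated)) {
    abort_fmt("both arms must be non-empty")
  }
  cols <- sample_covariates(sample)
  tr <- sample$treated == 1L
  res <- lapply(cols, function(cl) {
    x <- sample[[cl]]
    x1 <- x[tr]
    x0 <- x[!tr]
    binary <- all(x %in% c(0, 1))
    if (binary) {
      p1 <- mean(x1); p0 <- mean(x0)
      v1 <- p1 * (1 - p1); v0 <- p0 * (1 - p0)
      m1 <- p1; m0 <- p0
    } else {
      m1 <- mean(x1); m0 <- mean(x0)
      v1 <- var(x1); v0 <- var(x0)
    }
    pooled <- sqrt((v1 + v0) / 2)
    if (pooled == 0) {
      if (m1 == m0) {
        data.table::data.table(covariate = cl, asmd = 0,
                               incomputable = FALSE)
      } else {
        data.table::data.table(covariate = cl, asmd = NA_real_,
                               incomputable = TRUE)
      }
    } else {
      data.table::data.table(covariate = cl, asmd = abs(m1 - m0) / pooled,
                             incomputable = FALSE)
    }
  })
  out <- data.table::rbindlist(res)
  out[, imbalanced := !is.na(asmd) & asmd > 0.1]
  data.table::setorderv(out, "asmd", order = -1L, na.last = TRUE)
  data.table::setcolorder(out, c("covariate", "asmd", "imbalanced",
                                 "incomputable"))
  out[]
}

# 2x2 chi-squared without continuity correction:
# chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
chisq_2x2 <- function(a, b, c_, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c_ <- as.numeric(c_); d <- as.numeric(d)  # avoid integer overflow
  n <- a + b + c_ + d
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (den == 0) return(list(statistic = NA_real_, p_value = NA_real_))
  stat <- n * (a * d - b * c_)^2 / den
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Pre-treatment outcome comparison by shock status
#'
#' For each outcome x shock-domain cell: the size of the t+0 estimation
#' sample, the share with a "good habit" at the pre-shock period overall
#' and by treatment arm, and the chi-squared p-value (no continuity
#' correction) for equality across arms.
#'
#' @param panel a \code{shockdml_panel} or panel data.table.
#' @param outcomes,domains cells to tabulate.
#' @param threshold shock threshold.
#' @return data.table, one row per outcome x domain.
#' @export
pretreatment_outcome_table <- function(panel, outcomes = OUTCOMES,
                                       domains = DOMAINS, threshold = 0.25) {
  rows <- list()
  for (o in outcomes) {
    for (d in domains) {
      s0 <- min(lag_grid(o))
      smp <- build_sample(panel, timing_spec(o, d, s0), threshold)
      y_pre <- smp$y_pre
      tr <- smp$treated == 1L
      a <- sum(y_pre[tr] == 1L); b <- sum(y_pre[tr] == 0L)
      c_ <- sum(y_pre[!tr] == 1L); d_ <- sum(y_pre[!tr] == 0L)
      ch <- chisq_2x2(a, b, c_, d_)
      rows[[paste(o, d)]] <- data.table::data.table(
        outcome = o, domain = d, n = nrow(smp),
        share_pre = mean(y_pre), n_shock = sum(tr),
        share_pre_shock = mean(y_pre[tr]),
        n_noshock = sum(!tr), share_pre_noshock = mean(y_pre[!tr]),
        chisq = ch$statistic, p_value = ch$p_value)
    }
  }
  data.table::rbindlist(rows)
}

#' Sensitivity of the ATE to the shock-definition threshold
#'
#' Re-estimates the ATE over a grid of relative-drop thresholds
#' (reference grid: 1% to 40% in steps of 1). Cells with fewer treated
#' units than \code{min_treated} are flagged and not estimated (extreme
#' thresholds make shocks rare and estimates unstable).
#'
#' @param panel a \code{shockdml_panel} or panel data.table.
#' @param timing a \code{\link{timing_spec}}.
#' @param spec a \code{\link{learner_spec}}.
#' @param thresholds threshold grid in (0, 1).
#' @param K,R,seed passed to \code{\link{ddml_ate}}.
#' @param min_treated minimum treated count to attempt estimation.
#' @return data.table (threshold, n, n_treated, flagged, estimate, se,
#'   ci_lower, ci_upper); flagged rows carry NA estimates.
#' @export
threshold_sensitivity <- function(panel, timing, spec = learner_spec(),
                                  thresholds = seq(0.01, 0.40, by = 0.01),
                                  K = 5L, R = 3L, seed = 1L,
                                  min_treated = 30L) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort_fmt("thresholds must lie in (0, 1)")
  }
  rows <- lapply(thresholds, function(th) {
    smp <- tryCatch(build_sample(panel, timing, threshold = th),
                    error = function(e) NULL)
    if (is.null(smp)) {
      return(data.table::data.table(
        threshold = th, n = 0L, n_treated = 0L, flagged = TRUE,
        estimate = NA_real_, se = NA_real_, ci_lower = NA_real_,
        ci_upper = NA_real_))
    }
    nt <- sum(smp$treated)
    if (nt < min_treated || nt == nrow(smp)) {
      return(data.table::data.table(
        threshold = th, n = nrow(smp), n_treated = nt, flagged = TRUE,
        estimate = NA_real_, se = NA_real_, ci_lower = NA_real_,
        ci_upper = NA_real_))
    }
    est <- ddml_ate(smp, spec, K = K, R = R, seed = seed)
    data.table::data.table(
      threshold = th, n = est$n, n_treated = est$n_treated, flagged = FALSE,
      estimate = est$estimate, se = est$se, ci_lower = est$ci_lower,
      ci_upper = est$ci_upper)
  })
  data.table::rbindlist(rows)
}

#' Cell-specific attrition rates
#'
#' Starting from the t+0 estimation sample, the share of each
#' (treatment status x baseline outcome) cell that no longer provides
#' the behavioral outcome at each later lag.
#'
#' @param panel a \code{shockdml_panel} or panel data.table.
#' @param outcome,domain analysis cell.
#' @param threshold shock threshold.
#' @return data.table (lag, treated, y_baseline, n_cell, attrition_rate).
#' @export
attrition_rates <- function(panel, outcome, domain, threshold = 0.25) {
  dt <- as_panel_dt(panel)
  lags <- lag_grid(outcome)
  base <- build_sample(panel, timing_spec(outcome, domain, min(lags)),
                       threshold)
  ycol <- paste0("y_", outcome)
  t_ref <- attr(base, "timing")$reference_year
  cells <- base[, c("id", "treated", "y"), with = FALSE]
  data.table::setnames(cells, "y", "y_baseline")
  rows <- list()
  for (s in lags[-1]) {
    yv <- dt[dt$year == t_ref + s, c("id", ycol), with = FALSE]
    m <- merge(cells, yv, by = "id", all.x = TRUE)
    m$missing_out <- is.na(m[[ycol]])
    agg <- m[, list(n_cell = .N, attrition_rate = mean(missing_out)),
             by = c("treated", "y_baseline")]
    agg$lag <- s
    rows[[as.character(s)]] <- agg
  }
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("lag", "treated", "y_baseline", "n_cell",
                                 "attrition_rate"))
  data.table::setorderv(out, c("lag", "treated", "y_baseline"))
  out[]
}

#' DDML analysis of attrition as an outcome
#'
#' Treats "behavioral outcome not observed at t+s" as the dependent
#' variable and runs the same cross-fitted AIPW estimator per lag.
#'
#' @param panel a \code{shockdml_panel} or panel data.table.
#' @param outcome,domain analysis cell.
#' @param lags lags to analyze (default: all later lags of the outcome).
#' @param spec a \code{\link{learner_spec}}.
#' @param threshold shock threshold.
#' @param K,R,seed passed to \code{\link{ddml_ate}}.
#' @return named list of \code{shockdml_ate}, one per lag.
#' @export
attrition_effect <- function(panel, outcome, domain,
                             lags = lag_grid(outcome)[-1],
                             spec = learner_spec(), threshold = 0.25,
                             K = 5L, R = 3L, seed = 1L) {
  out <- list()
  for (s in lags) {
    smp <- attrition_outcome(panel, timing_spec(outcome, domain, s),
                             threshold)
    out[[as.character(s)]] <- ddml_ate(smp, spec, K = K, R = R, seed = seed)
  }
  out
}
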