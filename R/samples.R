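# Estimation-sample construction under the fixed-reference-year timing
# design: the shock is measured over the window (t-2, t], the outcome at
# t+s, and all conditioning information strictly before t. Individuals
# whose shock status is non-computable over the window (missing scores)
# are excluded from both arms; the control group is everyone without a
# flagged shock in the window, unconditional on later health events.

#' Timing specification of one analysis
#'
#' @param outcome "smoke", "diet" or "sport".
#' @param domain "physical" or "mental".
#' @param lag years between the reference year and outcome measurement
#'   (must lie on the outcome's availability grid).
#' @param reference_year the fixed year t closing the shock window;
#'   defaults to the design's reference year for the outcome (2004 for
#'   smoking/sports, 2006 for diet).
#' @param covariate_mode "t_minus_2" (the default conditioning set) or
#'   "full_history" (append all observed pre-shock waves, see
#'   \code{\link{attach_history}}).
#' @param placebo logical; marks shifted-window placebo analyses.
#' @return an object of class \code{shockdml_timing}.
#' @export
timing_spec <- function(outcome, domain, lag,
                        reference_year = REFERENCE_YEARS[[outcome]],
                        covariate_mode = c("t_minus_2", "full_history"),
                        placebo = FALSE) {
  if (!outcome %in% OUTCOMES) abort_fmt("unknown outcome '%s'", outcome)
  if (!domain %in% DOMAINS) abort_fmt("unknown domain '%s'", domain)
  covariate_mode <- match.arg(covariate_mode)
  lag <- as.integer(lag)
  reference_year <- as.integer(reference_year)
  if (reference_year %% 2L != 0L) {
    abort_fmt("reference_year must be a score-wave (even) year")
  }
  if (!placebo && (reference_year + lag) %% 2L != outcome_parity(outcome)) {
    abort_fmt("lag %d is off the %s availability grid", lag, outcome)
  }
  structure(list(outcome = outcome, domain = domain, lag = lag,
                 reference_year = reference_year,
                 covariate_mode = covariate_mode, placebo = placebo),
            class = "shockdml_timing")
}

outcome_parity <- function(outcome) {
  switch(outcome, smoke = 0L, diet = 0L, sport = 1L)
}

#' Lags at which an outcome can be analyzed
#'
#' Smoking is observed every even year 2002-2018 (lags 0, 2, ..., 14 from
#' reference 2004); healthy diet every even year 2004-2014 (lags 0-8 from
#' reference 2006); doing sports every odd year (lags 1, 3, ..., 15).
#'
#' @param outcome outcome name.
#' @param config generator configuration defining the panel years
#'   (default: the package default years 2001-2019).
#' @return integer vector of lags, ascending.
#' @export
lag_grid <- function(outcome, config = generator_config(n_individuals = 1)) {
  ys <- outcome_years(config, outcome)
  t_ref <- REFERENCE_YEARS[[outcome]]
  sort(ys[ys >= t_ref] - t_ref)
}

# covariates measured at t-2 for all rows of `dt` (one row per id):
# static columns + time-varying dummies and scores at t-2
covariates_at <- function(panel_dt, year_tm2, suffix = "_tm2") {
  cols <- c("id", CONTINUOUS_COVARIATES, names(STATIC_BINARIES),
            TIME_VARYING_BINARIES, "mcs", "pcs")
  x <- panel_dt[panel_dt$year == year_tm2, cols, with = FALSE]
  data.table::setnames(x, c("mcs", "pcs"),
                       paste0(c("mcs", "pcs"), suffix))
  for (tv in TIME_VARYING_BINARIES) {
    data.table::setnames(x, tv, paste0(tv, suffix))
  }
  x
}

# last availability year of `outcome` strictly before `year`
pre_outcome_year <- function(panel_dt, outcome, year) {
  col <- paste0("y_", outcome)
  ys <- sort(unique(panel_dt$year[!is.na(panel_dt[[col]])]))
  ys <- ys[ys < year]
  if (!length(ys)) return(NA_integer_)
  max(ys)
}

#' Build one estimation sample
#'
#' Assembles (Y at t+s, shock indicator T over (t-2, t], covariates at
#' t-2 including the pre-shock outcome level) for one timing
#' specification. Rows are kept only when the shock indicator is
#' computable, the outcome at t+s is observed, and the t-2 conditioning
#' information is complete.
#'
#' @param panel a \code{shockdml_panel} or its panel data.table.
#' @param timing a \code{\link{timing_spec}}.
#' @param threshold relative-drop threshold defining the shock.
#' @return a \code{shockdml_sample}: data.table with columns \code{id},
#'   \code{y}, \code{treated} and the covariate block; attributes
#'   \code{timing}, \code{threshold}, \code{n_treated}.
#' @export
build_sample <- function(panel, timing, threshold = 0.25) {
  dt <- as_panel_dt(panel)
  t_ref <- timing$reference_year
  s <- timing$lag
  y_year <- t_ref + s
  ycol <- paste0("y_", timing$outcome)
  if (!y_year %in% dt$year) {
    abort_fmt("panel does not cover outcome year %d", y_year)
  }

  flags <- flag_panel_shocks(dt, timing$domain, threshold)
  flags <- flags[flags$year == t_ref, c("id", "shock"), with = FALSE]
  if (!nrow(flags)) {
    abort_fmt("no computable shock indicators at reference year %d", t_ref)
  }

  yv <- dt[dt$year == y_year, c("id", ycol), with = FALSE]
  data.table::setnames(yv, ycol, "y")
  yv <- yv[!is.na(yv$y), ]

  x <- covariates_at(dt, t_ref - 2L)
  pre_y <- pre_outcome_year(dt, timing$outcome, t_ref)
  if (!is.na(pre_y)) {
    pv <- dt[dt$year == pre_y, c("id", ycol), with = FALSE]
    data.table::setnames(pv, ycol, "y_pre")
    x <- merge(x, pv, by = "id")
  }

  out <- merge(merge(yv, flags, by = "id"), x, by = "id")
  data.table::setnames(out, "shock", "treated")
  out <- out[complete.cases(out), ]
  data.table::setcolorder(out, c("id", "y", "treated"))
  as_sample(out, timing, threshold)
}

as_sample <- function(dt, timing, threshold) {
  if (!nrow(dt)) abort_fmt("estimation sample is empty")
  data.table::setattr(dt, "timing", timing)
  data.table::setattr(dt, "threshold", threshold)
  data.table::setattr(dt, "class", c("shockdml_sample", class(dt)))
  dt
}

#' Covariate column names of an estimation sample
#' @param sample a \code{shockdml_sample}.
#' @return character vector (everything except id, y, treated).
#' @export
sample_covariates <- function(sample) {
  setdiff(names(sample), c("id", "y", "treated"))
}

#' @export
print.shockdml_sample <- function(x, ...) {
  tm <- attr(x, "timing")
  cat(sprintf("<shockdml_sample> %s ~ %s shock, t=%d, lag %d\n",
              tm$outcome, tm$domain, tm$reference_year, tm$lag))
  cat(sprintf("  n = %d (treated %d), %d covariates, threshold %.2f\n",
              nrow(x), sum(x$treated), length(sample_covariates(x)),
              attr(x, "threshold")))
  invisible(x)
}

#' Placebo (pre-treatment) estimation samples
#'
#' Shifts the shock window ahead (default: shocks between
#' \code{shift_reference - 2} and \code{shift_reference = 2012}) and
#' measures outcomes before the shifted window. Since every outcome
#' predates the shock, nonzero estimates signal differential pre-trends
#' rather than causal effects. Conditioning mirrors the main design:
#' covariates (and scores) at t-2 plus the last pre-window value of each
#' behavior. Outcome years run from \code{t - 2 - max_abs_lag} up to the
#' year strictly before the analyzed behavior's own conditioning lag, so
#' no variable serves as outcome and control at once.
#'
#' @param panel a \code{shockdml_panel} or panel data.table.
#' @param outcome,domain analysis cell.
#' @param shift_reference shifted reference year (even).
#' @param threshold shock threshold.
#' @param max_abs_lag use placebo lags down to \code{-max_abs_lag}.
#' @return named list of \code{shockdml_sample}, one per negative lag
#'   (names are the lags).
#' @export
build_placebo_samples <- function(panel, outcome, domain,
                                  shift_reference = 2012L, threshold = 0.25,
                                  max_abs_lag = 10L) {
  dt <- as_panel_dt(panel)
  t_ref <- as.integer(shift_reference)
  ycol <- paste0("y_", outcome)
  obs_years <- sort(unique(dt$year[!is.na(dt[[ycol]])]))
  own_cond_year <- max(obs_years[obs_years <= t_ref - 2L])
  p_years <- obs_years[obs_years < own_cond_year &
                         obs_years >= t_ref - 2L - max_abs_lag]
  if (!length(p_years)) abort_fmt("insufficient pre-period for placebo")

  flags <- flag_panel_shocks(dt, domain, threshold)
  flags <- flags[flags$year == t_ref, c("id", "shock"), with = FALSE]
  if (!nrow(flags)) {
    abort_fmt("no computable shock indicators at shifted reference %d",
              t_ref)
  }
  x <- covariates_at(dt, t_ref - 2L)
  for (o in OUTCOMES) {
    oc <- paste0("y_", o)
    oys <- sort(unique(dt$year[!is.na(dt[[oc]])]))
    oys <- oys[oys <= t_ref - 2L]
    if (!length(oys)) next
    pv <- dt[dt$year == max(oys), c("id", oc), with = FALSE]
    data.table::setnames(pv, oc, paste0("y_lag_", o))
    x <- merge(x, pv, by = "id")
  }

  out <- list()
  for (yr in p_years) {
    s <- yr - t_ref
    yv <- dt[dt$year == yr, c("id", ycol), with = FALSE]
    data.table::setnames(yv, ycol, "y")
    yv <- yv[!is.na(yv$y), ]
    smp <- merge(merge(yv, flags, by = "id"), x, by = "id")
    data.table::setnames(smp, "shock", "treated")
    smp <- smp[complete.cases(smp), ]
    data.table::setcolorder(smp, c("id", "y", "treated"))
    tm <- timing_spec(outcome, domain, lag = s,
                      reference_year = t_ref, placebo = TRUE)
    out[[as.character(s)]] <- as_sample(smp, tm, threshold)
  }
  out
}

#' Append the full pre-shock covariate history
#'
#' Adds, for every observed score wave up to t-2, the time-varying
#' covariates (scores, self-assessed-health and utilization dummies) and
#' the outcome lags. Rows lacking any part of the history are dropped
#' (count reported via message and the \code{n_dropped_history}
#' attribute).
#'
#' @param sample a \code{shockdml_sample} built with
#'   \code{covariate_mode = "full_history"} in mind.
#' @param panel the panel the sample was built from.
#' @return the sample with the history block appended.
#' @export
attach_history <- function(sample, panel) {
  dt <- as_panel_dt(panel)
  tm <- attr(sample, "timing")
  t_ref <- tm$reference_year
  waves <- sort(unique(dt$year[!is.na(dt$mcs) | !is.na(dt$pcs)]))
  hist_waves <- waves[waves <= t_ref - 2L]
  hist_waves <- hist_waves[hist_waves != t_ref - 2L]  # t-2 already present
  if (!length(hist_waves)) abort_fmt("no pre-period waves before %d", t_ref)

  out <- data.table::copy(sample)
  ycol <- paste0("y_", tm$outcome)
  for (w in hist_waves) {
    blk <- covariates_at(dt, w, suffix = paste0("_", w))
    keep <- c("id", grep("^(mcs|pcs|sah_|hospital_stay|doctor_visits)",
                         names(blk), value = TRUE))
    blk <- blk[, keep, with = FALSE]
    yb <- dt[dt$year == w, c("id", ycol), with = FALSE]
    if (any(!is.na(yb[[ycol]]))) {
      data.table::setnames(yb, ycol, paste0("y_pre_", w))
      blk <- merge(blk, yb, by = "id")
    }
    out <- merge(out, blk, by = "id")
  }
  n_before <- nrow(out)
  out <- out[complete.cases(out), ]
  n_dropped <- nrow(sample) - nrow(out)
  if (n_dropped > 0) {
    message(sprintf("attach_history: dropped %d rows lacking full history",
                    n_dropped))
  }
  tm$covariate_mode <- "full_history"
  res <- as_sample(out, tm, attr(sample, "threshold"))
  data.table::setattr(res, "n_dropped_history", n_dropped)
  res
}

#' Attrition as an outcome
#'
#' Builds the estimation sample whose outcome is "behavioral outcome not
#' observed at t+s" (absorbing dropout or temporary non-response). Unlike
#' \code{\link{build_sample}}, rows are not dropped for a missing
#' behavior at t+s -- that missingness is the outcome.
#'
#' @inheritParams build_sample
#' @return a \code{shockdml_sample} with \code{y} = attrition indicator.
#' @export
attrition_outcome <- function(panel, timing, threshold = 0.25) {
  dt <- as_panel_dt(panel)
  t_ref <- timing$reference_year
  y_year <- t_ref + timing$lag
  ycol <- paste0("y_", timing$outcome)
  if (!y_year %in% dt$year) {
    abort_fmt("panel does not cover outcome year %d", y_year)
  }
  flags <- flag_panel_shocks(dt, timing$domain, threshold)
  flags <- flags[flags$year == t_ref, c("id", "shock"), with = FALSE]
  yv <- dt[dt$year == y_year, c("id", ycol), with = FALSE]
  yv$y <- as.integer(is.na(yv[[ycol]]))
  yv[[ycol]] <- NULL

  x <- covariates_at(dt, t_ref - 2L)
  pre_y <- pre_outcome_year(dt, timing$outcome, t_ref)
  if (!is.na(pre_y)) {
    pv <- dt[dt$year == pre_y, c("id", ycol), with = FALSE]
    data.table::setnames(pv, ycol, "y_pre")
    x <- merge(x, pv, by = "id")
  }
  out <- merge(merge(yv, flags, by = "id"), x, by = "id")
  data.table::setnames(out, "shock", "treated")
  out <- out[complete.cases(out), ]
  data.table::setcolorder(out, c("id", "y", "treated"))
  as_sample(out, timing, threshold)
}
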