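# Synthetic panel generation.
#
# Latent health per domain d (physical/mental) and individual i follows
#   L_{i,d,w} = mu_{i,d} + a_{i,d,w},  a AR(1) across biannual score waves,
# normalized so Var(L) = 1 at the baseline wave. Observed scores are
#   score = 50 + sqrt(100 - noise_sd^2) * L + N(0, noise_sd^2), clipped to
# [0, 100], so the baseline cross-section has mean 50 and SD 10 -- the
# norm-population standardization of the SF-12 component summaries.
# Health shocks emerge endogenously: with a covariate-dependent hazard an
# individual suffers a large latent drop at a wave; the analysis-side
# treatment indicator is the relative-drop rule (>25% below the score two
# years earlier), which also fires occasionally on ordinary fluctuation.
#
# Treatment effects are injected additively on the probability scale for
# individuals *flagged* in the outcome's reference window, so the
# ground-truth ATE equals the configured delta exactly (common random
# numbers make null effects exactly null). Outcomes depend on covariates
# and their own two-year lag but not on concurrent latent health; the
# shock-behavior link is therefore confounded only through information
# available at t-2, which is what makes parameter recovery a fair test of
# the estimator.

TREATMENT_THRESHOLD <- 0.25

#' Generate a synthetic SOEP-like panel with ground truth
#'
#' @param config a \code{\link{generator_config}}.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return an object of class \code{shockdml_panel}: a list with
#'   \describe{
#'     \item{panel}{long data.table, one row per (id, year): scores
#'       (\code{mcs}, \code{pcs}; present only on score-wave years),
#'       outcomes \code{y_smoke}, \code{y_diet}, \code{y_sport} (present
#'       only on their availability years), an \code{attrited} flag, and
#'       the covariate columns.}
#'     \item{truth}{data.table of potential outcomes per (id, outcome,
#'       domain, lag): \code{y1}, \code{y0}, and the realized reference
#'       treatment flag \code{treated}.}
#'     \item{config, seed}{the inputs, for provenance.}
#'   }
#' @export
generate_panel <- function(config, seed = config$seed) {
  validate_config(config)
  with_seed(seed, generate_panel_impl(config, seed))
}

generate_panel_impl <- function(cfg, seed) {
  n <- cfg$n_individuals
  waves <- score_wave_years(cfg)
  W <- length(waves)
  s_mu <- cfg$latent_heterogeneity_sd
  s_a <- sqrt(1 - s_mu^2)
  scale_score <- sqrt(100 - cfg$score_noise_sd^2)

  # --- permanent health component and covariates -----------------------
  mu <- list(physical = rnorm(n, 0, s_mu), mental = rnorm(n, 0, s_mu))
  covs <- r_covariates(n, (mu$physical + mu$mental) / 2)

  # --- outcome chains need shock flags at the reference waves, which in
  # turn need scores; but drop hazards need lagged behaviors. The loop
  # below therefore advances wave by wave: (1) latent/drop/score update,
  # then (2) outcomes of that calendar year and the following odd year.
  latent <- list(physical = matrix(NA_real_, n, W),
                 mental = matrix(NA_real_, n, W))
  scores <- list(physical = matrix(NA_real_, n, W),
                 mental = matrix(NA_real_, n, W))
  drop_event <- list(physical = matrix(FALSE, n, W),
                     mental = matrix(FALSE, n, W))

  # observed outcome values, keyed by outcome then calendar year
  yrs_by_outcome <- lapply(OUTCOMES, function(o) outcome_years(cfg, o))
  names(yrs_by_outcome) <- OUTCOMES
  y_obs <- lapply(OUTCOMES, function(o) {
    m <- matrix(NA_integer_, n, length(yrs_by_outcome[[o]]))
    colnames(m) <- as.character(yrs_by_outcome[[o]])
    m
  })
  names(y_obs) <- OUTCOMES

  # potential-outcome chains, per outcome x domain x arm
  pot <- list()

  # reference-window treatment flags per outcome domain (true scores)
  treat <- list()

  last_outcome_before <- function(o, year) {
    ys <- yrs_by_outcome[[o]]
    ys <- ys[ys < year]
    if (!length(ys)) return(NULL)
    y_obs[[o]][, as.character(max(ys))]
  }

  # behaviors entering the drop hazard at wave `year`: the last value
  # observed at or before year - 2, i.e. strictly outside the shock
  # window (year - 2, year], so that all confounding flows through
  # pre-window information
  lagged_behaviors <- function(year) {
    out <- list()
    for (o in OUTCOMES) {
      v <- last_outcome_before(o, year - 1L)
      if (!is.null(v)) out[[paste0("y_", o, "_lag")]] <- v
    }
    out
  }

  sim_outcome_year <- function(o, year) {
    # advance observed + potential chains of outcome o to `year`
    ys <- yrs_by_outcome[[o]]
    t_ref <- REFERENCE_YEARS[[o]]
    j <- match(year, ys)
    xb <- cfg$outcome_intercepts[[o]] +
      linear_index(cfg$outcome_coefficients[[o]], covs)
    gamma <- cfg$state_dependence[[o]]
    prev_obs <- if (j == 1L) NULL else y_obs[[o]][, j - 1L]
    u <- runif(n)
    s <- year - t_ref

    if (is.null(prev_obs)) {
      # stationarity-flavored initialization: lag replaced by its target
      eta0 <- xb + gamma * cfg$baseline_prevalence[[o]]
    } else {
      eta0 <- xb + gamma * prev_obs
    }

    if (s < 0 || is.null(treat[[o]])) {
      y <- as.integer(u < plogis(eta0))
      y_obs[[o]][, j] <<- y
      return(invisible(NULL))
    }

    Tp <- treat[[o]]$physical
    Tm <- treat[[o]]$mental
    dp <- effect_delta(cfg, covs, o, "physical", s)
    dm <- effect_delta(cfg, covs, o, "mental", s)

    key <- o
    if (is.null(pot[[key]])) {
      # chains split off from the shared pre-reference history
      init <- prev_obs  # may be NULL when the first observed year == t_ref
      pot[[key]] <<- list(p1 = init, p0 = init, m1 = init, m0 = init)
    }
    ch <- pot[[key]]
    lag_or <- function(v) if (is.null(v)) cfg$baseline_prevalence[[o]] else v
    draw <- function(lag_prev, d_phys, d_ment) {
      p <- plogis(xb + gamma * lag_or(lag_prev)) + d_phys + d_ment
      as.integer(u < clip(p, 0, 1))
    }
    y_p1 <- draw(ch$p1, dp * 1, dm * Tm)
    y_p0 <- draw(ch$p0, dp * 0, dm * Tm)
    y_m1 <- draw(ch$m1, dp * Tp, dm * 1)
    y_m0 <- draw(ch$m0, dp * Tp, dm * 0)
    pot[[key]] <<- list(p1 = y_p1, p0 = y_p0, m1 = y_m1, m0 = y_m0)

    y_obs[[o]][, j] <<- ifelse(Tp == 1L, y_p1, y_p0)

    truth_rows[[length(truth_rows) + 1L]] <<- data.table::data.table(
      id = seq_len(n), outcome = o, domain = "physical", lag = s,
      y1 = y_p1, y0 = y_p0, treated = Tp)
    truth_rows[[length(truth_rows) + 1L]] <<- data.table::data.table(
      id = seq_len(n), outcome = o, domain = "mental", lag = s,
      y1 = y_m1, y0 = y_m0, treated = Tm)
    invisible(NULL)
  }

  truth_rows <- list()
  conf_w <- cfg$confounding_weights
  dmag <- cfg$drop_magnitude

  all_years <- cfg$years

  # outcome years preceding the first score wave (e.g. sports in 2001)
  # initialize their chains before the wave loop needs them as lags
  for (o in OUTCOMES) {
    early <- yrs_by_outcome[[o]][yrs_by_outcome[[o]] < waves[1]]
    for (yr in early) {
      j <- match(yr, yrs_by_outcome[[o]])
      xb <- cfg$outcome_intercepts[[o]] +
        linear_index(cfg$outcome_coefficients[[o]], covs)
      p <- plogis(xb + cfg$state_dependence[[o]] *
                    cfg$baseline_prevalence[[o]])
      y_obs[[o]][, j] <- as.integer(runif(n) < p)
    }
  }
  for (w in seq_len(W)) {
    yr <- waves[w]
    for (d in DOMAINS) {
      rho <- cfg$latent_persistence[[d]]
      if (w == 1L) {
        a <- rnorm(n, 0, s_a)
      } else {
        innov <- rnorm(n, 0, s_a * sqrt(1 - rho^2))
        lagged <- lagged_behaviors(yr)
        hz <- plogis(cfg$drop_hazard_intercept[[d]] +
                       linear_index(conf_w, covs, lagged))
        ev <- runif(n) < hz
        mag <- runif(n, dmag[1], dmag[2])
        a <- rho * (latent[[d]][, w - 1L] - mu[[d]]) + innov - ev * mag
        drop_event[[d]][, w] <- ev
      }
      latent[[d]][, w] <- mu[[d]] + a
      scores[[d]][, w] <- clip(
        50 + scale_score * latent[[d]][, w] +
          rnorm(n, 0, cfg$score_noise_sd), 0, 100)
    }

    # treatment flags for outcomes whose reference wave is this one
    for (o in OUTCOMES) {
      if (REFERENCE_YEARS[[o]] == yr && w >= 2L) {
        treat[[o]] <- lapply(stats::setNames(DOMAINS, DOMAINS), function(d) {
          s_prev <- scores[[d]][, w - 1L]
          s_curr <- scores[[d]][, w]
          as.integer(s_prev > 0 &
                       (s_curr - s_prev) / s_prev < -TREATMENT_THRESHOLD)
        })
      }
    }

    # outcomes observed at this wave year and the following odd year
    next_odd <- yr + 1L
    for (o in OUTCOMES) {
      if (yr %in% yrs_by_outcome[[o]]) sim_outcome_year(o, yr)
      if (next_odd %in% yrs_by_outcome[[o]]) sim_outcome_year(o, next_odd)
    }
  }
  truth <- if (length(truth_rows)) {
    data.table::rbindlist(truth_rows)
  } else {
    data.table::data.table(id = integer(), outcome = character(),
                           domain = character(), lag = integer(),
                           y1 = integer(), y0 = integer(),
                           treated = integer())
  }

  # --- attrition -------------------------------------------------------
  am <- cfg$attrition_model
  dropout_year <- rep(Inf, n)
  alive <- rep(TRUE, n)
  any_drop <- drop_event$physical | drop_event$mental
  for (yr in all_years[-1]) {
    recent_wave <- waves[waves <= yr & waves >= yr - 1L]
    recent <- if (length(recent_wave)) {
      any_drop[, match(max(recent_wave), waves)]
    } else {
      rep(FALSE, n)
    }
    smoke_lag <- {
      ys <- yrs_by_outcome$smoke[yrs_by_outcome$smoke < yr]
      if (length(ys)) y_obs$smoke[, as.character(max(ys))]
      else rep(cfg$baseline_prevalence[["smoke"]], n)
    }
    hz <- plogis(am$baseline + am$shock * recent +
                   am$lagged_outcome * smoke_lag)
    leave <- alive & (runif(n) < hz)
    dropout_year[leave] <- yr
    alive <- alive & !leave
  }

  transient <- matrix(runif(n * length(all_years)) <
                        am$transient_nonresponse_prob,
                      n, length(all_years))

  # --- assemble long panel --------------------------------------------
  sah <- sah_dummies(latent, waves, all_years, covs)
  rows <- vector("list", length(all_years))
  for (yi in seq_along(all_years)) {
    yr <- all_years[yi]
    gone <- yr >= dropout_year
    miss <- gone | transient[, yi]
    wv <- match(yr, waves)
    dtb <- data.table::data.table(
      id = seq_len(n), year = yr, attrited = gone,
      mcs = if (!is.na(wv)) ifelse(miss, NA_real_, scores$mental[, wv])
            else NA_real_,
      pcs = if (!is.na(wv)) ifelse(miss, NA_real_, scores$physical[, wv])
            else NA_real_)
    for (o in OUTCOMES) {
      col <- paste0("y_", o)
      if (yr %in% yrs_by_outcome[[o]]) {
        v <- y_obs[[o]][, as.character(yr)]
        dtb[[col]] <- ifelse(miss, NA_integer_, v)
      } else {
        dtb[[col]] <- NA_integer_
      }
    }
    for (cv in c(CONTINUOUS_COVARIATES, names(STATIC_BINARIES))) {
      dtb[[cv]] <- covs[[cv]]
    }
    for (tv in TIME_VARYING_BINARIES) {
      dtb[[tv]] <- ifelse(miss, NA_integer_, sah[[tv]][, yi])
    }
    rows[[yi]] <- dtb
  }
  panel <- data.table::rbindlist(rows)
  data.table::setkeyv(panel, c("id", "year"))

  out <- list(panel = panel, truth = truth, config = cfg,
              seed = as.integer(seed))
  class(out) <- "shockdml_panel"
  out
}

# additive treatment effect (probability scale) for (outcome, domain, lag),
# possibly restricted to a subgroup
effect_delta <- function(cfg, covs, outcome_, domain_, lag_) {
  ep <- cfg$effect_profile
  rows <- ep[ep$outcome == outcome_ & ep$domain == domain_ & ep$lag == lag_, ]
  if (!nrow(rows)) return(0)
  out <- rep(0, nrow(covs))
  for (k in seq_len(nrow(rows))) {
    sg <- rows$subgroup[k]
    mask <- if (is.na(sg)) 1 else as.numeric(covs[[sg]] == 1)
    out <- out + rows$delta[k] * mask
  }
  out
}

# time-varying self-assessed-health and utilization dummies derived from
# the latent health path (the latest wave at or before each year)
sah_dummies <- function(latent, waves, all_years, covs) {
  n <- nrow(covs)
  res <- lapply(TIME_VARYING_BINARIES, function(x) {
    matrix(NA_integer_, n, length(all_years))
  })
  names(res) <- TIME_VARYING_BINARIES
  for (yi in seq_along(all_years)) {
    yr <- all_years[yi]
    wv <- waves[waves <= yr]
    if (!length(wv)) wv <- waves[1]
    w <- match(max(wv), waves)
    m <- (latent$physical[, w] + latent$mental[, w]) / 2
    res$sah_bad[, yi] <- as.integer(m < -0.8)
    res$sah_good[, yi] <- as.integer(m > 0.1)
    res$sah_satisfactory[, yi] <-
      as.integer(res$sah_bad[, yi] == 0L & res$sah_good[, yi] == 0L)
    res$hospital_stay[, yi] <- as.integer(
      runif(n) < plogis(-2.4 + 0.3 * covs$disabled +
                          0.01 * (covs$age - 45) - 0.35 * m))
    res$doctor_visits[, yi] <- as.integer(
      runif(n) < plogis(-0.3 - 0.4 * m + 0.01 * (covs$age - 45)))
  }
  res
}

# static covariate table (stylized emulation of a 40-variable survey set;
# marginal prevalences in STATIC_BINARIES, a few structural links)
r_covariates <- function(n, health_mu) {
  covs <- data.table::data.table(
    age = clip(round(rnorm(n, 45, 15)), 18, 90),
    bmi = clip(rnorm(n, 26, 4), 16, 45),
    education_years = clip(rnorm(n, 12, 2.7), 7, 18),
    household_size = clip(1 + rpois(n, 1.3), 1, 8)
  )
  pb <- STATIC_BINARIES
  simple <- c("german", "east", "female", "has_children", "unemployed",
              "vocational_training", "urban")
  for (nm in simple) covs[[nm]] <- as.integer(runif(n) < pb[[nm]])

  covs$married <- as.integer(runif(n) < plogis(0.32 + 0.05 * (covs$age - 45)))
  covs$single <- as.integer(covs$married == 0L &
                              runif(n) < plogis(0.8 - 0.06 * (covs$age - 45)))
  covs$retired <- as.integer(runif(n) < plogis(-1.0 + 0.3 * (covs$age - 60)))
  occ <- sample(c("blue", "white", "civil", "self", "none"), n, TRUE,
                prob = c(0.30, 0.44, 0.06, 0.08, 0.12))
  covs$blue_collar <- as.integer(occ == "blue")
  covs$white_collar <- as.integer(occ == "white")
  covs$civil_servant <- as.integer(occ == "civil")
  covs$self_employed <- as.integer(occ == "self")
  covs$disabled <- as.integer(runif(n) <
                                clip(0.04 + 0.0025 * (covs$age - 18), 0, 0.5))
  covs$university_degree <- as.integer(
    runif(n) < plogis(-1.15 + 0.55 * (covs$education_years - 12)))

  inc <- 0.25 * (covs$education_years - 12) / 2.7 + 0.3 * covs$white_collar +
    0.35 * covs$civil_servant + 0.2 * covs$self_employed -
    0.5 * covs$unemployed + rnorm(n)
  qs <- stats::quantile(inc, c(0.25, 0.5, 0.75))
  covs$income_q2 <- as.integer(inc > qs[1] & inc <= qs[2])
  covs$income_q3 <- as.integer(inc > qs[2] & inc <= qs[3])
  covs$income_q4 <- as.integer(inc > qs[3])

  sat_h <- 0.8 * health_mu + rnorm(n)
  covs$sat_health_med <- as.integer(sat_h > -0.71 & sat_h <= 0.40)
  covs$sat_health_high <- as.integer(sat_h > 0.40)
  for (dom in c("living", "income", "leisure", "life")) {
    nm_med <- paste0("sat_", dom, "_med")
    nm_high <- paste0("sat_", dom, "_high")
    z <- runif(n)
    p_high <- pb[[nm_high]]
    p_med <- pb[[nm_med]]
    covs[[nm_high]] <- as.integer(z < p_high)
    covs[[nm_med]] <- as.integer(z >= p_high & z < p_high + p_med)
  }
  covs
}

#' @export
print.shockdml_panel <- function(x, ...) {
  cat("<shockdml_panel>\n")
  cat(sprintf("  individuals : %d\n", x$config$n_individuals))
  cat(sprintf("  years       : %d-%d\n", min(x$config$years),
              max(x$config$years)))
  cat(sprintf("  panel rows  : %d\n", nrow(x$panel)))
  cat(sprintf("  truth cells : %d (outcome x domain x lag)\n",
              nrow(unique(x$truth[, c("outcome", "domain", "lag")]))))
  invisible(x)
}

#' Ground-truth average treatment effect from the generator
#'
#' Mean difference of the stored potential outcomes for one
#' (outcome, shock domain, lag) cell.
#'
#' @param truth the \code{truth} table of a \code{shockdml_panel} (or the
#'   panel object itself).
#' @param outcome one of "smoke", "diet", "sport".
#' @param domain "physical" or "mental".
#' @param lag years between the reference year and outcome measurement.
#' @return the oracle ATE (a number).
#' @export
oracle_ate <- function(truth, outcome, domain, lag) {
  if (inherits(truth, "shockdml_panel")) truth <- truth$truth
  o <- outcome; d <- domain; s <- as.integer(lag)
  cell <- truth[truth$outcome == o & truth$domain == d & truth$lag == s, ]
  if (!nrow(cell)) {
    abort_fmt("truth table has no cell (%s, %s, lag %d)", o, d, s)
  }
  mean(cell$y1 - cell$y0)
}

#' Calibrate outcome-model intercepts to target prevalences
#'
#' Adjusts the three outcome intercepts so that the simulated pre-shock
#' prevalence (share with Y = 1 at the outcome's reference year minus 2)
#' matches \code{config$baseline_prevalence}. Uses damped log-odds
#' updates on a fixed calibration seed, which converges in a few panel
#' simulations.
#'
#' @param config a \code{\link{generator_config}}.
#' @param n_calib individuals used per calibration simulation.
#' @param tol absolute tolerance on the prevalence (default half a
#'   percentage point).
#' @param max_iter maximum number of simulations.
#' @param seed calibration seed.
#' @return the configuration with updated \code{outcome_intercepts}.
#' @export
calibrate_intercepts <- function(config, n_calib = 20000, tol = 0.005,
                                 max_iter = 10, seed = 99L) {
  cfg <- config
  cfg$n_individuals <- as.integer(n_calib)
  target <- cfg$baseline_prevalence
  for (it in seq_len(max_iter)) {
    sim <- generate_panel(cfg, seed = seed)
    shares <- baseline_shares(sim)
    gap <- qlogis(unlist(target[OUTCOMES])) - qlogis(shares[OUTCOMES])
    if (any(!is.finite(gap))) {
      abort_fmt("calibration failed: degenerate simulated prevalence")
    }
    if (all(abs(shares[OUTCOMES] - unlist(target[OUTCOMES])) < tol)) {
      config$outcome_intercepts <- cfg$outcome_intercepts
      return(config)
    }
    cfg$outcome_intercepts[OUTCOMES] <-
      cfg$outcome_intercepts[OUTCOMES] + 0.9 * gap
  }
  abort_fmt(paste0("calibration did not converge within %d iterations; ",
                   "targets may be unattainable given the coefficients"),
            max_iter)
}

# share with Y = 1 at the reference year minus 2 (pre-shock), per outcome
baseline_shares <- function(sim) {
  vapply(OUTCOMES, function(o) {
    ys <- outcome_years(sim$config, o)
    yr <- max(ys[ys < REFERENCE_YEARS[[o]]])
    col <- paste0("y_", o)
    v <- sim$panel[sim$panel$year == yr, ][[col]]
    mean(v, na.rm = TRUE)
  }, numeric(1))
}
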