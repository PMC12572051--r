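# Generator configuration: the stated world the synthetic panels emulate.
#
# Scores mimic SF-12 component summaries (MCS mental, PCS physical):
# range 0-100, normalized to mean 50 / sd 10 in the norm population,
# observed biannually. Shock events are large latent-health drops whose
# hazard depends on covariates (confounded assignment); behavioral
# outcomes are state-dependent logistic draws with an additive treatment
# effect on the probability scale for individuals flagged as shocked in
# the reference window.

# reference years of the fixed-t design: smoking/sports shocks measured
# over (2002, 2004], diet over (2004, 2006]
REFERENCE_YEARS <- c(smoke = 2004L, diet = 2006L, sport = 2004L)

OUTCOMES <- c("smoke", "diet", "sport")
DOMAINS <- c("physical", "mental")

# continuous covariates are standardized with fixed constants so that
# configured weights have a stable meaning across runs
CONT_STANDARDIZATION <- list(
  age = c(center = 45, scale = 15),
  bmi = c(center = 26, scale = 4),
  education_years = c(center = 12, scale = 2.7),
  household_size = c(center = 2.3, scale = 1.2)
)

# 29 static binary dummies (name -> marginal prevalence); a handful are
# generated from structural links (age, education, income index, latent
# health) rather than independent coin flips -- see r_covariates().
STATIC_BINARIES <- c(
  german = 0.92, east = 0.21, female = 0.52, married = 0.58, single = 0.22,
  has_children = 0.38, unemployed = 0.06, retired = 0.22, blue_collar = 0.27,
  white_collar = 0.44, civil_servant = 0.06, self_employed = 0.08,
  disabled = 0.09, university_degree = 0.24, vocational_training = 0.55,
  urban = 0.70, income_q2 = 0.25, income_q3 = 0.25, income_q4 = 0.25,
  sat_health_med = 0.40, sat_health_high = 0.35, sat_living_med = 0.35,
  sat_living_high = 0.45, sat_income_med = 0.40, sat_income_high = 0.30,
  sat_leisure_med = 0.40, sat_leisure_high = 0.35, sat_life_med = 0.40,
  sat_life_high = 0.40
)

# 5 time-varying binary dummies (derived from the latent health path)
TIME_VARYING_BINARIES <- c(
  "sah_good", "sah_satisfactory", "sah_bad", "hospital_stay", "doctor_visits"
)

CONTINUOUS_COVARIATES <- c("age", "bmi", "education_years", "household_size")

# covariate columns carried in the panel (the two lagged scores join at
# sample-construction time, completing the 40-variable conditioning set)
panel_covariate_names <- function() {
  c(CONTINUOUS_COVARIATES, names(STATIC_BINARIES), TIME_VARYING_BINARIES)
}

#' Default treatment-effect profile
#'
#' True additive effects (probability scale) of a flagged shock in the
#' reference window on each behavior at each feasible lag. Defaults are
#' patterned on short-lived responses: a small positive effect of a
#' physical shock on not smoking and on healthy diet, a negative
#' short-term effect of a mental shock on not smoking, a persistent
#' negative effect of a physical shock on doing sports, and near-null
#' mental-shock effects on diet and sports.
#'
#' @return data.table with columns outcome, domain, lag, delta, subgroup
#'   (NA = applies to everyone; otherwise the name of a binary covariate
#'   restricting the effect to that subgroup).
#' @export
default_effect_profile <- function() {
  rb <- function(outcome, domain, lag, delta) {
    data.table::data.table(outcome = outcome, domain = domain,
                           lag = as.integer(lag), delta = delta,
                           subgroup = NA_character_)
  }
  out <- data.table::rbindlist(list(
    rb("smoke", "physical", c(0, 2), c(0.02, 0.01)),
    rb("smoke", "mental", c(0, 2), c(-0.02, -0.01)),
    rb("diet", "physical", c(0, 2), c(0.05, 0.01)),
    rb("sport", "physical", c(1, 3, 5, 7), c(-0.04, -0.03, -0.02, -0.01)),
    rb("sport", "mental", c(1, 3), c(-0.01, -0.01))
  ))
  out[]
}

#' Build a generator configuration
#'
#' Assembles and validates the full configuration of the synthetic panel
#' generator. Defaults encode the stated world the generator emulates:
#' biannual score waves over 2001-2019, norm-population scores with mean
#' 50 and SD 10, shock prevalence in the 5-8% band with mental shocks
#' roughly 2pp more frequent than physical ones, baseline outcome
#' prevalences 0.70 (not smoking), 0.51 (healthy diet), 0.26 (doing
#' sports), confounded shock assignment, and absorbing-plus-transient
#' panel attrition.
#'
#' @param n_individuals number of individuals.
#' @param years calendar years covered by the panel (strictly increasing).
#' @param score_wave_parity "even" or "odd": parity of years carrying
#'   MCS/PCS measurements.
#' @param latent_persistence named vector, AR(1) coefficient per domain
#'   (per score wave, i.e. per two years), each in \[0, 1).
#' @param latent_heterogeneity_sd SD of the permanent individual health
#'   component (latent total variance is normalized to 1 at baseline).
#' @param score_noise_sd measurement noise SD on the 0-100 score scale.
#' @param drop_hazard_intercept named log-odds intercepts of the
#'   latent-drop hazard per domain. Defaults are calibrated so flagged
#'   shock shares land in the 5-8% band with mental = physical + ~2pp.
#' @param drop_magnitude range (latent SD units) of the health drop.
#' @param confounding_weights named vector linking covariates (and lagged
#'   outcomes, names \code{y_*_lag}) to the drop hazard.
#' @param effect_profile data.table as from
#'   \code{\link{default_effect_profile}}; absolute deltas must be < 1.
#' @param baseline_prevalence named target pre-shock outcome shares.
#' @param outcome_intercepts named log-odds intercepts of the outcome
#'   models. Defaults are pre-calibrated to \code{baseline_prevalence};
#'   re-derive with \code{\link{calibrate_intercepts}} after changing
#'   coefficients.
#' @param state_dependence named log-odds coefficients on the outcome two
#'   years earlier.
#' @param outcome_coefficients list (per outcome) of named covariate
#'   coefficients on the outcome log-odds.
#' @param attrition_model list with \code{baseline} (annual log-odds of
#'   absorbing dropout), \code{shock} (coefficient on a recent true
#'   health-drop event), \code{lagged_outcome} (coefficient on lagged
#'   not-smoking), and \code{transient_nonresponse_prob}.
#' @param seed default seed used when \code{generate_panel} is called
#'   without one.
#' @return an object of class \code{shockdml_config}.
#' @export
generator_config <- function(n_individuals = 5000,
                             years = 2001:2019,
                             score_wave_parity = c("even", "odd"),
                             latent_persistence = c(physical = 0.75,
                                                    mental = 0.70),
                             latent_heterogeneity_sd = sqrt(0.3),
                             score_noise_sd = 2,
                             drop_hazard_intercept = c(physical = -3.12,
                                                       mental = -2.67),
                             drop_magnitude = c(1.5, 3.5),
                             confounding_weights = default_confounding_weights(),
                             effect_profile = default_effect_profile(),
                             baseline_prevalence = c(smoke = 0.70,
                                                     diet = 0.51,
                                                     sport = 0.26),
                             outcome_intercepts = c(smoke = -0.973,
                                                    diet = -1.198,
                                                    sport = -1.773),
                             state_dependence = c(smoke = 2.6, diet = 1.8,
                                                  sport = 2.0),
                             outcome_coefficients = default_outcome_coefficients(),
                             attrition_model = list(
                               baseline = qlogis(0.075),
                               shock = 0.4,
                               lagged_outcome = -0.25,
                               transient_nonresponse_prob = 0.03),
                             seed = 1L) {
  score_wave_parity <- match.arg(score_wave_parity)
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    years = as.integer(years),
    score_wave_parity = score_wave_parity,
    latent_persistence = latent_persistence,
    latent_heterogeneity_sd = latent_heterogeneity_sd,
    score_noise_sd = score_noise_sd,
    drop_hazard_intercept = drop_hazard_intercept,
    drop_magnitude = drop_magnitude,
    confounding_weights = confounding_weights,
    effect_profile = data.table::as.data.table(effect_profile),
    baseline_prevalence = baseline_prevalence,
    outcome_intercepts = outcome_intercepts,
    state_dependence = state_dependence,
    outcome_coefficients = outcome_coefficients,
    attrition_model = attrition_model,
    seed = as.integer(seed)
  )
  class(cfg) <- "shockdml_config"
  validate_config(cfg)
  cfg
}

#' @export
print.shockdml_config <- function(x, ...) {
  cat("<shockdml_config>\n")
  cat(sprintf("  individuals : %d\n", x$n_individuals))
  cat(sprintf("  years       : %d-%d (%s score waves)\n", min(x$years),
              max(x$years), x$score_wave_parity))
  cat(sprintf("  prevalences : smoke %.2f, diet %.2f, sport %.2f\n",
              x$baseline_prevalence[["smoke"]],
              x$baseline_prevalence[["diet"]],
              x$baseline_prevalence[["sport"]]))
  cat(sprintf("  effect rows : %d\n", nrow(x$effect_profile)))
  invisible(x)
}

validate_config <- function(cfg) {
  if (cfg$n_individuals <= 0) abort_fmt("n_individuals must be positive")
  if (any(diff(cfg$years) <= 0)) abort_fmt("years must be strictly increasing")
  if (length(score_wave_years(cfg)) < 2) {
    abort_fmt("years must contain at least two score waves")
  }
  for (d in DOMAINS) {
    rho <- cfg$latent_persistence[[d]]
    if (is.null(rho) || rho < 0 || rho >= 1) {
      abort_fmt("latent_persistence[%s] must be in [0, 1)", d)
    }
  }
  if (cfg$score_noise_sd <= 0) abort_fmt("score_noise_sd must be > 0")
  if (cfg$latent_heterogeneity_sd <= 0 || cfg$latent_heterogeneity_sd >= 1) {
    abort_fmt("latent_heterogeneity_sd must be in (0, 1)")
  }
  if (cfg$score_noise_sd >= 10) {
    abort_fmt("score_noise_sd must be < 10 (total score SD is fixed at 10)")
  }
  prev <- cfg$baseline_prevalence
  if (any(prev <= 0) || any(prev >= 1)) {
    abort_fmt("baseline prevalences must lie in (0, 1)")
  }
  ep <- cfg$effect_profile
  need <- c("outcome", "domain", "lag", "delta")
  if (!all(need %in% names(ep))) {
    abort_fmt("effect_profile must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(ep) && any(abs(ep$delta) >= 1)) {
    abort_fmt("effect_profile deltas must satisfy |delta| < 1")
  }
  if (nrow(ep) && any(!ep$outcome %in% OUTCOMES)) {
    abort_fmt("unknown outcome in effect_profile")
  }
  if (nrow(ep) && any(!ep$domain %in% DOMAINS)) {
    abort_fmt("unknown domain in effect_profile")
  }
  # reject profiles that would push the bulk of outcome probabilities out
  # of (0,1): the target prevalence plus the effect must stay inside
  for (k in seq_len(nrow(ep))) {
    p <- prev[[ep$outcome[k]]] + ep$delta[k]
    if (p <= 0 || p >= 1) {
      abort_fmt("effect_profile row %d pushes prevalence of %s to %.2f",
                k, ep$outcome[k], p)
    }
  }
  am <- cfg$attrition_model
  if (am$transient_nonresponse_prob < 0 || am$transient_nonresponse_prob >= 1) {
    abort_fmt("transient_nonresponse_prob must be in [0, 1)")
  }
  invisible(cfg)
}

# calendar years carrying MCS/PCS
score_wave_years <- function(cfg) {
  par <- if (cfg$score_wave_parity == "even") 0L else 1L
  cfg$years[cfg$years %% 2L == par]
}

# years at which an outcome is observed (biannual masks)
outcome_years <- function(cfg, outcome) {
  switch(outcome,
    smoke = cfg$years[cfg$years %% 2L == 0L & cfg$years >= 2002L],
    diet = cfg$years[cfg$years %% 2L == 0L & cfg$years >= 2004L &
                       cfg$years <= 2014L],
    sport = cfg$years[cfg$years %% 2L == 1L],
    abort_fmt("unknown outcome '%s'", outcome))
}

#' Default confounding weights of the drop hazard
#'
#' Log-odds weights linking pre-determined characteristics to the hazard
#' of a latent health drop. Continuous covariates enter standardized
#' (fixed centers/scales); \code{y_*_lag} names refer to the behavior
#' observed at the previous wave, so that shock-prone individuals have
#' systematically worse pre-shock habits (smoking, little sport) --
#' the pattern motivating conditioning on pre-shock behavior.
#'
#' @return named numeric vector.
#' @export
default_confounding_weights <- function() {
  c(age = 0.45, bmi = 0.20, education_years = -0.25,
    unemployed = 0.35, disabled = 0.55, east = 0.10, retired = 0.15,
    sat_health_high = -0.30, income_q4 = -0.20,
    y_smoke_lag = -0.30, y_diet_lag = 0.10, y_sport_lag = -0.35)
}

#' Default covariate effects on the outcome log-odds
#' @return named list with one coefficient vector per outcome.
#' @export
default_outcome_coefficients <- function() {
  list(
    smoke = c(education_years = 0.25, age = 0.15, female = 0.15,
              unemployed = -0.45, blue_collar = -0.30,
              university_degree = 0.20, east = -0.10, sat_life_high = 0.10),
    diet = c(female = 0.55, age = 0.30, education_years = 0.20,
             bmi = -0.15, sat_health_high = 0.15),
    sport = c(age = -0.40, education_years = 0.30, university_degree = 0.30,
              blue_collar = -0.25, disabled = -0.50, urban = 0.10)
  )
}

# linear index of named coefficients over a covariate table; continuous
# covariates standardized with the fixed constants, binaries used raw,
# y_*_lag resolved against `lagged` (named list of 0/1 vectors)
linear_index <- function(weights, covs, lagged = NULL) {
  out <- rep(0, nrow(covs))
  for (nm in names(weights)) {
    w <- weights[[nm]]
    if (startsWith(nm, "y_") && endsWith(nm, "_lag")) {
      v <- lagged[[nm]]
      if (is.null(v)) next  # lag not yet defined (first wave)
      out <- out + w * v
    } else if (nm %in% names(CONT_STANDARDIZATION)) {
      st <- CONT_STANDARDIZATION[[nm]]
      out <- out + w * (covs[[nm]] - st[["center"]]) / st[["scale"]]
    } else if (nm %in% names(covs)) {
      out <- out + w * covs[[nm]]
    } else {
      abort_fmt("unknown covariate '%s' in weight vector", nm)
    }
  }
  out
}
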