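# Shared fixtures: panels are expensive, so the default-config panel is
# generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# default-config synthetic panel, memoized by (n, seed)
fixture_panel <- function(n = 4000, seed = 7, config = NULL) {
  key <- paste0("panel_", n, "_", seed, "_", is.null(config))
  if (is.null(.fixture_env[[key]])) {
    cfg <- config %||% generator_config(n_individuals = n)
    .fixture_env[[key]] <- generate_panel(cfg, seed = seed)
  }
  .fixture_env[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast learner specs for tests
quick_rf <- function() learner_spec(n_trees = 30, tune = FALSE,
                                    fixed_depth = 6)
quick_lasso <- function() learner_spec(kind = "lasso")

# generator config with no behavior->hazard feedback (no differential
# pre-trends; used for placebo-null and related properties)
static_confounding_config <- function(n, ...) {
  cw <- default_confounding_weights()
  cw <- cw[!grepl("^y_", names(cw))]
  generator_config(n_individuals = n, confounding_weights = cw, ...)
}

# hand-rolled long panel for toy shock/sample tests: scores specified per
# (id, year); all covariates constant; outcomes optionally supplied
toy_panel <- function(scores, outcomes = NULL) {
  # scores: data.frame(id, year, mcs, pcs)
  dt <- data.table::as.data.table(scores)
  if (!"mcs" %in% names(dt)) dt$mcs <- 50
  if (!"pcs" %in% names(dt)) dt$pcs <- 50
  dt$attrited <- FALSE
  for (o in c("smoke", "diet", "sport")) {
    col <- paste0("y_", o)
    dt[[col]] <- if (!is.null(outcomes) && col %in% names(outcomes)) {
      outcomes[[col]][match(paste(dt$id, dt$year),
                            paste(outcomes$id, outcomes$year))]
    } else {
      NA_integer_
    }
  }
  for (cv in c("age", "bmi", "education_years", "household_size")) {
    dt[[cv]] <- c(age = 45, bmi = 26, education_years = 12,
                  household_size = 2)[[cv]]
  }
  statics <- shockdml:::STATIC_BINARIES
  for (nm in names(statics)) dt[[nm]] <- 0L
  for (nm in shockdml:::TIME_VARYING_BINARIES) dt[[nm]] <- 0L
  dt
}

# small randomized sample for estimator identities: known propensity,
# binary outcome, a couple of covariates
toy_sample <- function(n = 40, seed = 1, p_treat = 0.5) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    dt <- data.table::data.table(
      id = seq_len(n),
      treated = rbinom(n, 1, p_treat),
      x1 = rnorm(n),
      x2 = rnorm(n))
    dt$y <- rbinom(n, 1, plogis(0.3 * dt$x1 + 0.4 * dt$treated))
    data.table::setcolorder(dt, c("id", "y", "treated"))
    tm <- timing_spec("smoke", "physical", 0)
    shockdml:::as_sample(dt, tm, 0.25)
  })
}

withr_like_tempdir <- function() {
  d <- tempfile("shockdml_test_")
  dir.create(d)
  d
}

# independent brute-force evaluation of the AIPW expression, written as a
# plain loop so it shares no code with aipw_summands()
brute_force_aipw <- function(t, y, pi, g1, g0) {
  n <- length(y)
  total <- 0
  for (i in seq_len(n)) {
    term1 <- t[i] * y[i] / pi[i] - (t[i] - pi[i]) / pi[i] * g1[i]
    term0 <- (1 - t[i]) * y[i] / (1 - pi[i]) +
      (t[i] - pi[i]) / (1 - pi[i]) * g0[i]
    total <- total + (term1 - term0)
  }
  total / n
}
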