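test_that("configuration validation rejects malformed inputs", {
  expect_error(generator_config(n_individuals = 0), "positive")
  expect_error(generator_config(years = c(2004, 2002)), "increasing")
  expect_error(generator_config(score_noise_sd = -1), "score_noise_sd")
  expect_error(generator_config(
    latent_persistence = c(physical = 1.0, mental = 0.5)), "persistence")
  expect_error(generator_config(
    baseline_prevalence = c(smoke = 1.2, diet = 0.5, sport = 0.3)),
    "prevalence")
  bad <- default_effect_profile()
  bad$delta[1] <- 1.5
  expect_error(generator_config(effect_profile = bad), "delta")
  # profile pushing the target prevalence out of (0, 1) is rejected
  push <- data.table::data.table(outcome = "smoke", domain = "physical",
                                 lag = 0L, delta = 0.4,
                                 subgroup = NA_character_)
  expect_error(generator_config(effect_profile = push), "prevalence")
})

test_that("panels are deterministic given the seed", {
  cfg <- generator_config(n_individuals = 300)
  a <- generate_panel(cfg, seed = 11)
  b <- generate_panel(cfg, seed = 11)
  c <- generate_panel(cfg, seed = 12)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$panel, c$panel))
})

test_that("scores respect range, parity and attrition structure", {
  sim <- fixture_panel()
  p <- sim$panel
  expect_true(all(p$mcs >= 0 & p$mcs <= 100, na.rm = TRUE))
  expect_true(all(p$pcs >= 0 & p$pcs <= 100, na.rm = TRUE))
  # scores only on even years
  odd <- p[p$year %% 2L == 1L, ]
  expect_true(all(is.na(odd$mcs)) && all(is.na(odd$pcs)))
  even <- p[p$year %% 2L == 0L & !p$attrited, ]
  expect_gt(mean(!is.na(even$mcs)), 0.9)  # only transient non-response
  # absorbing attrition: everything missing afterwards
  att <- p[p$attrited == TRUE, ]
  expect_true(all(is.na(att$mcs)) && all(is.na(att$y_smoke)))
  att_flags <- p[, list(mono = !is.unsorted(attrited)), by = id]
  expect_true(all(att_flags$mono))
})

test_that("panel carries the 40-covariate conditioning set", {
  sim <- fixture_panel()
  smp <- build_sample(sim, timing_spec("smoke", "physical", 0))
  covs <- sample_covariates(smp)
  # 40 covariates (incl. both lagged scores) plus the lagged outcome
  expect_length(covs, 41L)
  expect_true(all(c("mcs_tm2", "pcs_tm2", "y_pre", "age", "female") %in% covs))
  cont <- c("age", "bmi", "education_years", "household_size",
            "mcs_tm2", "pcs_tm2")
  expect_length(setdiff(covs, c(cont, "y_pre")), 34L)  # binary dummies
  for (cv in setdiff(covs, cont)) {
    expect_true(all(smp[[cv]] %in% c(0L, 1L)), label = cv)
  }
})

test_that("oracle ATE equals the injected effect by construction", {
  # null profile with common random numbers -> exactly zero everywhere
  cfg <- generator_config(n_individuals = 2000)
  cfg$effect_profile <- cfg$effect_profile[0]
  simn <- generate_panel(cfg, seed = 5)
  expect_true(all(simn$truth$y1 == simn$truth$y0))
  expect_identical(oracle_ate(simn, "smoke", "physical", 0), 0)

  # injected +0.02 on not smoking recovers up to rare probability clipping
  cfg2 <- generator_config(n_individuals = 10000, effect_profile =
    data.table::data.table(outcome = "smoke", domain = "physical",
                           lag = 0L, delta = 0.02,
                           subgroup = NA_character_))
  sim2 <- generate_panel(cfg2, seed = 5)
  expect_equal(oracle_ate(sim2, "smoke", "physical", 0), 0.02,
               tolerance = 0.15)
  # untouched cells stay exactly null
  expect_identical(oracle_ate(sim2, "smoke", "mental", 0), 0)

  # hand-built truth table
  tt <- data.table::data.table(
    id = 1:4, outcome = "diet", domain = "physical", lag = 0L,
    y1 = c(1L, 1L, 0L, 1L), y0 = c(0L, 1L, 0L, 0L), treated = 0L)
  expect_identical(oracle_ate(tt, "diet", "physical", 0), 0.5)
  expect_error(oracle_ate(tt, "diet", "mental", 0), "no cell")
})

test_that("observed outcomes are consistent with potential outcomes", {
  sim <- fixture_panel()
  tr <- sim$truth[sim$truth$outcome == "diet" &
                    sim$truth$domain == "physical" &
                    sim$truth$lag == 0L, ]
  y06 <- sim$panel[sim$panel$year == 2006, c("id", "y_diet"), with = FALSE]
  m <- merge(tr, y06, by = "id")
  m <- m[!is.na(m$y_diet), ]
  expect_true(all(ifelse(m$treated == 1L, m$y1, m$y0) == m$y_diet))
})

test_that("shock prevalence sits in the stated band", {
  sim <- fixture_panel(n = 20000, seed = 3)
  shares <- sapply(c("physical", "mental"), function(d) {
    fl <- flag_panel_shocks(sim, d)
    mean(fl$shock[fl$year == 2004])
  })
  expect_gt(shares[["physical"]], 0.04)
  expect_lt(shares[["physical"]], 0.09)
  expect_gt(shares[["mental"]], 0.04)
  expect_lt(shares[["mental"]], 0.09)
  # mental more frequent by roughly two percentage points
  expect_lt(abs(shares[["mental"]] - shares[["physical"]] - 0.02), 0.015)
})

test_that("stronger confounding weight raises the covariate's ASMD", {
  cfg_lo <- static_confounding_config(20000)
  cfg_hi <- static_confounding_config(20000)
  cfg_hi$confounding_weights[["age"]] <-
    cfg_hi$confounding_weights[["age"]] + 0.8
  tm <- timing_spec("smoke", "physical", 0)
  a_lo <- asmd(build_sample(generate_panel(cfg_lo, seed = 21), tm))
  a_hi <- asmd(build_sample(generate_panel(cfg_hi, seed = 21), tm))
  expect_gt(a_hi$asmd[a_hi$covariate == "age"],
            a_lo$asmd[a_lo$covariate == "age"])
})

test_that("calibrate_intercepts hits the target prevalences", {
  # symmetry: no covariates, no state dependence, target one half
  cfg <- generator_config(
    n_individuals = 2000,
    baseline_prevalence = c(smoke = 0.5, diet = 0.5, sport = 0.5),
    outcome_intercepts = c(smoke = 0.7, diet = -0.9, sport = 0.4),
    state_dependence = c(smoke = 0, diet = 0, sport = 0),
    outcome_coefficients = list(smoke = numeric(), diet = numeric(),
                                sport = numeric()))
  cal <- calibrate_intercepts(cfg, n_calib = 8000, tol = 0.01, seed = 4)
  expect_true(all(abs(cal$outcome_intercepts) < 0.12))

  # shipped defaults reproduce the paper-style baseline shares
  sim <- fixture_panel(n = 20000, seed = 3)
  shares <- shockdml:::baseline_shares(sim)
  target <- c(smoke = 0.70, diet = 0.51, sport = 0.26)
  expect_true(all(abs(shares[names(target)] - target) < 0.015))
})
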