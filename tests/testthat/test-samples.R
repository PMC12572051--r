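test_that("lag grids follow the availability masks", {
  expect_identical(lag_grid("smoke"), seq(0L, 14L, 2L))
  expect_identical(lag_grid("diet"), seq(0L, 8L, 2L))   # diet ends in 2014
  expect_identical(lag_grid("sport"), seq(1L, 15L, 2L)) # odd lags only
  expect_error(lag_grid("tv"), "unknown outcome")
  expect_error(timing_spec("smoke", "physical", 1), "grid")
  expect_error(timing_spec("sport", "physical", 2), "grid")
})

test_that("build_sample assembles (Y, T, X) and drops incomplete rows", {
  # 3 ids: id 3 loses the outcome at t+s, id 4 has no 2004 score
  score_df <- expand.grid(id = 1:4, year = c(2002, 2004, 2006))
  score_df$pcs <- 50
  score_df$pcs[score_df$id == 1 & score_df$year == 2004] <- 30  # shock
  score_df$pcs[score_df$id == 4 & score_df$year == 2004] <- NA
  score_df$mcs <- 50
  outc <- expand.grid(id = 1:4, year = c(2002, 2004, 2006))
  outc$y_smoke <- 1L
  outc$y_smoke[outc$id == 3 & outc$year == 2006] <- NA
  tp <- toy_panel(score_df, outc)

  smp <- build_sample(tp, timing_spec("smoke", "physical", 2))
  expect_identical(sort(smp$id), c(1L, 2L))
  expect_identical(smp$treated[smp$id == 1L], 1L)
  expect_identical(smp$treated[smp$id == 2L], 0L)
  expect_true(all(c("y_pre", "mcs_tm2", "pcs_tm2") %in% names(smp)))

  # at lag 0 the attrited id 3 is present
  smp0 <- build_sample(tp, timing_spec("smoke", "physical", 0))
  expect_identical(sort(smp0$id), c(1L, 2L, 3L))

  # no shocked individuals: sample builds, the estimator refuses
  tp_null <- toy_panel(score_df[score_df$id != 1 & score_df$id != 4, ],
                       outc)
  smp_null <- build_sample(tp_null, timing_spec("smoke", "physical", 0))
  expect_true(all(smp_null$treated == 0L))
  expect_error(ddml_ate(smp_null, quick_rf(), K = 2, R = 1), "treated")
})

test_that("pre-treatment purity: no covariate is measured at or after t", {
  sim <- fixture_panel()
  smp <- build_sample(sim, timing_spec("diet", "physical", 2))
  covs <- sample_covariates(smp)
  # time-stamped columns must all be t-2; the sample carries no year >= t
  stamped <- grep("_(\\d{4})$", covs, value = TRUE)
  expect_length(stamped, 0L)
  # the t-2 values in the sample equal the panel values at t-2
  p_tm2 <- sim$panel[sim$panel$year == 2004,
                     c("id", "mcs", "pcs", "sah_good"), with = FALSE]
  m <- merge(smp, p_tm2, by = "id")
  expect_identical(m$mcs_tm2, m$mcs)
  expect_identical(m$pcs_tm2, m$pcs)
  expect_identical(m$sah_good_tm2, m$sah_good)
})

test_that("sample sizes shrink with the lag on the default panel", {
  sim <- fixture_panel()
  ns <- vapply(lag_grid("smoke"), function(s) {
    nrow(build_sample(sim, timing_spec("smoke", "physical", s)))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
  # treated share roughly constant across lags (non-selective attrition
  # dominates): within one percentage point of the t+0 share
  shares <- vapply(lag_grid("smoke"), function(s) {
    smp <- build_sample(sim, timing_spec("smoke", "physical", s))
    mean(smp$treated)
  }, numeric(1))
  expect_lt(max(shares) - min(shares), 0.02)
})

test_that("placebo samples use pre-window outcomes and t-2 conditioning", {
  sim <- fixture_panel()
  smps <- build_placebo_samples(sim, "smoke", "physical",
                                shift_reference = 2012L)
  lags <- as.integer(names(smps))
  expect_true(all(lags <= -4L))   # own conditioning year is t-2
  expect_true(min(lags) == -10L)  # reaches t-10
  s <- smps[["-6"]]
  expect_true(all(c("y_lag_smoke", "y_lag_diet", "y_lag_sport",
                    "mcs_tm2") %in% names(s)))
  # outcome at 2006 equals the panel's smoke value then
  p06 <- sim$panel[sim$panel$year == 2006, c("id", "y_smoke"), with = FALSE]
  m <- merge(s, p06, by = "id")
  expect_identical(m$y, m$y_smoke)
  # sports placebo lags are odd and stop before the sports conditioning lag
  smps_sport <- build_placebo_samples(sim, "sport", "physical")
  expect_true(all(as.integer(names(smps_sport)) <= -5L))
  expect_error(build_placebo_samples(sim, "smoke", "physical",
                                     shift_reference = 2004L),
               "insufficient")
})

test_that("attach_history appends complete pre-shock wave blocks", {
  sim <- fixture_panel()
  tm <- timing_spec("smoke", "physical", 0, reference_year = 2012L,
                    covariate_mode = "full_history")
  base <- build_sample(sim, tm)
  hist <- suppressMessages(attach_history(base, sim))
  # waves 2002..2008 add scores (2), sah/utilization dummies (5) and the
  # smoking lag (1) each
  waves <- c(2002, 2004, 2006, 2008)
  expect_identical(length(sample_covariates(hist)),
                   length(sample_covariates(base)) + length(waves) * 8L)
  expect_true(all(paste0("mcs_", waves) %in% names(hist)))
  expect_true(all(paste0("y_pre_", waves) %in% names(hist)))
  # rows lacking full history were dropped but treated rows remain
  expect_lte(nrow(hist), nrow(base))
  expect_gt(sum(hist$treated), 0)
  # estimator runs on the collinearity-prone wide block
  est <- ddml_ate(hist, quick_lasso(), K = 3, R = 1, seed = 2)
  expect_true(is.finite(est$estimate))
})

test_that("attrition outcome flags missing behaviors without dropping rows", {
  score_df <- expand.grid(id = 1:2, year = c(2002, 2004, 2006, 2008))
  score_df$pcs <- ifelse(score_df$id == 1 & score_df$year == 2004, 30, 50)
  score_df$mcs <- 50
  outc <- expand.grid(id = 1:2, year = c(2002, 2004, 2006, 2008))
  outc$y_smoke <- 1L
  outc$y_smoke[outc$id == 2 & outc$year >= 2006] <- NA  # drops out after t+2
  tp <- toy_panel(score_df, outc)
  for (s in c(0L, 2L, 4L)) {
    smp <- attrition_outcome(tp, timing_spec("smoke", "physical", s))
    expect_identical(nrow(smp), 2L)
    expect_identical(smp$y[smp$id == 1L], 0L)
    expect_identical(smp$y[smp$id == 2L], if (s >= 2L) 1L else 0L)
  }
})
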