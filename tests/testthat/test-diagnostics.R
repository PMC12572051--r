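test_that("asmd matches hand arithmetic and flags imbalance", {
  n <- 200
  dt <- data.table::data.table(
    id = seq_len(n), y = rbinom(n, 1, 0.5),
    treated = rep(c(1L, 0L), each = n / 2),
    b = c(rep(c(1L, 0L), each = n / 4), rep(c(1L, 0L), c(30, 70))),
    cont = rnorm(n))
  # binary covariate p1 = 0.5, p0 = 0.3 -> 0.2 / sqrt((0.25 + 0.21)/2)
  smp <- shockdml:::as_sample(dt, timing_spec("smoke", "physical", 0), 0.25)
  rep_ <- asmd(smp)
  expect_equal(rep_$asmd[rep_$covariate == "b"],
               0.2 / sqrt((0.25 + 0.21) / 2), tolerance = 1e-12)
  expect_true(rep_$imbalanced[rep_$covariate == "b"])
})

test_that("asmd is zero on cloned arms, symmetric, scale-invariant", {
  base <- data.table::data.table(id = 1:50, y = rbinom(50, 1, 0.5),
                                 b = rbinom(50, 1, 0.4), cont = rnorm(50))
  clone <- rbind(data.table::data.table(base, treated = 1L),
                 data.table::data.table(base, treated = 0L))
  clone$id <- seq_len(nrow(clone))
  smp <- shockdml:::as_sample(clone, timing_spec("smoke", "physical", 0),
                              0.25)
  expect_true(all(asmd(smp)$asmd == 0))

  set.seed(2)
  dt <- data.table::data.table(
    id = 1:120, y = rbinom(120, 1, 0.5), treated = rbinom(120, 1, 0.45),
    b = rbinom(120, 1, 0.3), cont = rnorm(120, 5, 2))
  smp1 <- shockdml:::as_sample(data.table::copy(dt),
                               timing_spec("smoke", "physical", 0), 0.25)
  a1 <- asmd(smp1)
  # swap arm labels
  dt2 <- data.table::copy(dt)[, treated := 1L - treated]
  smp2 <- shockdml:::as_sample(dt2, timing_spec("smoke", "physical", 0),
                               0.25)
  expect_equal(a1$asmd, asmd(smp2)$asmd, tolerance = 1e-12)
  # affine rescale of the continuous covariate
  dt3 <- data.table::copy(dt)[, cont := 100 * cont - 7]
  smp3 <- shockdml:::as_sample(dt3, timing_spec("smoke", "physical", 0),
                               0.25)
  expect_equal(a1$asmd[a1$covariate == "cont"],
               asmd(smp3)$asmd[asmd(smp3)$covariate == "cont"],
               tolerance = 1e-10)
  # zero-variance covariate: equal means -> 0; unequal -> incomputable
  dt4 <- data.table::copy(dt)[, c("const", "sep") :=
                                list(1L, as.integer(treated == 1L))]
  smp4 <- shockdml:::as_sample(dt4, timing_spec("smoke", "physical", 0),
                               0.25)
  a4 <- asmd(smp4)
  expect_identical(a4$asmd[a4$covariate == "const"], 0)
  expect_true(a4$incomputable[a4$covariate == "sep"])
})

test_that("age confounding surfaces among the largest imbalances", {
  sim <- fixture_panel(n = 20000, seed = 3)
  rep_ <- asmd(build_sample(sim, timing_spec("smoke", "physical", 0)))
  expect_lte(match("age", rep_$covariate), 6L)
  expect_true(rep_$imbalanced[rep_$covariate == "age"])
})

test_that("the 2x2 chi-squared uses the closed form without correction", {
  # frozen against the independent oracle
  # chisq.test(matrix(c(10,10,30,10), 2, byrow = TRUE), correct = FALSE)
  ch <- shockdml:::chisq_2x2(10, 10, 30, 10)
  expect_equal(ch$statistic, 3.75, tolerance = 1e-12)
  expect_equal(ch$p_value, pchisq(3.75, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # closed form agrees with stats::chisq.test on random tables
  set.seed(12)
  for (i in 1:20) {
    cnt <- rpois(4, 25) + 1
    ref <- suppressWarnings(stats::chisq.test(
      matrix(cnt, 2, byrow = TRUE), correct = FALSE))
    ch2 <- shockdml:::chisq_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(ch2$statistic, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("pre-treatment outcome table mirrors the selection pattern", {
  sim <- fixture_panel(n = 20000, seed = 3)
  tab <- pretreatment_outcome_table(sim, outcomes = c("smoke", "sport"),
                                    domains = "physical")
  # shock-prone individuals have worse pre-shock habits by construction
  expect_lt(tab$share_pre_shock[tab$outcome == "smoke"],
            tab$share_pre_noshock[tab$outcome == "smoke"])
  expect_lt(tab$share_pre_shock[tab$outcome == "sport"],
            tab$share_pre_noshock[tab$outcome == "sport"])
  expect_true(all(tab$n_shock + tab$n_noshock == tab$n))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})

test_that("threshold sweep: treated counts nest, small cells are flagged", {
  sim <- fixture_panel()
  tm <- timing_spec("smoke", "physical", 0)
  # estimation suppressed via an impossible floor: counts only, fast
  curve <- threshold_sensitivity(sim, tm, quick_rf(),
                                 thresholds = seq(0.05, 0.40, 0.05),
                                 min_treated = .Machine$integer.max)
  expect_true(all(diff(curve$n_treated) <= 0))
  expect_true(all(curve$flagged))
  expect_true(all(is.na(curve$estimate)))

  # with a realistic floor the mid-grid is estimated
  curve2 <- threshold_sensitivity(sim, tm, quick_lasso(),
                                  thresholds = c(0.25, 0.39),
                                  R = 1L, seed = 4, min_treated = 30L)
  expect_false(curve2$flagged[curve2$threshold == 0.25])
  expect_true(is.finite(curve2$estimate[curve2$threshold == 0.25]))
})

test_that("attrition rates behave under absorbing and null regimes", {
  # no attrition at all
  cfg <- static_confounding_config(
    1500, attrition_model = list(baseline = -30, shock = 0,
                                 lagged_outcome = 0,
                                 transient_nonresponse_prob = 0))
  sim <- generate_panel(cfg, seed = 13)
  rates <- attrition_rates(sim, "smoke", "physical")
  expect_true(all(rates$attrition_rate == 0))

  # absorbing-only attrition: rates non-decreasing in lag per cell
  cfg2 <- static_confounding_config(
    4000, attrition_model = list(baseline = qlogis(0.075), shock = 0,
                                 lagged_outcome = 0,
                                 transient_nonresponse_prob = 0))
  sim2 <- generate_panel(cfg2, seed = 14)
  rates2 <- attrition_rates(sim2, "smoke", "physical")
  for (cell in split(rates2, rates2[, c("treated", "y_baseline")])) {
    expect_true(all(diff(cell$attrition_rate[order(cell$lag)]) >= 0))
  }
  # shock-independent attrition: treated vs control within 3 SE
  agg <- rates2[, list(rate = sum(n_cell * attrition_rate) / sum(n_cell),
                       n = sum(n_cell)), by = c("lag", "treated")]
  wide <- data.table::dcast(agg, lag ~ treated, value.var = c("rate", "n"))
  z <- abs(wide$rate_1 - wide$rate_0) /
    sqrt(wide$rate_0 * (1 - wide$rate_0) * (1 / wide$n_1 + 1 / wide$n_0))
  expect_lt(mean(z > 3), 0.2)
})

test_that("attrition-as-outcome estimates track the dropout regime", {
  # shock-independent attrition: DDML attrition 'effects' are null
  cfg0 <- static_confounding_config(
    4000, attrition_model = list(baseline = qlogis(0.075), shock = 0,
                                 lagged_outcome = 0,
                                 transient_nonresponse_prob = 0.03))
  sim0 <- generate_panel(cfg0, seed = 23)
  ests0 <- suppressWarnings(
    attrition_effect(sim0, "smoke", "physical", lags = c(4L, 10L),
                     spec = quick_lasso(), R = 1L, seed = 3))
  for (e in ests0) {
    expect_true(e$ci_lower <= 0 && 0 <= e$ci_upper)
  }

  # strongly shock-driven dropout: positive estimated attrition effect
  # (the hazard bump lasts two years after the event and the first year
  # removes people from the sample, so only a large coefficient shows)
  cfg1 <- static_confounding_config(
    6000, attrition_model = list(baseline = qlogis(0.06), shock = 2.5,
                                 lagged_outcome = 0,
                                 transient_nonresponse_prob = 0.03))
  sim1 <- generate_panel(cfg1, seed = 23)
  ests1 <- suppressWarnings(
    attrition_effect(sim1, "smoke", "physical", lags = 4L,
                     spec = quick_lasso(), R = 1L, seed = 3))
  expect_gt(ests1[["4"]]$estimate, 0)
  expect_gt(ests1[["4"]]$ci_lower, 0)
})
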