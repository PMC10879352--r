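test_that("patient sampling: determinism, extension stability, zero-CV limit", {
  a <- sample_patients(50, seed = 3)
  b <- sample_patients(50, seed = 3)
  expect_identical(a, b)
  # adding patients never perturbs existing ones
  big <- sample_patients(80, seed = 3)
  expect_equal(big[1:50, ], a[1:50, ], ignore_attr = TRUE)
  # all CVs zero: identical patients at the medians
  cv0 <- stats::setNames(rep(0, length(default_cv_table())),
                         names(default_cv_table()))
  p0 <- sample_patients(5, seed = 1, cv_table = cv0)
  expect_equal(unique(p0$k_inj), 0.0035)
  expect_equal(unique(p0$LVEDV), 125)
  expect_error(sample_patients(5, seed = 1, cv_table = c(k_inj = -0.1)),
               "invalid CV")
})

test_that("sampled dispersion matches the configured CV (law of large numbers)", {
  p <- sample_patients(10000, seed = 11)
  cv_hat <- stats::sd(p$k_inj) / mean(p$k_inj)
  expect_lt(abs(cv_hat / 0.0847 - 1), 0.05)
  # comorbidity rule is exactly the published cutoffs
  expect_identical(p$comorbid, p$MAP >= 115 | p$LVEDV >= 146)
  # screening: included iff baseline LVEF >= 50
  expect_identical(p$included, p$baseline_lvef >= 50)
})

test_that("cohort engine agrees with the R-level LVEF model on the E_drug path", {
  # one patient, trastuzumab regimen: feed the engine's own E_drug series
  # through the independent R implementation of the compensation model
  pat <- sample_patients(1, seed = 21)
  tr <- simulate_patient(pat[1, ], "TRZ", horizon_weeks = 20, dt = 0.5)
  qsp <- structure(list(SV0 = pat$SV0[1], LVEDV = pat$LVEDV[1],
                        gain = pat$gain[1], ceiling = pat$ceiling[1],
                        tau_comp = pat$tau_comp[1], comorbid = pat$comorbid[1],
                        r_access = pat$r_access[1]),
                   class = "cardio_qsp_params")
  ref <- simulate_lvef(qsp, data.frame(time_h = tr$time_h,
                                       e_drug = pmin(pmax(tr$E_drug, 1e-12), 1)))
  expect_equal(tr$LVEF, ref$LVEF, tolerance = 1e-6)
})

test_that("trials: determinism, zero dose, bounds, subgroup ordering", {
  spec0 <- trial_spec("DOX", n = 400, seed = 5, cum_dose = 0)
  t0 <- run_trial(spec0)
  expect_equal(t0$incidence$incidence_pct,
               rep(0, 3))
  spec <- trial_spec("DOX_then_TRZ", n = 400, seed = 5)
  t1 <- run_trial(spec)
  t2 <- run_trial(spec)
  expect_identical(t1$incidence, t2$incidence)
  expect_identical(t1$patients$dysfunction, t2$patients$dysfunction)
  inc <- t1$incidence
  expect_true(all(inc$incidence_pct >= 0 & inc$incidence_pct <= 100))
  ok <- !is.na(inc$ci_lo)
  expect_true(all(inc$ci_lo[ok] <= inc$incidence_pct[ok] + 1e-9))
  expect_true(all(inc$ci_hi[ok] >= inc$incidence_pct[ok] - 1e-9))
})

test_that("monotone harm: pointwise-lower E_drug cannot raise minimum LVEF", {
  pat <- sample_patients(1, seed = 9)
  qsp <- structure(list(SV0 = pat$SV0[1], LVEDV = pat$LVEDV[1],
                        gain = pat$gain[1], ceiling = pat$ceiling[1],
                        tau_comp = pat$tau_comp[1], comorbid = pat$comorbid[1],
                        r_access = 0.12),
                   class = "cardio_qsp_params")
  tt <- seq(0, 4000, 10)
  set.seed(1)
  for (i in 1:5) {
    e1 <- c(1, pmin(1, 0.7 + 0.3 * stats::runif(length(tt) - 1)))
    e2 <- e1 * c(1, stats::runif(length(tt) - 1, 0.8, 1))  # pointwise lower
    l1 <- simulate_lvef(qsp, data.frame(time_h = tt, e_drug = e1))
    l2 <- simulate_lvef(qsp, data.frame(time_h = tt, e_drug = e2))
    expect_lte(min(l2$LVEF), min(l1$LVEF) + 1e-9)
  }
})

test_that("scaled-down trials are consistent with larger cohorts", {
  small <- run_trial(trial_spec("DOX_then_TRZ", n = 1000, seed = 4))
  large <- run_trial(trial_spec("DOX_then_TRZ", n = 4000, seed = 4))
  s <- small$incidence[small$incidence$subgroup == "overall", ]
  l <- large$incidence[large$incidence$subgroup == "overall", ]
  expect_true(s$ci_lo <= l$ci_hi && l$ci_lo <= s$ci_hi)  # CI overlap
})

test_that("sensitivity analysis: linear synthetic response gives sensitivity 1", {
  # analytic check of the normalized-sensitivity formula on Incidence = c * p
  inc <- function(p) 0.04 * p
  p0 <- 2
  for (f in c(1 / 3, 0.5, 2, 3)) {
    s <- (inc(p0 * f) - inc(p0)) / inc(p0) / (f - 1)
    expect_equal(s, 1, tolerance = 1e-12)
  }
})

test_that("sensitivity analysis runs and flags zero baseline", {
  spec0 <- trial_spec("DOX", n = 150, seed = 2, cum_dose = 60)
  expect_warning(s <- sensitivity_analysis(spec0, parameters = "k_inj",
                                           folds = 3),
                 "baseline incidence is zero")
  expect_true(is.na(s$sensitivity[1]))
  expect_error(sensitivity_analysis(trial_spec("TRZ", n = 50, seed = 1),
                                    parameters = "nope"),
               "unknown parameter")
  expect_error(sensitivity_analysis(trial_spec("TRZ", n = 50, seed = 1),
                                    folds = 10), "folds")
})
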