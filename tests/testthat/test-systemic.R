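test_that("e_drug follows the accessibility power law", {
  expect_equal(e_drug(1, 1, 0.12), 1)
  expect_equal(e_drug(1, 1, 1), 1)
  expect_equal(e_drug(0.5, 1, 0.12), exp(0.12 * log(0.5)))
  expect_equal(round(e_drug(0.5, 1, 0.12), 3), 0.920)
  expect_equal(e_drug(0.6, 0.5, 1), 0.3)  # in-vitro limit: identity
  # attenuation: in-vivo exponent never harms more than the in-vitro effect
  x <- seq(0.01, 1, 0.01)
  expect_true(all(e_drug(x, 1, 0.12) >= e_drug(x, 1, 1)))
  expect_error(e_drug(0.5, 0.5, 0), "r_access")
})

test_that("heart profiles: linearity, superposition, zero dose", {
  reg1 <- regimen(data.frame(drug = "dox", dose = 60,
                             dose_unit = "mg_per_m2", time_week = 0,
                             infusion_h = 1))
  tg <- seq(0, 800, 2)
  p1 <- heart_interstitial_profiles(reg1, t_grid = tg)
  # doubling the dose doubles the profile pointwise
  reg2 <- regimen(transform(reg1$events, dose = 120))
  p2 <- heart_interstitial_profiles(reg2, t_grid = tg)
  expect_equal(p2$dox$profile$conc, 2 * p1$dox$profile$conc,
               tolerance = 1e-10)
  # q3w multi-dose profile equals the sum of shifted single-dose profiles
  reg3 <- regimen(data.frame(drug = "dox", dose = c(60, 60),
                             dose_unit = "mg_per_m2", time_week = c(0, 3),
                             infusion_h = 1))
  p3 <- heart_interstitial_profiles(reg3, t_grid = tg)
  shift <- ctqsp::schedule_conc(p1$dox, pmax(tg - 3 * 168, 0)) *
    (tg >= 3 * 168)
  expect_equal(p3$dox$profile$conc,
               p1$dox$profile$conc + shift, tolerance = 1e-8)
  # zero-dose regimen: identically zero profile
  reg0 <- regimen_preset("DOX", cum_dose = 0)
  p0 <- heart_interstitial_profiles(reg0, t_grid = tg)
  expect_true(all(p0$dox$profile$conc == 0))
  expect_true(all(p0$trz$profile$conc == 0))
})

test_that("overlapping infusions of the same drug are rejected", {
  expect_error(regimen(data.frame(drug = "dox", dose = c(60, 60),
                                  dose_unit = "mg_per_m2",
                                  time_week = c(0, 0.001),
                                  infusion_h = c(2, 1))),
               "overlapping")
})

test_that("LVEF model: baseline flatness, compensated and ceiling-limited steps", {
  pat <- cardio_qsp_params(SV0 = 75, LVEDV = 120, ceiling = 1.3)
  tt <- seq(0, 2000, 10)
  flat <- simulate_lvef(pat, data.frame(time_h = tt, e_drug = rep(1, length(tt))))
  expect_equal(flat$LVEF, rep(attr(flat, "baseline"), length(tt)),
               tolerance = 1e-12)
  # step to 0.8 with generous ceiling: LVEF returns to baseline with the
  # compensation time constant
  step <- simulate_lvef(pat, data.frame(time_h = tt,
                                        e_drug = c(1, rep(0.8, length(tt) - 1))))
  base <- attr(step, "baseline")
  expect_equal(tail(step$LVEF, 1), base, tolerance = 1e-3)
  i200 <- which.min(abs(tt - pat$tau_comp))  # one time constant after step
  expected <- base * 0.8 * (1.25 + (1 - 1.25) * exp(-tt[i200] / pat$tau_comp))
  expect_equal(step$LVEF[i200], expected, tolerance = 0.02)
  # ceiling 1.1: steady-state deficit factor 0.8 * 1.1 = 0.88
  pat2 <- cardio_qsp_params(SV0 = 75, LVEDV = 120, ceiling = 1.1)
  step2 <- simulate_lvef(pat2, data.frame(time_h = tt,
                                          e_drug = c(1, rep(0.8, length(tt) - 1))))
  expect_equal(tail(step2$LVEF, 1), attr(step2, "baseline") * 0.88,
               tolerance = 1e-4)
})

test_that("dysfunction classifier modes", {
  base <- 60
  flat <- rep(60, 10)
  expect_false(classify_systolic_dysfunction(flat, base)$dysfunction)
  dip49 <- c(60, 55, 49, 52, 60)
  r <- classify_systolic_dysfunction(dip49, base, times = 0:4)
  expect_true(r$dysfunction)  # 11-point drop (and < 50 absolute)
  expect_equal(r$onset_h, 2)
  # 52%: false under point-drop mode, true under relative mode (13.3% drop)
  dip52 <- c(60, 55, 52, 60)
  expect_false(classify_systolic_dysfunction(dip52, base)$dysfunction)
  expect_true(classify_systolic_dysfunction(dip52, base,
                                            mode = "relative")$dysfunction)
  expect_error(classify_systolic_dysfunction(numeric(0), base), "empty")
})

test_that("comorbidity penalty compromises compensation", {
  normal <- cardio_qsp_params(SV0 = 75, LVEDV = 120, MAP = 95)
  comorbid <- cardio_qsp_params(SV0 = 75, LVEDV = 120, MAP = 120)
  expect_false(normal$comorbid); expect_true(comorbid$comorbid)
  tt <- seq(0, 3000, 10)
  ee <- data.frame(time_h = tt, e_drug = c(1, rep(0.85, length(tt) - 1)))
  ln <- simulate_lvef(normal, ee); lc <- simulate_lvef(comorbid, ee)
  expect_lt(min(lc$LVEF), min(ln$LVEF))
})
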