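baseline_state <- function() {
  c(f_nor = 1, f_inj_1 = 0, f_inj_2 = 0, f_inj_3 = 0, f_dead = 0,
    ATP = 1, MMP = 1, E_DOX_TRZ = 1)
}

test_that("drug-free baseline is a steady state and fraction flux is conserved", {
  p <- td_preset("interaction")
  d0 <- td_derivatives(baseline_state(), 0, 0, p)
  expect_equal(unname(d0), rep(0, 8))
  # fraction derivatives sum to zero exactly, at arbitrary states
  st <- c(f_nor = 0.4, f_inj_1 = 0.2, f_inj_2 = 0.15, f_inj_3 = 0.1,
          f_dead = 0.15, ATP = 0.7, MMP = 0.6, E_DOX_TRZ = 0.5)
  d <- td_derivatives(st, 2.3, 40, p)
  # double-precision accumulation (base sum() uses extended precision)
  expect_identical(Reduce(`+`, as.list(unname(d[1:5]))), 0)
})

test_that("injury hazard and Emax midpoints match their closed forms", {
  p <- td_preset("interaction")
  # 0.35% of normal myocytes injured per hour at 1 umol/L free doxorubicin
  d <- td_derivatives(baseline_state(), 1, 0, p)
  expect_equal(-d[["f_nor"]] * 100, 0.35, tolerance = 1e-12)
  # at C = EC50 the MMP production term is halved (Emax_kinMMP = 1)
  d_ec <- td_derivatives(baseline_state(), p[["EC50_kinMMP"]], 0, p)
  expect_equal(d_ec[["MMP"]],
               p[["k_in_MMP"]] * 0.5 - p[["k_out_MMP"]], tolerance = 1e-12)
})

test_that("survival fraction arithmetic and degenerate input", {
  expect_equal(survival_fraction(1, 0, 0), 1)
  expect_equal(survival_fraction(0.5, 0.2, 0.3), 0.7)
  expect_error(survival_fraction(0, 0, 0), "degenerate")
})

test_that("contractile force model: limits and ATP50 structure", {
  p <- td_preset("interaction")
  expect_equal(acf_force(0, 0, 1, p)$ACF, 0)
  expect_equal(acf_force(1, 0, 1, p)$ATP50, p[["ATP50_ref"]])
  # baseline force normalizes to 1: ACF_max/(1 + ATP50_ref)
  expect_equal(acf_force(1, 0, 1, p)$ACF, 1)
  # halving the enhancement state doubles the trastuzumab term in ATP50
  a1 <- acf_force(1, 50, 1, p)$ATP50 / p[["ATP50_ref"]] - 1
  a2 <- acf_force(1, 50, 0.5, p)$ATP50 / p[["ATP50_ref"]] - 1
  expect_equal(a2 / a1, 2, tolerance = 1e-12)
  expect_error(acf_force(1, 10, 0, p), "E_DOX_TRZ")
})

test_that("closed-form solutions match the adaptive ODE integration", {
  p <- td_preset("interaction")
  # clamp the free intracellular concentration via an effectively unbuffered
  # cell (tiny CN) held at partition equilibrium k_pp = 1
  dox_p <- dox_cellular_params(CN = 1e-9, k_pp = 1, PER = 100)
  C <- 1.5
  tg <- c(0, 2, 6, 12, 24)
  tr <- simulate_td(constant_exposure(C, 0, 24, drug = "dox"), NULL, tg,
                    td_params = p, dox_params = dox_p)
  # Eq-style exponential decay of the normal fraction under constant C
  expect_equal(tr$f_nor, exp(-p[["k_inj"]] * C * tg), tolerance = 1e-5)
  # enhancement state decay
  expect_equal(tr$E_DOX_TRZ, exp(-p[["k_e"]] * C * tg), tolerance = 1e-4)
  # MMP steady state under constant C
  mmp_ss <- 1 - C / (C + p[["EC50_kinMMP"]])
  tr_long <- simulate_td(constant_exposure(C, 0, 400, drug = "dox"), NULL,
                         c(0, 100, 400), td_params = p, dox_params = dox_p)
  expect_equal(tail(tr_long$MMP, 1), mmp_ss, tolerance = 1e-5)
  # analytic survival example: f_nor(24 h) at 5 umol/L with k_inj = 0.0035
  tr5 <- simulate_td(constant_exposure(5, 0, 24, drug = "dox"), NULL,
                     c(0, 24), td_params = p, dox_params = dox_p)
  expect_equal(tr5$f_nor[2], exp(-0.0035 * 5 * 24), tolerance = 1e-5)
  expect_equal(tr5$f_nor[2], 0.657, tolerance = 1e-3)
})

test_that("ATP steady state under saturating trastuzumab inhibition", {
  p <- td_preset("interaction")
  # saturating internalized trastuzumab: ATP production inhibited by
  # Emax_kinATP = 0.54, so ATP settles at 46% of baseline
  trz_p <- trz_cellular_params(k_int = 10, k_deg = 1e-9, k_dec = 0,
                               Ag_cell = 1e7)
  tr <- simulate_td(NULL, constant_exposure(1e6, 0, 2000, drug = "trz"),
                    c(0, 500, 1000, 2000),
                    td_params = p, trz_params = trz_p, clamp_trz = TRUE)
  expect_equal(tail(tr$ATP, 1), 1 - p[["Emax_kinATP"]], tolerance = 1e-3)
})

test_that("simulate_td: conservation, monotonicity, drug-free flatness", {
  p <- td_preset("interaction")
  tg <- c(0, 6, 12, 24, 30, 48, 72)
  # drug-free protocol: every observable identically 1
  tr0 <- simulate_td(NULL, NULL, tg, td_params = p)
  for (v in c("survival_fraction", "ATP", "MMP", "ACF", "E_DOX_TRZ"))
    expect_equal(tr0[[v]], rep(1, length(tg)), tolerance = 1e-10)
  # combination protocol
  tr <- simulate_td(constant_exposure(5, 0, 24, drug = "dox"),
                    constant_exposure(1000, 0, 72, drug = "trz"), tg,
                    td_params = p)
  tot <- tr$f_nor + tr$f_inj + tr$f_dead
  expect_equal(tot, rep(1, length(tg)), tolerance = 1e-8)
  expect_true(all(diff(tr$survival_fraction) <= 1e-12))
  expect_true(all(diff(tr$f_dead) >= -1e-12))
  expect_true(all(diff(tr$E_DOX_TRZ) <= 1e-12))
  expect_true(all(tr$ACF >= 0 & tr$ACF <= 1 + 1e-9))
})

test_that("trastuzumab 1 uM and 10 uM give near-identical force trajectories", {
  tg <- c(0, 6, 12, 24, 30, 48, 72)
  t1 <- simulate_td(NULL, constant_exposure(1000, 0, 72, drug = "trz"), tg)
  t10 <- simulate_td(NULL, constant_exposure(10000, 0, 72, drug = "trz"), tg)
  expect_equal(t1$ACF[-1], t10$ACF[-1], tolerance = 5e-3)
})

test_that("TD core agrees with an independent RK4 reference on a smooth segment", {
  p <- td_preset("interaction")
  dox_p <- dox_cellular_params()
  tg <- c(0, 3, 6, 9, 12)
  tr <- simulate_td(constant_exposure(5, 0, 12, drug = "dox"), NULL, tg,
                    td_params = p, dox_params = dox_p)
  rhs <- function(t, y) {
    cf <- free_intracellular_dox(max(y[["Ct"]], 0), dox_p)
    td <- td_derivatives(y[-1], cf, 0, p)
    c(ctqsp:::dox_uptake_rhs(y[["Ct"]], 5, dox_p), td)
  }
  y0 <- c(Ct = 0, baseline_state())
  ref <- rk4_integrate(rhs, y0, 12, dt = 1e-3, t_out = tg)
  expect_equal(tr$f_nor, unname(ref[, "f_nor"]), tolerance = 1e-5)
  expect_equal(tr$MMP, unname(ref[, "MMP"]), tolerance = 1e-5)
  expect_equal(tr$ATP, unname(ref[, "ATP"]), tolerance = 1e-5)
})
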