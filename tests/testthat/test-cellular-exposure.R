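test_that("free intracellular doxorubicin matches the mass-balance root", {
  p <- dox_cellular_params()
  expect_identical(free_intracellular_dox(0, p), 0)
  # frozen value computed with the independent uniroot oracle at the
  # published CN = 7.21e4 umol/L, k_d = 0.5 umol/L, C_total = 100 umol/L
  expect_equal(free_intracellular_dox(100, p), 6.944396e-4, tolerance = 1e-6)
  for (ct in c(1e-6, 0.1, 10, 1e3, 5e4, 7.2e4, 9e4, 2e5)) {
    expect_equal(free_intracellular_dox(ct, p),
                 free_dox_root(ct, p[["CN"]], p[["k_d"]]),
                 tolerance = 1e-9, label = sprintf("C_total = %g", ct))
  }
  expect_error(free_intracellular_dox(-1, p), "must be >= 0")
})

test_that("free concentration stays within [0, C_total] and has the no-binding limit", {
  p <- dox_cellular_params()
  ct <- 10^seq(-3, 5, length.out = 30)
  cf <- free_intracellular_dox(ct, p)
  expect_true(all(cf >= 0 & cf <= ct))
  # k_d -> infinity with finite CN: no effective binding, free == total
  p_free <- dox_cellular_params(k_d = 1e12)
  expect_equal(free_intracellular_dox(50, p_free), 50, tolerance = 1e-6)
})

test_that("doxorubicin uptake reaches the partition steady state and washes out", {
  p <- dox_cellular_params()
  sch <- constant_exposure(5, 0, 400, drug = "dox")
  out <- simulate_dox_cellular(p, sch, t_grid = c(0, 1, 5, seq(10, 400, 10)))
  expect_equal(out$C_in_total[1], 0)
  # long constant exposure: free concentration -> k_pp * C_ex
  expect_equal(tail(out$C_in_DOX, 1), p[["k_pp"]] * 5, tolerance = 1e-3)
  # zero exposure stays identically zero
  out0 <- simulate_dox_cellular(p, constant_exposure(0, 0, 10, drug = "dox"),
                                t_grid = 0:10)
  expect_true(all(out0$C_in_total == 0))
  # washout: total intracellular drug strictly decreasing afterwards
  outw <- simulate_dox_cellular(p, constant_exposure(5, 0, 24, drug = "dox"),
                                t_grid = c(0, 6, 12, 24, 30, 48, 72))
  post <- outw$C_in_total[outw$time >= 24]
  expect_true(all(diff(post) < 0))
})

test_that("dox uptake agrees with a fixed-step RK4 reference integrator", {
  p <- dox_cellular_params()
  sch <- constant_exposure(5, 0, 12, drug = "dox")
  t_out <- c(0, 2, 6, 12)
  sol <- simulate_dox_cellular(p, sch, t_out)
  rhs <- function(t, y) ctqsp:::dox_uptake_rhs(y, 5, p)
  ref <- rk4_integrate(rhs, c(Ct = 0), 12, dt = 1e-3, t_out = t_out)
  expect_equal(sol$C_in_total[-1], ref[-1, "Ct"], tolerance = 1e-6)
})

test_that("trastuzumab kinetics: binding steady state and conservation", {
  # k_int = k_dec = k_deg = 0 with clamped medium: Langmuir steady state
  p <- trz_cellular_params(k_int = 0, k_deg = 0, k_dec = 0)
  out <- simulate_trz_cellular(p, 100, t_grid = c(0, seq(0.5, 40, 0.5)),
                               clamp_medium = TRUE)
  kdis <- p[["k_off"]] / p[["k_on"]]
  expect_equal(tail(out$C_bind_TRZ, 1),
               p[["Ag_cell"]] * 100 / (kdis + 100), tolerance = 1e-6)
  # mass bookkeeping without degradation/deconjugation, unclamped
  out2 <- simulate_trz_cellular(p, 50, t_grid = seq(0, 48, 2))
  total <- out2$C_ex_TRZ + out2$C_bind_TRZ + out2$C_in_TRZ
  expect_equal(total, rep(50, length(total)), tolerance = 1e-7)
  # zero initial concentration: all states remain zero
  out0 <- simulate_trz_cellular(trz_cellular_params(), 0, t_grid = 0:10)
  expect_true(all(as.matrix(out0[, -1]) == 0))
})

test_that("receptor occupancy saturates: 1 uM and 10 uM arms nearly coincide", {
  p <- trz_cellular_params()
  tg <- seq(0, 72, 4)
  o1 <- simulate_trz_cellular(p, 1000, tg)
  o10 <- simulate_trz_cellular(p, 10000, tg)
  rel <- abs(o10$C_bind_TRZ[-1] / o1$C_bind_TRZ[-1] - 1)
  expect_true(all(rel < 0.05))
})

test_that("trz kinetics agree with a fixed-step RK4 reference", {
  p <- trz_cellular_params()
  t_out <- c(0, 6, 24, 48)
  # 100 nmol/L keeps the binding relaxation rate well inside the explicit
  # reference integrator's accurate region at dt = 1e-3 h
  sol <- simulate_trz_cellular(p, 100, t_out)
  rhs <- function(t, y) {
    bind <- p[["k_on"]] * y[1] * (p[["Ag_cell"]] - y[2]) - p[["k_off"]] * y[2]
    c(-bind - p[["k_dec"]] * y[1],
      bind - p[["k_int"]] * y[2],
      p[["k_int"]] * y[2] - p[["k_deg"]] * y[3])
  }
  ref <- rk4_integrate(rhs, c(Cex = 100, Cb = 0, Cin = 0), 48, dt = 1e-3,
                       t_out = t_out)
  expect_equal(sol$C_in_TRZ, unname(ref[, "Cin"]), tolerance = 1e-6)
  expect_equal(sol$C_bind_TRZ, unname(ref[, "Cb"]), tolerance = 1e-6)
})

test_that("all trajectories stay nonnegative", {
  p <- trz_cellular_params()
  for (c0 in c(1, 100, 10000)) {
    o <- simulate_trz_cellular(p, c0, seq(0, 72, 3))
    expect_true(all(as.matrix(o[, -1]) >= 0))
  }
  d <- simulate_dox_cellular(dox_cellular_params(),
                             constant_exposure(20, 0, 6, drug = "dox"),
                             seq(0, 72, 3))
  expect_true(all(as.matrix(d[, -1]) >= 0))
})
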