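test_that("two-step normalization arithmetic and control mapping", {
  expect_equal(normalize_two_step(80, 100, 0.9), (80 / 100) / 0.9)
  expect_error(normalize_two_step(80, 0, 0.9), "baseline")

  # treated identical to control at all times -> all normalized values 1
  arms <- data.frame(arm = c("control", "T"),
                     dox_start = 0, dox_end = 0, dox_conc = c(0, 0),
                     trz_start = 0, trz_end = 0, trz_conc = 0)
  tt <- c(0, 6, 24)
  raw <- expand.grid(arm = c("control", "T"), endpoint = "ACF",
                     time_h = tt, replicate = 1,
                     stringsAsFactors = FALSE)
  raw$value <- rep(c(5, 5), length(tt)) * rep(c(1, 0.8, 1.3), each = 2)
  ds <- normalize_raw(raw, arms)
  expect_true(all(abs(ds$data$value - 1) < 1e-12))

  # zero control measurement is reported with the offending time
  raw_bad <- raw; raw_bad$value[raw_bad$arm == "control" &
                                  raw_bad$time_h == 6] <- 0
  expect_error(normalize_raw(raw_bad, arms), "control")
})

test_that("generator round-trip: zero noise reproduces model trajectories", {
  ds <- generate_dataset("fig1b",
                         noise = noise_model(cv = 0, well_cv = 0,
                                             drift_amp = 0),
                         seed = 7)
  preset <- design_preset("fig1b")
  sim <- simulate_invitro_arms(preset$arms, preset$times)
  for (e in preset$endpoints) {
    d <- ds$data[ds$data$endpoint == e & ds$data$replicate == 1, ]
    model <- sim[[e]][cbind(match(d$arm, rownames(sim[[e]])),
                            match(as.character(d$time_h),
                                  colnames(sim[[e]])))]
    expect_equal(d$value, model, tolerance = 1e-10,
                 label = paste("endpoint", e))
  }
})

test_that("generator: drift cancels in the control arm and noise CV is honored", {
  ds <- generate_dataset("fig1b",
                         noise = noise_model(cv = 0.1, well_cv = 0.05,
                                             drift_amp = 0.05),
                         seed = 3)
  ctrl <- ds$data[ds$data$arm == "control", ]
  expect_true(all(abs(ctrl$value - 1) < 1e-12))

  # empirical raw-noise CV close to configured (treated wells, fixed point)
  preset <- design_preset("fig1b")
  preset$replicates <- 170
  ds2 <- generate_dataset(preset, noise = noise_model(cv = 0.1, well_cv = 0,
                                                      drift_amp = 0),
                          seed = 11)
  d <- ds2$data[ds2$data$arm == "TRZ1" & ds2$data$endpoint == "ATP" &
                  ds2$data$time_h == 48, ]
  cv_hat <- stats::sd(d$value) / mean(d$value)
  expect_gt(cv_hat, 0.08); expect_lt(cv_hat, 0.12)
})

test_that("generator is deterministic given the seed", {
  a <- generate_dataset("fig1b", seed = 5)
  b <- generate_dataset("fig1b", seed = 5)
  expect_identical(a$data$value, b$data$value)
  c <- generate_dataset("fig1b", seed = 6)
  expect_false(identical(a$data$value, c$data$value))
})

test_that("dataset CSV round-trips through the flat schema", {
  ds <- generate_dataset("fig1b", seed = 2)
  f <- tempfile(fileext = ".csv")
  write_invitro_csv(ds, f)
  ds2 <- read_invitro_csv(f)
  expect_equal(ds2$data$value, ds$data$value)
  d1 <- ds$design[order(ds$design$arm), ]
  d2 <- ds2$design[order(ds2$design$arm), ]
  expect_equal(d2$dox_conc, d1$dox_conc)
  expect_equal(d2$trz_end, d1$trz_end)
  unlink(f)
})

test_that("noise-free fit started at truth returns truth", {
  ds <- generate_dataset("fig1b",
                         noise = noise_model(cv = 0, well_cv = 0,
                                             drift_amp = 0),
                         seed = 1)
  f <- fit_stage2_interaction(ds, n_starts = 1, seed = 1)
  truth <- c(unclass(td_preset("interaction"))[
    c("k_inj", "tau", "EC50_kinMMP", "Emax_kinATP", "EC50_kinATP",
      "k_TRZ_ATP50", "k_e", "k_in_ATP", "k_in_MMP", "n")],
    CN = unname(dox_cellular_params()[["CN"]]))
  expect_equal(f$estimates[names(truth)], truth, tolerance = 1e-4)
  expect_lt(f$objective, 1e-10)
})

test_that("objective is invariant under record shuffling", {
  ds <- generate_dataset("fig1b", seed = 9)
  set.seed(33)
  perm <- sample(nrow(ds$data))
  ds_shuf <- ds
  ds_shuf$data <- ds$data[perm, ]
  # the objective value at a fixed parameter point is order-invariant ...
  ssr_at <- function(d, theta) {
    fd <- ctqsp:::build_fit_data(d, loq = 1e-3)
    am <- as.matrix(d$design[, c("dox_start", "dox_end", "dox_conc",
                                 "trz_start", "trz_end", "trz_conc")])
    storage.mode(am) <- "double"
    fd$arm_matrix <- am
    sum(ctqsp:::fit_residuals(log10(theta), names(theta), fd,
                              td_preset("interaction"),
                              dox_cellular_params(), trz_cellular_params(),
                              c(SF = 1, ACF = 1, ATP = 1, MMP = 1), 0.05)^2)
  }
  theta <- c(k_inj = 0.004, tau = 4, k_e = 8)
  expect_equal(ssr_at(ds, theta), ssr_at(ds_shuf, theta), tolerance = 1e-12)
  # ... and full fits agree up to the optimizer's floating-point path
  f1 <- fit_stage2_interaction(ds, n_starts = 1, seed = 1)
  f2 <- fit_stage2_interaction(ds_shuf, n_starts = 1, seed = 1)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-6)
  expect_equal(f1$estimates, f2$estimates, tolerance = 0.01)
})

test_that("bootstrap cross-check tracks the curvature-based uncertainties", {
  ds <- generate_dataset("fig1a", td_params = td_preset("dox_only"),
                         seed = 12)
  f <- fit_stage1_dox(ds, n_starts = 1, seed = 1)
  bs <- bootstrap_fit(f, ds, n_boot = 6, seed = 2)
  expect_equal(nrow(bs), 6)
  expect_true(all(is.finite(attr(bs, "rse_pct"))))
  # deterministic given the seed
  bs2 <- bootstrap_fit(f, ds, n_boot = 6, seed = 2)
  expect_identical(bs$k_inj, bs2$k_inj)
})

test_that("identifiability flags: single concentration and missing combo arms", {
  # single-concentration doxorubicin design: EC50_kinMMP flagged
  arms <- design_preset("fig1a")$arms
  keep <- arms$arm %in% c("control", grep("^DOX5_", arms$arm, value = TRUE))
  pre <- design_preset("fig1a"); pre$arms <- arms[keep, ]
  ds <- generate_dataset(pre, td_params = td_preset("dox_only"), seed = 4)
  expect_warning(f <- fit_stage1_dox(ds, n_starts = 1, seed = 1),
                 "single doxorubicin concentration")

  # no sequential/concurrent arms: k_e flagged non-identifiable
  pre_b <- design_preset("fig1b")
  keep_b <- pre_b$arms$arm %in% c("control", "DOX5", "TRZ1", "TRZ10")
  pre_b$arms <- pre_b$arms[keep_b, ]
  ds_b <- generate_dataset(pre_b, seed = 4)
  expect_warning(f_b <- fit_stage2_interaction(ds_b, n_starts = 1, seed = 1),
                 "k_e")
  expect_true("k_e" %in% f_b$flagged_nonidentifiable)
})
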