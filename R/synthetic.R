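#' Experimental design presets
#'
#' Arm tables of the two in-vitro designs the platform is calibrated on:
#'
#' * `"fig1a"` — doxorubicin exposure-extent/duration panel: 1.25, 2.5, 5,
#'   10 and 20 umol/L, each applied from time 0 for 6, 12, 24, 48 or 72 h
#'   followed by washout, observed to 72 h (endpoints ACF, SF, ATP, MMP;
#'   measurements at 0, 3, 6, 12, 24, 48, 72 h).
#' * `"fig1b"` — doxorubicin-trastuzumab interaction panel: doxorubicin
#'   5 umol/L for 24 h and trastuzumab 1 or 10 umol/L (1000 / 10000 nmol/L)
#'   given alone, sequentially (trastuzumab after the doxorubicin washout) or
#'   concurrently, observed at 0, 6, 12, 24, 30, 48, 72 h (endpoints ACF,
#'   SF, ATP).
#'
#' Both include a drug-free control arm and default to 3 replicates per arm.
#'
#' @param name `"fig1a"` or `"fig1b"`.
#' @param replicates wells per arm.
#' @return A list with `arms` (design data.frame), `times`, `endpoints`,
#'   `replicates`, `name`.
#' @export
design_preset <- function(name = c("fig1b", "fig1a"), replicates = 3) {
  name <- match.arg(name)
  if (name == "fig1a") {
    conc <- c(1.25, 2.5, 5, 10, 20)
    dur <- c(6, 12, 24, 48, 72)
    g <- expand.grid(conc = conc, dur = dur)
    arms <- data.frame(
      arm = sprintf("DOX%g_%gh", g$conc, g$dur),
      dox_start = 0, dox_end = g$dur, dox_conc = g$conc,
      trz_start = 0, trz_end = 0, trz_conc = 0)
    arms <- rbind(
      data.frame(arm = "control", dox_start = 0, dox_end = 0, dox_conc = 0,
                 trz_start = 0, trz_end = 0, trz_conc = 0),
      arms)
    times <- c(0, 3, 6, 12, 24, 48, 72)
    endpoints <- c("ACF", "SF", "ATP", "MMP")
  } else {
    trz_nM <- c(1, 10) * 1000
    mk <- function(id, ds, de, dc, ts, te, tc)
      data.frame(arm = id, dox_start = ds, dox_end = de, dox_conc = dc,
                 trz_start = ts, trz_end = te, trz_conc = tc)
    arms <- rbind(
      mk("control", 0, 0, 0, 0, 0, 0),
      mk("DOX5", 0, 24, 5, 0, 0, 0),
      mk("TRZ1", 0, 0, 0, 0, 72, trz_nM[1]),
      mk("TRZ10", 0, 0, 0, 0, 72, trz_nM[2]),
      mk("DOX5_TRZ1_seq", 0, 24, 5, 24, 72, trz_nM[1]),
      mk("DOX5_TRZ10_seq", 0, 24, 5, 24, 72, trz_nM[2]),
      mk("DOX5_TRZ1_conc", 0, 24, 5, 0, 72, trz_nM[1]),
      mk("DOX5_TRZ10_conc", 0, 24, 5, 0, 72, trz_nM[2]))
    times <- c(0, 6, 12, 24, 30, 48, 72)
    endpoints <- c("ACF", "SF", "ATP")
  }
  list(name = name, arms = arms, times = times, endpoints = endpoints,
       replicates = replicates)
}

#' Measurement noise model for the synthetic generator
#'
#' Multiplicative structure: per-well lognormal effects (inter-well
#' variability), a shared sinusoidal drift of the culture over time (a
#' circadian surrogate, affecting all wells including controls) and
#' independent lognormal measurement error per observation.
#'
#' @param cv measurement coefficient of variation, scalar or named per
#'   endpoint (`ACF`, `SF`, `ATP`, `MMP`).
#' @param well_cv inter-well effect CV.
#' @param drift_amp amplitude of the shared drift (fraction of signal).
#' @param drift_period drift period (h).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.10, well_cv = 0.05,
                        drift_amp = 0.05, drift_period = 24) {
  if (any(c(cv, well_cv, drift_amp) < 0))
    stop("noise_model: CVs and amplitudes must be >= 0")
  structure(list(cv = cv, well_cv = well_cv, drift_amp = drift_amp,
                 drift_period = drift_period),
            class = "noise_model")
}

# endpoint-specific raw instrument scales (arbitrary units)
.endpoint_scale <- c(ACF = 1, SF = 100, ATP = 2e5, MMP = 3.2)

#' Generate a synthetic in-vitro dataset
#'
#' Forward-simulates a design preset under given "true" parameters with the
#' fixed-step engine, applies the multiplicative noise structure to produce
#' raw well measurements, and runs them through the two-step normalization
#' ([normalize_raw()]) — so generated data carry exactly the statistical
#' structure the calibration module assumes.
#'
#' @param preset a [design_preset()] or preset name.
#' @param td_params,dox_params,trz_params generating ("true") parameters.
#' @param noise a [noise_model()].
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param dt engine step (h).
#' @return An [invitro_dataset()] (normalized; raw records attached). The
#'   generating parameters are attached as attribute `"truth"`.
#' @export
generate_dataset <- function(preset = "fig1b",
                             td_params = td_preset("interaction"),
                             dox_params = dox_cellular_params(),
                             trz_params = trz_cellular_params(),
                             noise = noise_model(),
                             seed = 1, dt = 0.05) {
  if (is.character(preset)) preset <- design_preset(preset)
  arms <- preset$arms; times <- preset$times
  endpoints <- preset$endpoints; n_rep <- preset$replicates

  sim <- simulate_invitro_arms(arms, times, td_params, dox_params,
                               trz_params, dt = dt)
  cv <- noise$cv
  if (length(cv) == 1) cv <- stats::setNames(rep(cv, 4), c("ACF", "SF", "ATP", "MMP"))

  drift <- 1 + noise$drift_amp * sin(2 * pi * times / noise$drift_period)

  set.seed(as.integer(seed))
  rows <- list(); k <- 0
  for (e in endpoints) {
    mod <- sim[[e]]
    sdl_w <- sqrt(log(1 + noise$well_cv^2))
    sdl_e <- sqrt(log(1 + cv[[e]]^2))
    for (r in seq_len(n_rep)) {
      well <- if (sdl_w > 0)
        exp(stats::rnorm(nrow(arms), -sdl_w^2 / 2, sdl_w)) else rep(1, nrow(arms))
      eps <- if (sdl_e > 0)
        matrix(exp(stats::rnorm(length(mod), -sdl_e^2 / 2, sdl_e)),
               nrow(mod), ncol(mod)) else matrix(1, nrow(mod), ncol(mod))
      # baseline (t = 0) and control-arm series are recorded as averages
      # (multiple fields of view per well; pooled control wells), so their
      # measurement error is negligible against the treated-well error:
      # a normalized observation then carries the configured endpoint CV.
      eps[, times == 0] <- 1
      eps[arms$arm == "control", ] <- 1
      raw <- mod * .endpoint_scale[[e]] * well *
        matrix(drift, nrow(mod), ncol(mod), byrow = TRUE) * eps
      k <- k + 1
      rows[[k]] <- data.frame(
        arm = rep(arms$arm, ncol(mod)),
        endpoint = e,
        time_h = rep(times, each = nrow(arms)),
        value = as.vector(raw),
        replicate = r)
    }
  }
  raw_df <- do.call(rbind, rows)
  ds <- normalize_raw(raw_df, arms, control_arm = "control")
  attr(ds, "truth") <- list(td = td_params, dox = dox_params, trz = trz_params)
  attr(ds, "preset") <- preset$name
  attr(ds, "seed") <- seed
  ds
}
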