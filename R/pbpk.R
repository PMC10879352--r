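#' Surrogate PBPK disposition parameters
#'
#' Linear two-compartment disposition surrogates used to generate
#' heart-interstitial exposure profiles from dosing regimens. All values are
#' placeholder, literature-informed and configurable; the `access` scalar is
#' the effective heart-interstitial access factor (interstitial effective
#' concentration as a fraction of total plasma concentration, absorbing
#' plasma protein binding and tissue penetration). The doxorubicin access
#' default is a calibration constant of the in-vivo translation layer (see
#' the package vignette).
#'
#' @param drug `"dox"` or `"trz"`.
#' @param CL clearance (L/h).
#' @param V1,V2 central / peripheral volumes (L).
#' @param Q intercompartmental clearance (L/h).
#' @param access heart-interstitial access factor (dimensionless).
#' @param infusion_h default infusion duration (h).
#' @param mw molecular mass (g/mol).
#' @return An object of class `pbpk_params`.
#' @export
pbpk_params <- function(drug = c("dox", "trz"),
                        CL = NULL, V1 = NULL, V2 = NULL, Q = NULL,
                        access = NULL, infusion_h = NULL, mw = NULL) {
  drug <- match.arg(drug)
  def <- if (drug == "dox") {
    list(CL = 55, V1 = 25, V2 = 1100, Q = 100, access = 0.006,
         infusion_h = 1, mw = 543.5)
  } else {
    list(CL = 0.012, V1 = 3.0, V2 = 3.0, Q = 0.03, access = 0.20,
         infusion_h = 1.5, mw = 1.48e5)
  }
  p <- list(drug = drug,
            CL = CL %||% def$CL, V1 = V1 %||% def$V1, V2 = V2 %||% def$V2,
            Q = Q %||% def$Q, access = access %||% def$access,
            infusion_h = infusion_h %||% def$infusion_h, mw = mw %||% def$mw)
  if (any(unlist(p[c("CL", "V1", "V2", "Q", "access", "infusion_h", "mw")]) <= 0))
    stop("pbpk_params: all values must be strictly positive")
  structure(p, class = "pbpk_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# modal (eigen) decomposition of the two-compartment system: central
# concentration C1(t) = B1*m1 + B2*m2 with dm_i/dt = -l_i*m_i + u(t),
# u = infusion rate (amount/h).
pk_modal <- function(CL, V1, V2, Q) {
  k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
  s <- k10 + k12 + k21
  disc <- sqrt(s * s - 4 * k10 * k21)
  l1 <- (s + disc) / 2
  l2 <- (s - disc) / 2
  B1 <- (k21 - l1) / (l2 - l1) / V1
  B2 <- (k21 - l2) / (l1 - l2) / V1
  c(l1 = l1, l2 = l2, B1 = B1, B2 = B2)
}

#' Dosing regimen
#'
#' @param events data.frame with columns `drug` (`"dox"`/`"trz"`), `dose`,
#'   `dose_unit` (`"mg_per_m2"` or `"mg_per_kg"`), `time_week`, `infusion_h`.
#' @return An object of class `regimen`.
#' @export
regimen <- function(events) {
  need <- c("drug", "dose", "dose_unit", "time_week", "infusion_h")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("regimen: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(events$drug %in% c("dox", "trz")))
    stop("regimen: drug must be 'dox' or 'trz'")
  if (!all(events$dose_unit %in% c("mg_per_m2", "mg_per_kg")))
    stop("regimen: dose_unit must be 'mg_per_m2' or 'mg_per_kg'")
  if (any(events$dose < 0) || any(events$time_week < 0) ||
      any(events$infusion_h <= 0))
    stop("regimen: nonnegative doses/times and positive infusion durations required")
  events <- events[order(events$drug, events$time_week), , drop = FALSE]
  for (d in unique(events$drug)) {
    e <- events[events$drug == d, ]
    t0 <- e$time_week * 168
    t1 <- t0 + e$infusion_h
    if (nrow(e) > 1 && any(t0[-1] < t1[-nrow(e)]))
      stop("regimen: overlapping infusions of ", d)
  }
  structure(list(events = events), class = "regimen")
}

#' Regimen presets of the virtual trials
#'
#' * `"TRZ"` — trastuzumab 4 mg/kg loading at week 0, then 2 mg/kg weekly
#'   through week 52.
#' * `"DOX_then_TRZ"` — doxorubicin 60 mg/m2 every 3 weeks for 12 weeks
#'   (weeks 0, 3, 6, 9), then the trastuzumab course starting week 13.
#' * `"DOX_plus_TRZ"` — the same doxorubicin course with the trastuzumab
#'   course starting concurrently at week 0.
#' * `"DOX"` — doxorubicin 60 mg/m2 every 3 weeks up to a cumulative dose
#'   `cum_dose` (mg/m2, multiple of 60).
#'
#' @param name preset name.
#' @param cum_dose cumulative doxorubicin dose (mg/m2) for `"DOX"`.
#' @return A [regimen()].
#' @export
regimen_preset <- function(name = c("TRZ", "DOX_then_TRZ", "DOX_plus_TRZ", "DOX"),
                           cum_dose = 240) {
  name <- match.arg(name)
  # 52 weekly administrations; the first week carries an additional 2 mg/kg
  # (4 mg/kg loading)
  trz_course <- function(start_week) {
    wk <- start_week + 0:51
    data.frame(drug = "trz", dose = c(4, rep(2, 51)),
               dose_unit = "mg_per_kg", time_week = wk, infusion_h = 1.5)
  }
  dox_course <- function(n_doses) {
    data.frame(drug = "dox", dose = rep(60, n_doses),
               dose_unit = "mg_per_m2", time_week = seq(0, by = 3,
                                                        length.out = n_doses),
               infusion_h = 1)
  }
  ev <- switch(name,
    TRZ = trz_course(0),
    DOX_then_TRZ = rbind(dox_course(4), trz_course(13)),
    DOX_plus_TRZ = rbind(dox_course(4), trz_course(0)),
    DOX = {
      if (cum_dose %% 60 != 0) stop("regimen_preset: cum_dose must be a multiple of 60")
      if (cum_dose == 0) data.frame(drug = character(), dose = numeric(),
                                    dose_unit = character(),
                                    time_week = numeric(),
                                    infusion_h = numeric())
      else dox_course(cum_dose / 60)
    })
  r <- if (nrow(ev) == 0)
    structure(list(events = ev), class = "regimen") else regimen(ev)
  attr(r, "preset") <- name
  r
}

# per-patient infusion rate matrices (amount/h) and shared event windows
regimen_engine_inputs <- function(reg, weight, bsa,
                                  pbpk_dox = pbpk_params("dox"),
                                  pbpk_trz = pbpk_params("trz")) {
  ev <- reg$events
  n <- length(weight)
  out <- list()
  for (d in c("dox", "trz")) {
    e <- ev[ev$drug == d, , drop = FALSE]
    pb <- if (d == "dox") pbpk_dox else pbpk_trz
    if (nrow(e) == 0) {
      out[[d]] <- list(ev = matrix(0, 0, 2), rate = matrix(0, n, 0))
      next
    }
    t0 <- e$time_week * 168
    win <- cbind(t0, t0 + e$infusion_h)
    size <- if (all(e$dose_unit == "mg_per_m2")) bsa else weight
    # mg -> umol (dox) / nmol (trz)
    amount_factor <- if (d == "dox") 1000 / pb$mw else 1e6 / pb$mw
    rate <- outer(size, e$dose * amount_factor / e$infusion_h)
    out[[d]] <- list(ev = win, rate = rate)
  }
  out
}

#' Heart-interstitial exposure profiles for a regimen
#'
#' Closed-form central concentrations of the linear two-compartment
#' surrogates (superposition of infusion responses), scaled by the
#' heart-interstitial access factor, sampled on a regular grid.
#'
#' @param reg a [regimen()].
#' @param weight,bsa patient size (kg, m2).
#' @param pbpk_dox,pbpk_trz [pbpk_params()] objects.
#' @param t_grid output times (h); default hourly over the regimen span
#'   plus five terminal half-lives.
#' @return List with [exposure_schedule()] profiles `dox` (umol/L) and
#'   `trz` (nmol/L).
#' @export
heart_interstitial_profiles <- function(reg, weight = 70, bsa = 1.79,
                                        pbpk_dox = pbpk_params("dox"),
                                        pbpk_trz = pbpk_params("trz"),
                                        t_grid = NULL) {
  stopifnot(inherits(reg, "regimen"))
  if (is.null(t_grid)) {
    t_end <- if (nrow(reg$events)) max(reg$events$time_week) * 168 + 24 * 7 * 4
             else 168
    t_grid <- seq(0, t_end, by = 1)
  }
  inp <- regimen_engine_inputs(reg, weight, bsa, pbpk_dox, pbpk_trz)
  prof <- function(d, pb) {
    modal <- pk_modal(pb$CL, pb$V1, pb$V2, pb$Q)
    ev <- inp[[d]]$ev; rate <- inp[[d]]$rate
    conc <- numeric(length(t_grid))
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        for (m in 1:2) {
          l <- modal[[paste0("l", m)]]; B <- modal[[paste0("B", m)]]
          te <- pmax(pmin(t_grid, ev[i, 2]) - ev[i, 1], 0)  # time infused
          ta <- pmax(t_grid - ev[i, 2], 0)                  # time since end
          mode_amt <- rate[1, i] / l * (1 - exp(-l * te)) * exp(-l * ta)
          conc <- conc + B * mode_amt
        }
      }
    }
    exposure_schedule(profile = list(time = t_grid, conc = pb$access * pmax(conc, 0)),
                      drug = if (d == "dox") "dox" else "trz")
  }
  list(dox = prof("dox", pbpk_dox), trz = prof("trz", pbpk_trz))
}
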