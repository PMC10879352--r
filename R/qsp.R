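#' Cardiac response (surrogate QSP) parameters
#'
#' Minimal stroke-volume model of the systemic response: the drug effect
#' multiplies stroke volume, and a first-order compensation state relaxes
#' toward restoring cardiac output up to a ceiling. Comorbid patients
#' (hypertension: MAP >= 115 mmHg, or dilated cardiomyopathy:
#' LVEDV >= 146 mL) have their compensation gain and ceiling margin scaled
#' down by `comorbid_penalty`.
#'
#' @param SV0 baseline stroke volume (mL).
#' @param LVEDV left-ventricular end-diastolic volume (mL).
#' @param MAP mean arterial pressure (mmHg).
#' @param gain compensation gain (1 = full restoration up to the ceiling).
#' @param ceiling maximal compensatory amplification of stroke volume.
#' @param tau_comp compensation time constant (h).
#' @param comorbid_penalty multiplier applied to `gain` and `ceiling - 1`
#'   for comorbid patients.
#' @param r_access drug-accessibility exponent (1 in vitro, 0.12 in vivo).
#' @return An object of class `cardio_qsp_params`. Baseline LVEF (%) is
#'   attached as attribute; comorbidity is derived from `MAP` and `LVEDV`.
#' @export
cardio_qsp_params <- function(SV0 = 77, LVEDV = 125, MAP = 95,
                              gain = 1, ceiling = 1.2, tau_comp = 96,
                              comorbid_penalty = 0.5, r_access = 0.12) {
  if (SV0 <= 0 || LVEDV <= 0 || SV0 >= LVEDV)
    stop("cardio_qsp_params: need 0 < SV0 < LVEDV")
  if (r_access <= 0 || r_access > 1)
    stop("cardio_qsp_params: r_access must be in (0, 1]")
  comorbid <- MAP >= 115 || LVEDV >= 146
  if (comorbid) {
    gain <- gain * comorbid_penalty
    ceiling <- 1 + (ceiling - 1) * comorbid_penalty
  }
  structure(list(SV0 = SV0, LVEDV = LVEDV, MAP = MAP, gain = gain,
                 ceiling = ceiling, tau_comp = tau_comp,
                 comorbid = comorbid, r_access = r_access),
            class = "cardio_qsp_params")
}

#' Cellular effect scaled to tissue: E_drug
#'
#' `E_drug = (survival_fraction * ACF) ^ r_access`. With `r_access = 1` this
#' is the in-vitro effect itself; in vivo the exponent (default 0.12)
#' attenuates the effect to reflect the reduced drug accessibility of
#' cardiomyocytes in 3D tissue.
#'
#' @param survival_fraction surviving myocyte fraction, in `[0, 1]`.
#' @param acf normalized average contractile force, in `[0, 1]`.
#' @param r_access accessibility exponent in (0, 1].
#' @return E_drug in `[0, 1]`; vectorized.
#' @export
e_drug <- function(survival_fraction, acf, r_access = 0.12) {
  if (any(r_access <= 0 | r_access > 1))
    stop("e_drug: r_access must be in (0, 1]")
  if (any(survival_fraction < 0 | acf < 0))
    stop("e_drug: inputs must be nonnegative")
  (survival_fraction * acf)^r_access
}

#' Simulate the LVEF trajectory for a drug-effect series
#'
#' Stroke volume is `SV0 * E_drug(t) * Comp(t)`, where the compensation
#' state relaxes first-order (time constant `tau_comp`) toward
#' `min(1 + gain * (1/E_drug - 1), ceiling)`; LVEF(t) = SV(t)/LVEDV * 100.
#'
#' @param patient a [cardio_qsp_params()] object.
#' @param e_drug_series data.frame with columns `time_h` (increasing, from
#'   0) and `e_drug` in (0, 1].
#' @return An `lvef_trajectory` data.frame: `time_h`, `time_week`, `LVEF`,
#'   `E_drug`, `comp`. Baseline LVEF is attached as attribute `"baseline"`.
#' @export
simulate_lvef <- function(patient, e_drug_series) {
  stopifnot(inherits(patient, "cardio_qsp_params"))
  tt <- e_drug_series$time_h
  ee <- e_drug_series$e_drug
  if (any(ee <= 0) || any(ee > 1))
    stop("simulate_lvef: E_drug must be in (0, 1]")
  stopifnot(!is.unsorted(tt, strictly = TRUE), tt[1] == 0)
  base <- 100 * patient$SV0 / patient$LVEDV
  n <- length(tt)
  comp <- numeric(n); comp[1] <- 1
  for (i in 2:n) {
    h <- tt[i] - tt[i - 1]
    target <- min(1 + patient$gain * (1 / ee[i] - 1), patient$ceiling)
    comp[i] <- target + (comp[i - 1] - target) * exp(-h / patient$tau_comp)
  }
  out <- data.frame(time_h = tt, time_week = tt / 168,
                    LVEF = base * ee * comp, E_drug = ee, comp = comp)
  attr(out, "baseline") <- base
  class(out) <- c("lvef_trajectory", "data.frame")
  out
}

#' Classify systolic dysfunction from an LVEF trajectory
#'
#' Two selectable readings of the clinical rule:
#' * `"point_drop_or_absolute50"` (default): a drop of more than 10 LVEF
#'   percentage points from baseline, or absolute LVEF below 50%.
#' * `"relative"`: a relative drop of more than 10% of baseline, or LVEF
#'   below 50% of baseline.
#'
#' @param lvef numeric LVEF series (%) or an `lvef_trajectory`.
#' @param baseline baseline LVEF (%); taken from the trajectory attribute
#'   if missing.
#' @param mode classification mode.
#' @param times times (h) matching `lvef`; used for the onset.
#' @return list with `dysfunction` (logical) and `onset_h` (first time the
#'   criterion is met, `NA` if never).
#' @export
classify_systolic_dysfunction <- function(lvef, baseline = NULL,
                                          mode = c("point_drop_or_absolute50",
                                                   "relative"),
                                          times = NULL) {
  mode <- match.arg(mode)
  if (inherits(lvef, "lvef_trajectory")) {
    if (is.null(baseline)) baseline <- attr(lvef, "baseline")
    times <- lvef$time_h
    lvef <- lvef$LVEF
  }
  if (!length(lvef)) stop("classify_systolic_dysfunction: empty trajectory")
  if (is.null(baseline)) stop("classify_systolic_dysfunction: baseline required")
  hit <- if (mode == "point_drop_or_absolute50")
    (baseline - lvef > 10) | (lvef < 50)
  else
    (lvef < 0.9 * baseline) | (lvef < 0.5 * baseline)
  onset <- if (any(hit)) {
    if (is.null(times)) which(hit)[1] else times[which(hit)[1]]
  } else NA_real_
  list(dysfunction = any(hit), onset_h = onset)
}
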