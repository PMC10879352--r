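#' Free intracellular doxorubicin from total intracellular drug
#'
#' Closed-form solution of the intracellular mass balance
#' `C_free + CN * C_free / (k_d + C_free) = C_total` for the free
#' concentration, given a single class of DNA-binding sites at concentration
#' `CN` with dissociation constant `k_d`. Implemented in the algebraically
#' stable form `2*k_d*C_total / ((CN + k_d - C_total) + sqrt((CN + k_d -
#' C_total)^2 + 4*k_d*C_total))`, which avoids the catastrophic cancellation
#' of the textbook quadratic root when `C_total << CN`.
#'
#' @param C_in_total total intracellular doxorubicin (umol/L); vectorized.
#' @param params a [dox_cellular_params()] object (uses `CN`, `k_d`).
#' @return Free intracellular concentration (umol/L), in `[0, C_in_total]`.
#' @export
free_intracellular_dox <- function(C_in_total, params = dox_cellular_params()) {
  if (any(C_in_total < 0)) stop("free_intracellular_dox: C_in_total must be >= 0")
  CN <- params[["CN"]]; kd <- params[["k_d"]]
  b <- CN + kd - C_in_total
  disc <- sqrt(b * b + 4 * kd * C_in_total)
  ifelse(b >= 0,
         2 * kd * C_in_total / (b + disc),
         0.5 * (-b + disc))
}

# RHS of the total intracellular doxorubicin balance (umol/L/h)
dox_uptake_rhs <- function(C_in_total, C_ex, params) {
  k_flux <- attr(params, "k_flux")
  C_free <- free_intracellular_dox(C_in_total, params)
  k_flux * (C_ex - C_free / params[["k_pp"]])
}

#' Simulate cellular doxorubicin exposure
#'
#' Integrates the total intracellular doxorubicin balance (influx, efflux and
#' DNA binding) under a piecewise extracellular schedule, restarting the
#' adaptive solver exactly at every window boundary. Medium depletion is
#' neglected (medium volume >> total cell volume); washout is an
#' instantaneous step of the extracellular concentration to zero.
#'
#' @param params a [dox_cellular_params()] object.
#' @param schedule an [exposure_schedule()] for doxorubicin (umol/L).
#' @param t_grid increasing output times (h).
#' @param rtol,atol solver tolerances.
#' @return data.frame with columns `time`, `C_ex_DOX`, `C_in_total`,
#'   `C_in_DOX` (free).
#' @export
simulate_dox_cellular <- function(params, schedule, t_grid,
                                  rtol = 1e-8, atol = 1e-10) {
  stopifnot(!is.unsorted(t_grid, strictly = TRUE))
  rhs <- function(t, y, parms) {
    list(dox_uptake_rhs(y[1], sched_eval(schedule, t, parms), params))
  }
  sol <- integrate_piecewise(rhs, y0 = c(C_in_total = 0), t_grid = t_grid,
                             breaks = schedule_breaks(schedule),
                             rtol = rtol, atol = atol)
  data.frame(
    time = sol[, "time"],
    C_ex_DOX = schedule_conc(schedule, sol[, "time"]),
    C_in_total = sol[, "C_in_total"],
    C_in_DOX = free_intracellular_dox(pmax(sol[, "C_in_total"], 0), params))
}

#' Simulate cellular trastuzumab kinetics
#'
#' Integrates free-medium, surface-bound and internalized trastuzumab.
#' With `clamp_medium = FALSE` (default) the medium is depleted by net binding
#' and deconjugation as written in the model; with `clamp_medium = TRUE` the
#' medium concentration is held at the schedule value (reservoir assumption,
#' used for in-vivo tissue driven by plasma).
#'
#' @param params a [trz_cellular_params()] object.
#' @param C_ex0 initial medium concentration (nmol/L) for a constant-exposure
#'   run, or an [exposure_schedule()] (profile schedules imply clamping).
#' @param t_grid increasing output times (h).
#' @param clamp_medium hold the medium concentration fixed?
#' @param rtol,atol solver tolerances.
#' @return data.frame with columns `time`, `C_ex_TRZ`, `C_bind_TRZ`,
#'   `C_in_TRZ`.
#' @export
simulate_trz_cellular <- function(params, C_ex0, t_grid,
                                  clamp_medium = FALSE,
                                  rtol = 1e-8, atol = 1e-10) {
  stopifnot(!is.unsorted(t_grid, strictly = TRUE))
  if (inherits(C_ex0, "exposure_schedule")) {
    schedule <- C_ex0
  } else {
    if (C_ex0 < 0) stop("simulate_trz_cellular: C_ex0 must be >= 0")
    schedule <- constant_exposure(C_ex0, 0, max(t_grid) + 1, drug = "trz")
  }
  k_on <- params[["k_on"]]; k_off <- params[["k_off"]]
  k_int <- params[["k_int"]]; k_deg <- params[["k_deg"]]
  k_dec <- params[["k_dec"]]; Ag <- params[["Ag_cell"]]

  if (clamp_medium) {
    rhs <- function(t, y, parms) {
      Cex <- sched_eval(schedule, t, parms)
      bind <- k_on * Cex * (Ag - y[1]) - k_off * y[1]
      list(c(bind - k_int * y[1],
             k_int * y[1] - k_deg * y[2]))
    }
    y0 <- c(C_bind_TRZ = 0, C_in_TRZ = 0)
    sol <- integrate_piecewise(rhs, y0, t_grid, schedule_breaks(schedule),
                               rtol = rtol, atol = atol)
    out <- data.frame(time = sol[, "time"],
                      C_ex_TRZ = schedule_conc(schedule, sol[, "time"]),
                      C_bind_TRZ = sol[, "C_bind_TRZ"],
                      C_in_TRZ = sol[, "C_in_TRZ"])
  } else {
    # medium state carries across windows; schedule steps add/remove drug:
    # at a window start the medium is set to the window concentration,
    # at washout it is set to 0 (bound/internalized drug is retained).
    rhs <- function(t, y, parms) {
      bind <- k_on * y[1] * (Ag - y[2]) - k_off * y[2]
      list(c(-bind - k_dec * y[1],
             bind - k_int * y[2],
             k_int * y[2] - k_deg * y[3]))
    }
    breaks <- schedule_breaks(schedule)
    segs <- unique(c(min(t_grid), breaks[breaks > min(t_grid) & breaks < max(t_grid)],
                     max(t_grid)))
    y <- c(C_ex_TRZ = schedule_conc(schedule, segs[1]),
           C_bind_TRZ = 0, C_in_TRZ = 0)
    rows <- list()
    for (i in seq_len(length(segs) - 1)) {
      tt <- sort(unique(c(segs[i], t_grid[t_grid >= segs[i] & t_grid <= segs[i + 1]],
                          segs[i + 1])))
      sol <- deSolve::lsoda(y, tt, rhs, parms = NULL, rtol = rtol, atol = atol)
      rows[[i]] <- sol[sol[, "time"] %in% t_grid, , drop = FALSE]
      y <- sol[nrow(sol), -1]
      # reset medium at the segment boundary to the incoming window value
      y[1] <- schedule_conc(schedule, segs[i + 1])
    }
    sol <- do.call(rbind, rows)
    sol <- sol[!duplicated(sol[, "time"]), , drop = FALSE]
    out <- data.frame(time = sol[, "time"],
                      C_ex_TRZ = sol[, "C_ex_TRZ"],
                      C_bind_TRZ = sol[, "C_bind_TRZ"],
                      C_in_TRZ = sol[, "C_in_TRZ"])
  }
  rownames(out) <- NULL
  out
}

# Integrate an ODE with hard restarts at schedule discontinuities, returning
# states on t_grid. rhs is a deSolve-style function(t, y, parms); parms
# receives the segment midpoint, so piecewise-constant forcings can be
# evaluated frozen per segment (exact, and it keeps the discontinuity out of
# the solver's error test at segment endpoints).
integrate_piecewise <- function(rhs, y0, t_grid, breaks,
                                rtol = 1e-8, atol = 1e-10) {
  t0 <- t_grid[1]; t1 <- t_grid[length(t_grid)]
  breaks <- breaks[breaks > t0 & breaks < t1]
  segs <- unique(c(t0, breaks, t1))
  y <- y0
  rows <- list()
  for (i in seq_len(length(segs) - 1)) {
    tt <- sort(unique(c(segs[i], t_grid[t_grid >= segs[i] & t_grid <= segs[i + 1]],
                        segs[i + 1])))
    tm <- (segs[i] + segs[i + 1]) / 2
    sol <- tryCatch(
      deSolve::lsoda(y, tt, rhs, parms = tm, rtol = rtol, atol = atol),
      error = function(e) stop("integration failed near t = ", segs[i],
                               " (state: ", paste(signif(y, 4), collapse = ", "),
                               "): ", conditionMessage(e)))
    rows[[i]] <- sol[sol[, "time"] %in% t_grid, , drop = FALSE]
    y <- sol[nrow(sol), -1]
    names(y) <- names(y0)
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out[, "time"]), , drop = FALSE]
}
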