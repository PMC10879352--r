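#' Derivatives of the toxicodynamic state
#'
#' Pure function returning the time derivative of the nine-dimensional TD
#' state: the five population fractions (normal, three injured transit
#' compartments, dead), normalized ATP and MMP, and the doxorubicin
#' enhancement state `E_DOX_TRZ`, given the instantaneous free intracellular
#' doxorubicin and internalized trastuzumab concentrations.
#'
#' Structure: injury is a first-order loss of normal cells with hazard
#' `k_inj * C_in_DOX`; injured cells traverse three transit compartments of
#' mean time `tau` each before dying; MMP production is zero-order with an
#' Emax inhibition by doxorubicin; ATP production is stimulated by
#' `(MMP/MMP0)^n` and inhibited by trastuzumab (Emax model); `E_DOX_TRZ`
#' decays at rate `k_e * C_in_DOX`. The five fraction derivatives sum to zero
#' exactly.
#'
#' @param state named numeric vector with `f_nor`, `f_inj_1`, `f_inj_2`,
#'   `f_inj_3`, `f_dead`, `ATP`, `MMP`, `E_DOX_TRZ`.
#' @param C_in_DOX free intracellular doxorubicin (umol/L).
#' @param C_in_TRZ internalized trastuzumab (nmol/L).
#' @param params a [td_parameters()] object.
#' @return Named numeric vector of derivatives, same order as `state`.
#' @export
td_derivatives <- function(state, C_in_DOX, C_in_TRZ, params) {
  p <- params
  inj_flux <- p[["k_inj"]] * C_in_DOX * state[["f_nor"]]
  t1 <- state[["f_inj_1"]] / p[["tau"]]
  t2 <- state[["f_inj_2"]] / p[["tau"]]
  t3 <- state[["f_inj_3"]] / p[["tau"]]
  inh_mmp <- p[["Emax_kinMMP"]] * C_in_DOX / (C_in_DOX + p[["EC50_kinMMP"]])
  inh_atp <- p[["Emax_kinATP"]] * C_in_TRZ / (C_in_TRZ + p[["EC50_kinATP"]])
  dMMP <- p[["k_in_MMP"]] * (1 - inh_mmp) - p[["k_out_MMP"]] * state[["MMP"]]
  dATP <- p[["k_in_ATP"]] * (state[["MMP"]] / p[["MMP0"]])^p[["n"]] *
    (1 - inh_atp) - p[["k_out_ATP"]] * state[["ATP"]]
  dE <- -p[["k_e"]] * C_in_DOX * state[["E_DOX_TRZ"]]
  d_nor <- -inj_flux
  d1 <- inj_flux - t1
  d2 <- t1 - t2
  d3 <- t2 - t3
  # closing the balance makes the five-fraction flux sum exactly zero in
  # floating point (algebraically d_dead == t3)
  d_dead <- -(d_nor + d1 + d2 + d3)
  c(f_nor = d_nor, f_inj_1 = d1, f_inj_2 = d2, f_inj_3 = d3, f_dead = d_dead,
    ATP = dATP, MMP = dMMP, E_DOX_TRZ = dE)
}

#' Survival fraction of the myocyte population
#'
#' `(f_nor + f_inj) / (f_nor + f_inj + f_dead)`: the surviving (normal plus
#' injured) share of the population. Equals `f_nor + f_inj` whenever the
#' fractions sum to one.
#'
#' @param f_nor fraction of normal myocytes.
#' @param f_inj total injured fraction (sum of the transit compartments).
#' @param f_dead dead fraction.
#' @return Survival fraction in `[0, 1]`; vectorized.
#' @export
survival_fraction <- function(f_nor, f_inj, f_dead) {
  tot <- f_nor + f_inj + f_dead
  if (any(tot <= 0)) stop("survival_fraction: degenerate all-zero population")
  (f_nor + f_inj) / tot
}

#' Average contractile force from ATP
#'
#' Emax relationship between the remaining ATP fraction and the average
#' contractile force (ACF), with a half-maximal ATP level (`ATP50`) that is
#' raised linearly by internalized trastuzumab and further amplified after
#' doxorubicin exposure through the enhancement state:
#' `ATP50 = ATP50_ref * (1 + C_in_TRZ * k_TRZ_ATP50 / E_DOX_TRZ)` and
#' `ACF = ACF_max * ATP / (ATP + ATP50)`.
#'
#' @param ATP normalized ATP level (>= 0).
#' @param C_in_TRZ internalized trastuzumab (nmol/L).
#' @param E_DOX_TRZ doxorubicin enhancement state (> 0).
#' @param params a [td_parameters()] object.
#' @return Named list with vectors `ACF` and `ATP50`.
#' @export
acf_force <- function(ATP, C_in_TRZ = 0, E_DOX_TRZ = 1, params) {
  if (any(ATP < 0)) stop("acf_force: ATP must be >= 0")
  if (any(E_DOX_TRZ <= 0)) stop("acf_force: E_DOX_TRZ must be > 0")
  ATP50 <- params[["ATP50_ref"]] *
    (1 + C_in_TRZ * params[["k_TRZ_ATP50"]] / E_DOX_TRZ)
  list(ACF = params[["ACF_max"]] * ATP / (ATP + ATP50), ATP50 = ATP50)
}

#' Simulate the full in-vitro toxicodynamic trajectory
#'
#' Couples cellular drug exposure (doxorubicin uptake/DNA binding and
#' trastuzumab binding/internalization) to the TD core and integrates the
#' joint system with a stiff-capable adaptive solver, restarting exactly at
#' every exposure discontinuity. ATP, MMP and ACF are reported normalized to
#' their baseline (t = 0, drug-free steady state) values.
#'
#' @param dox_schedule [exposure_schedule()] for doxorubicin, or `NULL`.
#' @param trz_schedule [exposure_schedule()] for trastuzumab, or `NULL`.
#' @param t_grid increasing output times (h), starting at 0.
#' @param td_params a [td_parameters()] object.
#' @param dox_params a [dox_cellular_params()] object.
#' @param trz_params a [trz_cellular_params()] object.
#' @param clamp_trz hold the trastuzumab medium concentration at the schedule
#'   value (reservoir assumption) instead of depleting it.
#' @param rtol,atol solver tolerances.
#' @return A `td_trajectory`: data.frame with columns `time`, `f_nor`,
#'   `f_inj`, `f_dead`, `survival_fraction`, `ATP`, `MMP`, `ACF`,
#'   `E_DOX_TRZ`, `C_in_DOX`, `C_in_TRZ`, plus the raw fraction compartments.
#' @export
simulate_td <- function(dox_schedule = NULL, trz_schedule = NULL, t_grid,
                        td_params = td_preset("interaction"),
                        dox_params = dox_cellular_params(),
                        trz_params = trz_cellular_params(),
                        clamp_trz = FALSE,
                        rtol = 1e-8, atol = 1e-12) {
  stopifnot(t_grid[1] == 0, !is.unsorted(t_grid, strictly = TRUE))
  p <- td_params
  k_on <- trz_params[["k_on"]]; k_off <- trz_params[["k_off"]]
  k_int <- trz_params[["k_int"]]; k_deg <- trz_params[["k_deg"]]
  k_dec <- trz_params[["k_dec"]]; Ag <- trz_params[["Ag_cell"]]

  MMP0_ss <- p[["k_in_MMP"]] / p[["k_out_MMP"]]
  ATP0_ss <- p[["k_in_ATP"]] / p[["k_out_ATP"]] * (MMP0_ss / p[["MMP0"]])^p[["n"]]

  has_dox <- !is.null(dox_schedule)
  has_trz <- !is.null(trz_schedule)

  # state: Ct (dox total), Cex/Cb/Cin (trz), f_nor, f1, f2, f3, f_dead, ATP, MMP, E
  y0 <- c(Ct = 0, Cex = 0, Cb = 0, Cin = 0,
          f_nor = 1, f_inj_1 = 0, f_inj_2 = 0, f_inj_3 = 0, f_dead = 0,
          ATP = ATP0_ss, MMP = MMP0_ss, E = 1)
  if (has_trz && !clamp_trz)
    y0[["Cex"]] <- schedule_conc(trz_schedule, 0)

  rhs <- function(t, y, parms) {
    C_ex_dox <- if (has_dox) sched_eval(dox_schedule, t, parms) else 0
    C_free <- free_intracellular_dox(max(y[["Ct"]], 0), dox_params)
    dCt <- attr(dox_params, "k_flux") *
      (C_ex_dox - C_free / dox_params[["k_pp"]])
    if (has_trz) {
      Cex <- if (clamp_trz) sched_eval(trz_schedule, t, parms) else y[["Cex"]]
      bind <- k_on * Cex * (Ag - y[["Cb"]]) - k_off * y[["Cb"]]
      dCex <- if (clamp_trz) 0 else -bind - k_dec * y[["Cex"]]
      dCb <- bind - k_int * y[["Cb"]]
      dCin <- k_int * y[["Cb"]] - k_deg * y[["Cin"]]
    } else {
      dCex <- dCb <- dCin <- 0
    }
    td <- td_derivatives(
      y[c("f_nor", "f_inj_1", "f_inj_2", "f_inj_3", "f_dead", "ATP", "MMP")] |>
        c(E_DOX_TRZ = unname(y[["E"]])),
      C_in_DOX = C_free, C_in_TRZ = max(y[["Cin"]], 0), params = p)
    # once the enhancement state is scientifically zero, freeze it: its
    # continued exponential crash only starves the step-size controller
    if (y[["E"]] < 1e-30) td[["E_DOX_TRZ"]] <- 0
    list(c(dCt, dCex, dCb, dCin, td))
  }

  breaks <- sort(unique(c(schedule_breaks(dox_schedule),
                          schedule_breaks(trz_schedule))))
  # unclamped trz medium resets at its own window boundaries
  trz_breaks <- if (has_trz && !clamp_trz) schedule_breaks(trz_schedule) else numeric()

  t0 <- t_grid[1]; t1 <- t_grid[length(t_grid)]
  segs <- unique(c(t0, breaks[breaks > t0 & breaks < t1], t1))
  y <- y0
  rows <- list()
  for (i in seq_len(length(segs) - 1)) {
    tt <- sort(unique(c(segs[i], t_grid[t_grid >= segs[i] & t_grid <= segs[i + 1]],
                        segs[i + 1])))
    sol <- tryCatch(
      deSolve::lsoda(y, tt, rhs, parms = (segs[i] + segs[i + 1]) / 2,
                     rtol = rtol, atol = atol),
      error = function(e) stop("simulate_td: integration failed near t = ",
                               segs[i], ": ", conditionMessage(e)))
    rows[[i]] <- sol[sol[, "time"] %in% t_grid, , drop = FALSE]
    y <- sol[nrow(sol), -1]
    names(y) <- names(y0)
    if (segs[i + 1] %in% trz_breaks)
      y[["Cex"]] <- schedule_conc(trz_schedule, segs[i + 1])
  }
  sol <- do.call(rbind, rows)
  sol <- sol[!duplicated(sol[, "time"]), , drop = FALSE]

  f_inj <- sol[, "f_inj_1"] + sol[, "f_inj_2"] + sol[, "f_inj_3"]
  Cin <- pmax(sol[, "Cin"], 0)
  E <- pmax(sol[, "E"], .Machine$double.xmin)
  acf_abs <- acf_force(pmax(sol[, "ATP"], 0) , Cin, E, p)$ACF
  acf0 <- acf_force(ATP0_ss, 0, 1, p)$ACF
  out <- data.frame(
    time = sol[, "time"],
    f_nor = sol[, "f_nor"],
    f_inj = f_inj,
    f_dead = sol[, "f_dead"],
    survival_fraction = survival_fraction(sol[, "f_nor"], f_inj, sol[, "f_dead"]),
    ATP = sol[, "ATP"] / ATP0_ss,
    MMP = sol[, "MMP"] / MMP0_ss,
    ACF = acf_abs / acf0,
    E_DOX_TRZ = sol[, "E"],
    C_in_DOX = free_intracellular_dox(pmax(sol[, "Ct"], 0), dox_params),
    C_in_TRZ = Cin,
    C_in_total = sol[, "Ct"],
    f_inj_1 = sol[, "f_inj_1"], f_inj_2 = sol[, "f_inj_2"],
    f_inj_3 = sol[, "f_inj_3"])
  rownames(out) <- NULL
  class(out) <- c("td_trajectory", "data.frame")
  out
}

#' Export a TD trajectory as CSV
#'
#' @param trajectory a `td_trajectory` from [simulate_td()].
#' @param path output file.
#' @export
write_td_trajectory <- function(trajectory, path) {
  cols <- c("time", "f_nor", "f_inj", "f_dead", "survival_fraction",
            "ATP", "MMP", "ACF", "E_DOX_TRZ", "C_in_DOX", "C_in_TRZ")
  utils::write.csv(as.data.frame(trajectory)[, cols], path, row.names = FALSE)
  invisible(path)
}
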