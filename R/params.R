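#' Toxicodynamic model parameters
#'
#' Constructs the full parameter set of the cardiomyocyte toxicodynamic (TD)
#' model: the injury/death transit chain, ATP/MMP bioenergetics and
#' chemo-mechanical energy transduction.
#'
#' Two published estimates ship as presets (see [td_preset()]): a
#' doxorubicin-only fit and a doxorubicin-trastuzumab interaction fit. Fixed
#' structural constants are tied by baseline constraints rather than fitted:
#' `MMP0 = 1` and `Emax_kinMMP = 1`; the elimination constants default to
#' `k_out_ATP = k_in_ATP` and `k_out_MMP = k_in_MMP` so that drug-free ATP and
#' MMP stay at their normalized baseline of 1; and `ACF_max = 1 + ATP50_ref`
#' so that baseline contractile force is 1.
#'
#' @param k_inj injury rate constant, 1/(h*umol/L): fraction of normal
#'   myocytes injured per hour per unit free intracellular doxorubicin.
#' @param tau transit time of each of the three injured-cell compartments (h).
#' @param EC50_kinMMP free intracellular doxorubicin concentration giving
#'   half-maximal inhibition of MMP production (umol/L).
#' @param Emax_kinMMP maximal fractional inhibition of MMP production
#'   (dimensionless, fixed at 1 by convention).
#' @param k_in_MMP zero-order MMP production rate (1/h).
#' @param k_out_MMP first-order MMP loss rate (1/h); default `k_in_MMP`.
#' @param k_in_ATP zero-order ATP production rate (1/h).
#' @param k_out_ATP first-order ATP loss rate (1/h); default `k_in_ATP`.
#' @param n exponent of the stimulatory effect of MMP on ATP production.
#' @param Emax_kinATP maximal fractional inhibition of ATP production by
#'   trastuzumab (dimensionless, in (0, 1]).
#' @param EC50_kinATP internalized trastuzumab concentration giving
#'   half-maximal inhibition of ATP production (nmol/L).
#' @param k_TRZ_ATP50 linear coefficient of internalized trastuzumab on the
#'   half-maximal ATP level of the force model (1/(nmol/L)).
#' @param k_e rate constant of the doxorubicin enhancement of trastuzumab's
#'   effect on ATP50, 1/(h*umol/L).
#' @param MMP0 baseline MMP level (fixed at 1).
#' @param ATP50_ref drug-free ATP level giving half-maximal contractile force
#'   (normalized units).
#' @param ACF_max maximal average contractile force (normalized units);
#'   default `1 + ATP50_ref` so that force is 1 at baseline ATP = 1.
#' @return An object of class `td_parameters` (named numeric vector).
#' @seealso [td_preset()], [simulate_td()], [td_derivatives()]
#' @export
td_parameters <- function(k_inj, tau, EC50_kinMMP,
                          Emax_kinMMP = 1,
                          k_in_MMP = 0.96, k_out_MMP = k_in_MMP,
                          k_in_ATP = 0.032, k_out_ATP = k_in_ATP,
                          n = 0.8,
                          Emax_kinATP = 0.54, EC50_kinATP = 30.11,
                          k_TRZ_ATP50 = 0.013, k_e = 9.94,
                          MMP0 = 1, ATP50_ref = 0.5,
                          ACF_max = 1 + ATP50_ref) {
  p <- c(k_inj = k_inj, tau = tau, EC50_kinMMP = EC50_kinMMP,
         Emax_kinMMP = Emax_kinMMP,
         k_in_MMP = k_in_MMP, k_out_MMP = k_out_MMP,
         k_in_ATP = k_in_ATP, k_out_ATP = k_out_ATP,
         n = n, Emax_kinATP = Emax_kinATP, EC50_kinATP = EC50_kinATP,
         k_TRZ_ATP50 = k_TRZ_ATP50, k_e = k_e,
         MMP0 = MMP0, ACF_max = ACF_max, ATP50_ref = ATP50_ref)
  validate_td_parameters(p)
  structure(p, class = c("td_parameters", "numeric"))
}

validate_td_parameters <- function(p) {
  if (any(!is.finite(p))) stop("td_parameters: all values must be finite")
  if (any(p <= 0)) {
    bad <- names(p)[p <= 0]
    stop("td_parameters: values must be strictly positive: ",
         paste(bad, collapse = ", "))
  }
  if (p[["Emax_kinATP"]] > 1) stop("td_parameters: Emax_kinATP must be in (0, 1]")
  invisible(p)
}

#' Published TD parameter presets
#'
#' Named presets of the toxicodynamic parameters: `"dox_only"` (estimated from
#' the doxorubicin exposure-duration panel) and `"interaction"` (estimated
#' jointly from doxorubicin-trastuzumab interaction data; the default for
#' combined simulations). Relative standard errors of the estimates are
#' attached as attribute `"rse_pct"` and are also the default inter-individual
#' coefficients of variation of the virtual-trial engine.
#'
#' @param name `"interaction"` (default) or `"dox_only"`.
#' @return A `td_parameters` object.
#' @export
td_preset <- function(name = c("interaction", "dox_only")) {
  name <- match.arg(name)
  if (name == "dox_only") {
    p <- td_parameters(k_inj = 0.0023, tau = 1.38, EC50_kinMMP = 0.36)
    rse <- c(k_inj = 20.6, tau = 17.9, EC50_kinMMP = 18.4,
             k_in_ATP = 4.09, k_in_MMP = 38.7, n = 8.98)
  } else {
    p <- td_parameters(k_inj = 0.0035, tau = 4.9, EC50_kinMMP = 1.87)
    rse <- c(k_inj = 8.47, tau = 7.86, EC50_kinMMP = 24.8,
             Emax_kinATP = 22.1, EC50_kinATP = 25.3,
             k_TRZ_ATP50 = 14.8, k_e = 11.2,
             k_in_ATP = 4.09, k_in_MMP = 38.7, n = 8.98)
  }
  attr(p, "preset") <- name
  attr(p, "rse_pct") <- rse
  p
}

#' Doxorubicin cellular exposure parameters
#'
#' Membrane-transport and DNA-binding constants of the cellular doxorubicin
#' disposition model. Defaults other than `CN` are placeholder,
#' literature-sourced and configurable; they are chosen so that free
#' intracellular drug approaches its partition equilibrium within a typical
#' exposure window while total intracellular drug is strongly buffered by DNA
#' binding. `CN` defaults to the published estimate 7.21e4 umol/L.
#'
#' @param V_cell cell volume (L).
#' @param PER membrane permeability (cm/h).
#' @param S_cell membrane surface area per cell (cm^2).
#' @param k_pp unbound intracellular/extracellular partition ratio.
#' @param CN concentration of DNA-binding domains (umol/L).
#' @param k_d drug-DNA equilibrium dissociation constant (umol/L).
#' @return An object of class `dox_cellular_params`. The derived first-order
#'   influx constant `PER*S_cell/V_cell` (1/h) is attached as attribute
#'   `"k_flux"`.
#' @export
dox_cellular_params <- function(V_cell = 4e-12, PER = 0.16,
                                S_cell = 1.5e-5, k_pp = 1.3,
                                CN = 7.21e4, k_d = 0.5) {
  p <- c(V_cell = V_cell, PER = PER, S_cell = S_cell,
         k_pp = k_pp, CN = CN, k_d = k_d)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("dox_cellular_params: all values must be finite and strictly positive")
  # V_cell in L -> cm^3 for the permeability product
  attr(p, "k_flux") <- PER * S_cell / (V_cell * 1000)
  structure(p, class = c("dox_cellular_params", "numeric"))
}

#' Trastuzumab cellular kinetics parameters
#'
#' Binding, internalization and turnover constants of trastuzumab at the
#' cardiomyocyte surface. All defaults are placeholder, literature-sourced and
#' configurable. `Ag_cell` is the total surface-antigen (ErbB-2) concentration
#' referenced to the medium volume; [ag_cell_concentration()] converts
#' per-cell receptor counts at a given seeding density to this scale.
#'
#' @param k_on association rate constant (1/((nmol/L)*h)).
#' @param k_off dissociation rate constant (1/h).
#' @param k_int internalization rate of the bound complex (1/h).
#' @param k_deg endosomal degradation rate of internalized drug (1/h).
#' @param k_dec non-specific extracellular deconjugation rate (1/h).
#' @param Ag_cell total surface-antigen concentration, medium-referenced
#'   (nmol/L).
#' @return An object of class `trz_cellular_params`.
#' @export
trz_cellular_params <- function(k_on = 2.56, k_off = 1.28,
                                k_int = 0.12, k_deg = 0.03,
                                k_dec = 0.001, Ag_cell = 10) {
  p <- c(k_on = k_on, k_off = k_off, k_int = k_int,
         k_deg = k_deg, k_dec = k_dec, Ag_cell = Ag_cell)
  if (any(!is.finite(p)) || any(p < 0))
    stop("trz_cellular_params: all values must be finite and nonnegative")
  if (k_on <= 0) stop("trz_cellular_params: k_on must be > 0")
  structure(p, class = c("trz_cellular_params", "numeric"))
}

#' Convert per-cell receptor counts to a medium-referenced concentration
#'
#' @param receptors_per_cell surface receptors per cardiomyocyte.
#' @param cells_per_well seeded cells per well (default 2e5).
#' @param medium_volume_mL culture medium volume per well (mL).
#' @return Antigen concentration in nmol/L of medium.
#' @export
ag_cell_concentration <- function(receptors_per_cell,
                                  cells_per_well = 2e5,
                                  medium_volume_mL = 0.5) {
  avogadro <- 6.02214076e23
  mol <- receptors_per_cell * cells_per_well / avogadro
  mol / (medium_volume_mL * 1e-3) * 1e9
}

#' Molar/mass unit conversion for drug concentrations
#'
#' @param x concentration values.
#' @param from,to units among `"umol/L"`, `"nmol/L"`, `"ug/mL"`.
#' @param mw molecular mass (g/mol); defaults: doxorubicin 543.5 for
#'   micromolar scales, trastuzumab 1.48e5 for nanomolar scales must be given
#'   explicitly via `mw`.
#' @return Converted values.
#' @export
convert_conc <- function(x, from, to, mw) {
  units <- c("umol/L", "nmol/L", "ug/mL")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (from == to) return(x)
  # to umol/L first
  xu <- switch(from,
    "umol/L" = x,
    "nmol/L" = x / 1000,
    "ug/mL" = x / mw * 1000)
  switch(to,
    "umol/L" = xu,
    "nmol/L" = xu * 1000,
    "ug/mL" = xu * mw / 1000)
}

# canonical ordering used by the compiled engines
.td_par_order <- c("k_inj", "tau", "EC50_kinMMP", "Emax_kinMMP",
                   "k_in_MMP", "k_out_MMP", "k_in_ATP", "k_out_ATP",
                   "n", "Emax_kinATP", "EC50_kinATP", "k_TRZ_ATP50",
                   "k_e", "MMP0", "ACF_max", "ATP50_ref")

.dox_par_order <- c("k_flux", "k_pp", "CN", "k_d")
.trz_par_order <- c("k_on", "k_off", "k_int", "k_deg", "k_dec", "Ag_cell")

td_par_vector <- function(p) {
  unname(as.numeric(p)[match(.td_par_order, names(p))])
}

dox_par_vector <- function(p) {
  c(attr(p, "k_flux"), p[["k_pp"]], p[["CN"]], p[["k_d"]])
}

trz_par_vector <- function(p) {
  unname(as.numeric(p)[match(.trz_par_order, names(p))])
}

#' @export
print.td_parameters <- function(x, ...) {
  cat("<td_parameters>")
  if (!is.null(attr(x, "preset"))) cat(" preset:", attr(x, "preset"))
  cat("\n")
  print(round(unclass(x), 6))
  invisible(x)
}
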