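#' Fast fixed-step simulation of in-vitro design arms
#'
#' Simulates many single-window exposure arms (the building block of the
#' experimental designs) with the compiled fixed-step engine: exponential
#' updates for all linear sub-systems and an RK4 substep for the nonlinear
#' doxorubicin uptake. This is the engine behind the synthetic-data generator
#' and the calibration objective; the adaptive-solver path ([simulate_td()])
#' is the reference it is cross-checked against.
#'
#' @param arms data.frame with one row per arm and columns `arm` (id),
#'   `dox_start`, `dox_end`, `dox_conc` (umol/L), `trz_start`, `trz_end`,
#'   `trz_conc` (nmol/L). A concentration of 0 disables the drug.
#' @param times output times (h), increasing, starting at 0.
#' @param td_params,dox_params,trz_params parameter objects.
#' @param dt base step size (h).
#' @param clamp_trz reservoir assumption for the trastuzumab medium.
#' @return Named list of `n_arms x n_times` matrices: `SF`, `ACF`, `ATP`,
#'   `MMP`, `E_DOX_TRZ`, `C_in_DOX`, `C_in_TRZ`, `f_nor` (ATP, MMP, ACF
#'   normalized to baseline).
#' @export
simulate_invitro_arms <- function(arms, times,
                                  td_params = td_preset("interaction"),
                                  dox_params = dox_cellular_params(),
                                  trz_params = trz_cellular_params(),
                                  dt = 0.05, clamp_trz = FALSE) {
  need <- c("dox_start", "dox_end", "dox_conc",
            "trz_start", "trz_end", "trz_conc")
  if (!all(need %in% names(arms)))
    stop("simulate_invitro_arms: arms needs columns ", paste(need, collapse = ", "))
  stopifnot(!is.unsorted(times, strictly = TRUE), times[1] >= 0)
  m <- as.matrix(arms[, need])
  storage.mode(m) <- "double"
  res <- cpp_invitro_sim(td_par_vector(td_params),
                         dox_par_vector(dox_params),
                         trz_par_vector(trz_params),
                         m, as.numeric(times), dt, clamp_trz)
  layers <- c("SF", "ACF", "ATP", "MMP", "E_DOX_TRZ",
              "C_in_DOX", "C_in_TRZ", "f_nor")
  out <- stats::setNames(vector("list", length(layers)), layers)
  dn <- list(if ("arm" %in% names(arms)) as.character(arms$arm) else
               as.character(seq_len(nrow(arms))),
             as.character(times))
  for (k in seq_along(layers)) {
    mat <- res[, , k, drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(arms))
    dimnames(mat) <- dn
    out[[k]] <- mat
  }
  out
}
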