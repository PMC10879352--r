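#' Default inter-individual coefficient-of-variation table
#'
#' Lognormal CVs (as fractions) used by the Monte-Carlo patient generator.
#' The toxicodynamic individual-dependent parameters default to the relative
#' standard errors of the interaction-fit estimates (the only dispersions the
#' calibration reports); pharmacokinetic scalars default to 30%; physiology
#' CVs are set so that the default population composition matches the
#' virtual-trial cohorts the platform was validated against (roughly 37%
#' comorbid, and ~0.4% of patients excluded for baseline LVEF below 50%).
#'
#' @return Named numeric vector of CVs.
#' @export
default_cv_table <- function() {
  c(k_inj = 0.0847, tau = 0.0786, EC50_kinMMP = 0.248,
    Emax_kinATP = 0.221, EC50_kinATP = 0.253, k_TRZ_ATP50 = 0.148,
    k_e = 0.112,
    CL_dox = 0.30, V1_dox = 0.30, V2_dox = 0.30, Q_dox = 0.30,
    access_dox = 0.30,
    CL_trz = 0.30, V1_trz = 0.30, V2_trz = 0.30, Q_trz = 0.30,
    access_trz = 0.30,
    weight = 0.20, BSA = 0.11, MAP = 0.15, LVEDV = 0.30, EF0 = 0.08)
}

# median physiology of the virtual population
default_physiology <- function() {
  c(weight = 70, BSA = 1.79, MAP = 95, LVEDV = 125, EF0 = 62)
}

.sampled_par_order <- names(default_cv_table())

#' Generate a virtual-patient cohort by Monte-Carlo sampling
#'
#' Samples positive parameters lognormally around their medians with the
#' given CVs. Each patient draws from its own L'Ecuyer-CMRG substream
#' derived from the master seed, so cohorts are reproducible and enlarging a
#' cohort never perturbs already-generated patients. Patients with baseline
#' LVEF below 50% are flagged as not included (screening criterion) but kept
#' in the table.
#'
#' @param n number of patients to generate.
#' @param seed master integer seed.
#' @param cv_table named CV vector, see [default_cv_table()]; CVs of 0 give
#'   point values at the medians.
#' @param td_params median individual-dependent TD parameters
#'   (default interaction preset).
#' @param pbpk_dox,pbpk_trz median disposition parameters.
#' @param physiology named medians (`weight`, `BSA`, `MAP`, `LVEDV`, `EF0`).
#' @param gain,ceiling,tau_comp,comorbid_penalty,r_access cardiac-response
#'   constants applied to every patient (comorbid penalty applied where the
#'   sampled physiology meets the comorbidity cutoffs MAP >= 115 mmHg or
#'   LVEDV >= 146 mL).
#' @return A `virtual_cohort` data.frame, one row per patient.
#' @export
sample_patients <- function(n, seed = 1, cv_table = default_cv_table(),
                            td_params = td_preset("interaction"),
                            pbpk_dox = pbpk_params("dox"),
                            pbpk_trz = pbpk_params("trz"),
                            physiology = default_physiology(),
                            gain = 1, ceiling = 1.2, tau_comp = 96,
                            comorbid_penalty = 0.5, r_access = 0.12) {
  if (n <= 0) stop("sample_patients: n must be > 0")
  cv <- default_cv_table()
  cv[names(cv_table)] <- cv_table
  if (any(cv < 0) || any(is.na(cv)))
    stop("sample_patients: invalid CV (must be >= 0): ",
         paste(names(cv)[is.na(cv) | cv < 0], collapse = ", "))

  med <- c(unclass(td_params)[c("k_inj", "tau", "EC50_kinMMP", "Emax_kinATP",
                                "EC50_kinATP", "k_TRZ_ATP50", "k_e")],
           CL_dox = pbpk_dox$CL, V1_dox = pbpk_dox$V1, V2_dox = pbpk_dox$V2,
           Q_dox = pbpk_dox$Q, access_dox = pbpk_dox$access,
           CL_trz = pbpk_trz$CL, V1_trz = pbpk_trz$V1, V2_trz = pbpk_trz$V2,
           Q_trz = pbpk_trz$Q, access_trz = pbpk_trz$access,
           physiology[c("weight", "BSA", "MAP", "LVEDV", "EF0")])
  med <- med[.sampled_par_order]
  sdlog <- sqrt(log(1 + cv[.sampled_par_order]^2))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kind[1:2]))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)

  RNGkind("L'Ecuyer-CMRG")
  set.seed(as.integer(seed))
  s <- get(".Random.seed", envir = globalenv())
  k <- length(med)
  z <- matrix(0, n, k)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    assign(".Random.seed", s, envir = globalenv())
    z[i, ] <- stats::rnorm(k)
  }
  x <- sweep(exp(sweep(z, 2, sdlog, `*`)), 2, med, `*`)
  colnames(x) <- .sampled_par_order
  x <- as.data.frame(x)
  x$Emax_kinATP <- pmin(x$Emax_kinATP, 0.999)

  comorbid <- x$MAP >= 115 | x$LVEDV >= 146
  pen <- ifelse(comorbid, comorbid_penalty, 1)
  out <- cbind(
    data.frame(id = seq_len(n)),
    x,
    data.frame(
      SV0 = x$EF0 / 100 * x$LVEDV,
      baseline_lvef = x$EF0,
      comorbid = comorbid,
      gain = gain * pen,
      ceiling = 1 + (ceiling - 1) * pen,
      tau_comp = tau_comp,
      r_access = r_access,
      included = x$EF0 >= 50))
  class(out) <- c("virtual_cohort", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat("<virtual_cohort>", nrow(x), "patients;",
      sum(x$included), "included (baseline LVEF >= 50%);",
      sum(x$comorbid), "comorbid\n")
  invisible(x)
}
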