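#' Virtual-trial specification
#'
#' @param regimen a preset name (`"TRZ"`, `"DOX_then_TRZ"`, `"DOX_plus_TRZ"`,
#'   `"DOX"`) or a [regimen()] object.
#' @param n patients to generate (before screening).
#' @param seed master seed (cohort sampling and bootstrap).
#' @param horizon_weeks follow-up horizon; defaults: 64 weeks for
#'   trastuzumab-containing presets, 52 weeks after the first dose otherwise.
#' @param classifier_mode see [classify_systolic_dysfunction()].
#' @param cv_table inter-individual CVs, see [default_cv_table()].
#' @param cum_dose cumulative dose (mg/m2) when `regimen = "DOX"`.
#' @param dt engine step (h).
#' @param bootstrap_n bootstrap resamples for incidence CIs.
#' @return A `trial_spec` object.
#' @export
trial_spec <- function(regimen = "TRZ", n = 6000, seed = 1,
                       horizon_weeks = NULL,
                       classifier_mode = c("point_drop_or_absolute50",
                                           "relative"),
                       cv_table = default_cv_table(),
                       cum_dose = 240, dt = 0.5, bootstrap_n = 200) {
  classifier_mode <- match.arg(classifier_mode)
  if (n <= 0) stop("trial_spec: n must be > 0")
  reg <- if (inherits(regimen, "regimen")) regimen
         else regimen_preset(regimen, cum_dose = cum_dose)
  name <- if (is.character(regimen)) regimen else attr(regimen, "preset") %||% "custom"
  if (is.null(horizon_weeks)) {
    horizon_weeks <- if (any(reg$events$drug == "trz")) 64
      else if (nrow(reg$events)) max(reg$events$time_week) + 52 -
        min(reg$events$time_week) else 52
  }
  if (nrow(reg$events) && horizon_weeks < max(reg$events$time_week))
    stop("trial_spec: horizon shorter than the regimen")
  structure(list(regimen = reg, regimen_name = name, n = n, seed = seed,
                 horizon_weeks = horizon_weeks,
                 classifier_mode = classifier_mode,
                 cv_table = cv_table, dt = dt, bootstrap_n = bootstrap_n),
            class = "trial_spec")
}

# Run the compiled cohort engine for a set of (included) patients.
# td_ind_scale / td_sys_scale: named multiplicative perturbations
# (sensitivity analysis).
run_cohort <- function(patients, reg, horizon_weeks, dt, mode,
                       td_params = td_preset("interaction"),
                       dox_params = dox_cellular_params(),
                       trz_params = trz_cellular_params(),
                       td_ind_scale = NULL, td_sys_scale = NULL) {
  n <- nrow(patients)
  ind_cols <- c("k_inj", "tau", "EC50_kinMMP", "Emax_kinATP",
                "EC50_kinATP", "k_TRZ_ATP50", "k_e")
  td_ind <- as.matrix(patients[, ind_cols])
  if (!is.null(td_ind_scale))
    for (nm in names(td_ind_scale))
      td_ind[, nm] <- td_ind[, nm] * td_ind_scale[[nm]]

  p <- unclass(td_params)
  sys <- c(p[["Emax_kinMMP"]], p[["k_in_MMP"]], p[["k_out_MMP"]],
           p[["k_in_ATP"]], p[["k_out_ATP"]], p[["n"]],
           p[["MMP0"]], p[["ACF_max"]], p[["ATP50_ref"]])
  names(sys) <- c("Emax_kinMMP", "k_in_MMP", "k_out_MMP", "k_in_ATP",
                  "k_out_ATP", "n", "MMP0", "ACF_max", "ATP50_ref")
  if (!is.null(td_sys_scale))
    for (nm in names(td_sys_scale))
      sys[[nm]] <- sys[[nm]] * td_sys_scale[[nm]]

  modal <- function(CL, V1, V2, Q) {
    k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
    s <- k10 + k12 + k21
    disc <- sqrt(s * s - 4 * k10 * k21)
    l1 <- (s + disc) / 2; l2 <- (s - disc) / 2
    cbind(l1, l2,
          B1 = (k21 - l1) / (l2 - l1) / V1,
          B2 = (k21 - l2) / (l1 - l2) / V1)
  }
  pk <- cbind(modal(patients$CL_dox, patients$V1_dox, patients$V2_dox,
                    patients$Q_dox),
              modal(patients$CL_trz, patients$V1_trz, patients$V2_trz,
                    patients$Q_trz))
  access <- cbind(patients$access_dox, patients$access_trz)
  qsp <- cbind(patients$SV0, patients$LVEDV, patients$ceiling,
               patients$gain, patients$tau_comp, patients$r_access)

  inp <- regimen_engine_inputs(reg, patients$weight, patients$BSA)
  trz_t0 <- if (nrow(inp$trz$ev)) min(inp$trz$ev[, 1]) else -1
  t_precut <- if (trz_t0 > 0) trz_t0 else -1

  res <- cpp_cohort_sim(
    td_ind, sys,
    dox_par_vector(dox_params), trz_par_vector(trz_params),
    pk, access,
    inp$dox$ev, inp$dox$rate, inp$trz$ev, inp$trz$rate,
    qsp, horizon_weeks * 168, dt, t_precut,
    if (mode == "point_drop_or_absolute50") 0L else 1L,
    -1L)
  res$onset_h[res$onset_h < 0] <- NA_real_
  res$t_precut <- t_precut
  res
}

boot_ci <- function(x, B, seed) {
  if (!length(x)) return(c(lo = NA_real_, hi = NA_real_))
  set.seed(as.integer(seed))
  n <- length(x)
  draws <- vapply(seq_len(B),
                  function(b) mean(x[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  stats::quantile(draws, c(0.025, 0.975), names = FALSE) * 100 ->
    q
  c(lo = q[1], hi = q[2])
}

#' Run a virtual-patient trial
#'
#' Samples the cohort, screens out patients with baseline LVEF below 50%,
#' simulates every included patient through the exposure, toxicodynamic and
#' cardiac-response chain, applies the pre-trastuzumab dysfunction exclusion
#' where the regimen administers trastuzumab after time zero, and reports
#' systolic-dysfunction incidence overall and by cardiovascular subgroup
#' with seeded bootstrap confidence intervals.
#'
#' @param spec a [trial_spec()].
#' @param cohort optionally, a pre-sampled `virtual_cohort` (shared across
#'   trials for variance reduction); defaults to sampling from `spec`.
#' @param td_ind_scale,td_sys_scale named multiplicative parameter
#'   perturbations (used by [sensitivity_analysis()]).
#' @return A `trial_result`: counts, incidence table (`overall`, `normal`,
#'   `comorbid`), and the per-patient outcome table.
#' @export
run_trial <- function(spec, cohort = NULL,
                      td_ind_scale = NULL, td_sys_scale = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  if (is.null(cohort)) cohort <- sample_patients(spec$n, spec$seed,
                                                 spec$cv_table)
  pts <- cohort[cohort$included, , drop = FALSE]
  n_gen <- nrow(cohort)
  n_base_excl <- n_gen - nrow(pts)

  res <- run_cohort(pts, spec$regimen, spec$horizon_weeks, spec$dt,
                    spec$classifier_mode,
                    td_ind_scale = td_ind_scale, td_sys_scale = td_sys_scale)

  pre_excl <- res$dysfunction_pre == 1
  keep <- !pre_excl
  out <- data.frame(id = pts$id,
                    comorbid = pts$comorbid,
                    baseline_lvef = res$baseline_lvef,
                    min_lvef = res$min_lvef,
                    dysfunction = res$dysfunction == 1,
                    onset_week = res$onset_h / 168,
                    excluded_pre_trz = pre_excl)
  inc_row <- function(sel, label) {
    d <- out$dysfunction[sel & keep]
    ci <- boot_ci(d, spec$bootstrap_n, spec$seed + 7777)
    data.frame(subgroup = label, n = sum(sel & keep), n_dysfunction = sum(d),
               incidence_pct = if (length(d)) mean(d) * 100 else NA_real_,
               ci_lo = ci[["lo"]], ci_hi = ci[["hi"]])
  }
  tab <- rbind(inc_row(rep(TRUE, nrow(out)), "overall"),
               inc_row(!out$comorbid, "normal"),
               inc_row(out$comorbid, "comorbid"))
  structure(list(
    regimen = spec$regimen_name,
    n_generated = n_gen,
    n_included = sum(keep),
    n_excluded_baseline = n_base_excl,
    n_excluded_pre_TRZ = sum(pre_excl),
    incidence = tab,
    patients = out,
    spec = spec),
    class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result>", x$regimen, "-", x$n_included, "patients analysed (",
      x$n_excluded_baseline, "screened out,", x$n_excluded_pre_TRZ,
      "excluded pre-trastuzumab )\n")
  print(transform(x$incidence,
                  incidence_pct = round(incidence_pct, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3)))
  invisible(x)
}

#' Doxorubicin cumulative dose-response of dysfunction incidence
#'
#' One virtual trial per cumulative dose (60 mg/m2 units), on a single
#' shared cohort for variance reduction.
#'
#' @param doses cumulative doses (mg/m2), each a multiple of 60.
#' @param spec a [trial_spec()] (its regimen is ignored).
#' @return data.frame with per-dose overall and subgroup incidences and CIs.
#' @export
dose_response_curve <- function(doses = seq(60, 960, by = 60), spec) {
  if (any(doses %% 60 != 0) || any(doses < 0))
    stop("dose_response_curve: doses must be nonnegative multiples of 60")
  cohort <- sample_patients(spec$n, spec$seed, spec$cv_table)
  rows <- lapply(doses, function(d) {
    sp <- spec
    sp$regimen <- regimen_preset("DOX", cum_dose = d)
    sp$regimen_name <- sprintf("DOX_%d", d)
    sp$horizon_weeks <- max((d / 60 - 1) * 3, 0) + 52
    tr <- run_trial(sp, cohort = cohort)
    i <- tr$incidence
    data.frame(cum_dose = d,
               incidence_pct = i$incidence_pct[i$subgroup == "overall"],
               ci_lo = i$ci_lo[i$subgroup == "overall"],
               ci_hi = i$ci_hi[i$subgroup == "overall"],
               normal_pct = i$incidence_pct[i$subgroup == "normal"],
               comorbid_pct = i$incidence_pct[i$subgroup == "comorbid"])
  })
  do.call(rbind, rows)
}

#' Local sensitivity analysis of dysfunction incidence
#'
#' Perturbs each toxicodynamic parameter multiplicatively on the same cohort
#' and seed, reruns the trial, and reports the normalized sensitivity
#' `(p / Incidence) * (dIncidence / dp)`, evaluated against the unperturbed
#' trial.
#'
#' @param spec a [trial_spec()] (typically the sequential regimen).
#' @param parameters parameter names among the individual-dependent
#'   (`k_inj`, `tau`, `EC50_kinMMP`, `Emax_kinATP`, `EC50_kinATP`,
#'   `k_TRZ_ATP50`, `k_e`) and system-dependent (`k_in_ATP`, `k_in_MMP`,
#'   `n`) sets.
#' @param folds multiplicative perturbations, within `[1/3, 3]`.
#' @return data.frame `parameter`, `fold`, `incidence_pct`, `sensitivity`;
#'   baseline incidence attached as attribute `"baseline_incidence_pct"`.
#' @export
sensitivity_analysis <- function(spec,
                                 parameters = c("k_inj", "tau", "EC50_kinMMP",
                                                "Emax_kinATP", "EC50_kinATP",
                                                "k_TRZ_ATP50", "k_e",
                                                "k_in_ATP", "k_in_MMP", "n"),
                                 folds = c(1 / 3, 3)) {
  ind <- c("k_inj", "tau", "EC50_kinMMP", "Emax_kinATP", "EC50_kinATP",
           "k_TRZ_ATP50", "k_e")
  sys <- c("k_in_ATP", "k_in_MMP", "n")
  bad <- setdiff(parameters, c(ind, sys))
  if (length(bad)) stop("sensitivity_analysis: unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  if (any(folds < 1 / 3 - 1e-9) || any(folds > 3 + 1e-9))
    stop("sensitivity_analysis: folds must lie in [1/3, 3]")
  cohort <- sample_patients(spec$n, spec$seed, spec$cv_table)
  base <- run_trial(spec, cohort = cohort)
  I0 <- base$incidence$incidence_pct[base$incidence$subgroup == "overall"]
  if (is.na(I0) || I0 == 0)
    warning("sensitivity_analysis: baseline incidence is zero; ",
            "sensitivities are undefined (reported as NA)")
  rows <- list(); k <- 0
  for (p in parameters) {
    for (f in folds) {
      tr <- if (p %in% ind)
        run_trial(spec, cohort = cohort,
                  td_ind_scale = stats::setNames(list(f), p))
      else
        run_trial(spec, cohort = cohort,
                  td_sys_scale = stats::setNames(list(f), p))
      Ii <- tr$incidence$incidence_pct[tr$incidence$subgroup == "overall"]
      sens <- if (is.na(I0) || I0 == 0) NA_real_
              else (Ii - I0) / I0 / (f - 1)
      k <- k + 1
      rows[[k]] <- data.frame(parameter = p, fold = f,
                              incidence_pct = Ii, sensitivity = sens)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline_incidence_pct") <- I0
  out
}

#' Simulate a single virtual patient's LVEF trajectory
#'
#' Runs one patient through the full exposure / toxicodynamic /
#' cardiac-response chain and returns the time course (useful for
#' diagnostics and for cross-checking the cohort engine).
#'
#' @param patient one row of a `virtual_cohort` (data.frame).
#' @param reg a [regimen()] or preset name.
#' @param horizon_weeks follow-up horizon.
#' @param dt engine step (h).
#' @return data.frame time course: `time_h`, `LVEF`, `E_drug`,
#'   `survival_fraction`, `ACF`, `ATP`, `C_in_DOX`, `C_in_TRZ`,
#'   `E_DOX_TRZ`, `comp`.
#' @export
simulate_patient <- function(patient, reg = "DOX_then_TRZ",
                             horizon_weeks = 64, dt = 0.5) {
  if (is.character(reg)) reg <- regimen_preset(reg)
  ind_cols <- c("k_inj", "tau", "EC50_kinMMP", "Emax_kinATP",
                "EC50_kinATP", "k_TRZ_ATP50", "k_e")
  p <- unclass(td_preset("interaction"))
  sys <- c(p[["Emax_kinMMP"]], p[["k_in_MMP"]], p[["k_out_MMP"]],
           p[["k_in_ATP"]], p[["k_out_ATP"]], p[["n"]],
           p[["MMP0"]], p[["ACF_max"]], p[["ATP50_ref"]])
  modal <- function(CL, V1, V2, Q) {
    k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
    s <- k10 + k12 + k21
    disc <- sqrt(s * s - 4 * k10 * k21)
    l1 <- (s + disc) / 2; l2 <- (s - disc) / 2
    cbind(l1, l2, (k21 - l1) / (l2 - l1) / V1, (k21 - l2) / (l1 - l2) / V1)
  }
  pk <- cbind(modal(patient$CL_dox, patient$V1_dox, patient$V2_dox,
                    patient$Q_dox),
              modal(patient$CL_trz, patient$V1_trz, patient$V2_trz,
                    patient$Q_trz))
  inp <- regimen_engine_inputs(reg, patient$weight, patient$BSA)
  trz_t0 <- if (nrow(inp$trz$ev)) min(inp$trz$ev[, 1]) else -1
  out <- cpp_cohort_sim(
    as.matrix(patient[, ind_cols]), sys,
    dox_par_vector(dox_cellular_params()),
    trz_par_vector(trz_cellular_params()),
    pk, cbind(patient$access_dox, patient$access_trz),
    inp$dox$ev, inp$dox$rate, inp$trz$ev, inp$trz$rate,
    cbind(patient$SV0, patient$LVEDV, patient$ceiling, patient$gain,
          patient$tau_comp, patient$r_access),
    horizon_weeks * 168, dt, if (trz_t0 > 0) trz_t0 else -1, 0L, 0L)
  as.data.frame(out$trajectory)
}
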