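#' @useDynLib ctqsp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Parameters that may be estimated. "CN" lives in the cellular exposure layer;
# all others in td_parameters. k_out_ATP / k_out_MMP are tied to their k_in
# by the baseline steady-state constraint and are never fitted.
.stage1_params <- c("k_in_ATP", "k_in_MMP", "CN", "n",
                    "k_inj", "tau", "EC50_kinMMP")
.stage2_params <- c(.stage1_params,
                    "Emax_kinATP", "EC50_kinATP", "k_TRZ_ATP50", "k_e")

# apply a named natural-scale parameter vector onto (td, dox) parameter sets
apply_fit_params <- function(theta, td, dox) {
  td <- unclass(td)
  for (nm in names(theta)) {
    if (nm == "CN") next
    td[[nm]] <- theta[[nm]]
  }
  td[["k_out_ATP"]] <- td[["k_in_ATP"]]
  td[["k_out_MMP"]] <- td[["k_in_MMP"]]
  if ("CN" %in% names(theta)) {
    dox <- dox_cellular_params(V_cell = dox[["V_cell"]], PER = dox[["PER"]],
                               S_cell = dox[["S_cell"]], k_pp = dox[["k_pp"]],
                               CN = theta[["CN"]], k_d = dox[["k_d"]])
  }
  list(td = structure(td, class = c("td_parameters", "numeric")), dox = dox)
}

# Precompute the observation index against the design/simulation layout.
# `loq`: limit of quantification on the normalized scale; both observations
# and predictions are floored at it, so fully collapsed signals (below assay
# resolution) contribute no spurious log-scale residuals.
build_fit_data <- function(dataset, drop_t0 = TRUE, loq = 1e-3) {
  design <- dataset$design
  d <- dataset$data
  if (drop_t0) d <- d[d$time_h > 0, , drop = FALSE]
  times <- sort(unique(c(0, dataset$data$time_h)))
  arm_idx <- match(d$arm, design$arm)
  time_idx <- match(d$time_h, times)
  ep <- match(d$endpoint, c("SF", "ACF", "ATP", "MMP"))
  if (any(is.na(arm_idx)) || any(is.na(time_idx)) || any(is.na(ep)))
    stop("build_fit_data: records not matching design/endpoints")
  list(design = design, times = times, loq = loq,
       log_obs = log(pmax(d$value, loq)),
       flat_idx = arm_idx + nrow(design) * ((time_idx - 1) + length(times) * (ep - 1)),
       endpoint = d$endpoint, n = nrow(d))
}

# weighted log-scale residual vector for a candidate parameter set
fit_residuals <- function(log10_theta, fit_names, fd, td0, dox0, trz0,
                          weights, dt) {
  theta <- stats::setNames(10^log10_theta, fit_names)
  ps <- apply_fit_params(theta, td0, dox0)
  sim <- cpp_invitro_sim(td_par_vector(ps$td), dox_par_vector(ps$dox),
                         trz_par_vector(trz0),
                         fd$arm_matrix, fd$times, dt, FALSE)
  pred <- sim[fd$flat_idx]
  w <- weights[fd$endpoint]
  (log(pmax(pred, fd$loq)) - fd$log_obs) * w
}

#' Fit the toxicodynamic model to an in-vitro dataset
#'
#' Pooled weighted least squares on log-scale residuals (a proportional /
#' multiplicative error model on the normalized observations), with
#' multi-start Levenberg-Marquardt on log10-transformed parameters over a
#' log-uniform initial box. Relative standard errors come from the
#' finite-difference Gauss-Newton curvature at the optimum; parameters whose
#' RSE exceeds `identifiability_rse` are flagged non-identifiable.
#'
#' @param dataset an [invitro_dataset()].
#' @param fit_names names of the parameters to estimate.
#' @param init named initial values (natural scale); defaults from
#'   `td_params` / `dox_params`.
#' @param td_params,dox_params,trz_params baseline parameter objects holding
#'   every non-fitted value.
#' @param lower,upper named natural-scale bounds (defaults:
#'   `init / bound_factor` and `init * bound_factor`; `Emax_kinATP` capped
#'   at 1). Both stages are refinements of published / stage-1 values, so
#'   the default box is deliberately a plausible-range constraint, not an
#'   uninformative one: the injury/transit sub-model admits a distant
#'   competing mode (near-instant injury with a very slow transit) that is
#'   indistinguishable from the gradual-injury mode on short observation
#'   windows.
#' @param bound_factor multiplicative half-width of the default bound box.
#' @param n_starts number of optimization starts (first start is `init`,
#'   the rest sampled log-uniformly within `start_box`-fold of `init`).
#' @param start_box multiplicative half-width of the start box.
#' @param seed integer seed for the start sampling.
#' @param weights named per-endpoint residual weights (log scale).
#' @param dt engine step (h).
#' @param loq limit of quantification on the normalized scale; observations
#'   and predictions are floored at it before taking logs.
#' @param identifiability_rse RSE (%) above which a parameter is flagged.
#' @return A `td_fit` object: estimates, RSEs, objective, information
#'   criteria, convergence and identifiability flags.
#' @export
fit_td <- function(dataset, fit_names,
                   init = NULL,
                   td_params = td_preset("interaction"),
                   dox_params = dox_cellular_params(),
                   trz_params = trz_cellular_params(),
                   lower = NULL, upper = NULL, bound_factor = 10,
                   n_starts = 5, start_box = 3, seed = 1,
                   weights = c(SF = 1, ACF = 1, ATP = 1, MMP = 1),
                   dt = 0.05, loq = 1e-3,
                   identifiability_rse = 50) {
  stopifnot(inherits(dataset, "invitro_dataset"))
  defaults <- c(unclass(td_params), CN = unname(dox_params[["CN"]]))
  if (is.null(init)) init <- defaults[fit_names]
  init <- init[fit_names]
  if (any(is.na(init))) stop("fit_td: missing initial values")

  lo <- init / bound_factor; hi <- init * bound_factor
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if ("Emax_kinATP" %in% fit_names)
    hi[["Emax_kinATP"]] <- min(hi[["Emax_kinATP"]], 1)

  fd <- build_fit_data(dataset, loq = loq)
  am <- as.matrix(dataset$design[, c("dox_start", "dox_end", "dox_conc",
                                     "trz_start", "trz_end", "trz_conc")])
  storage.mode(am) <- "double"
  fd$arm_matrix <- am

  set.seed(as.integer(seed))
  starts <- matrix(rep(log10(init), n_starts), nrow = n_starts, byrow = TRUE)
  if (n_starts > 1) {
    jit <- matrix(stats::runif((n_starts - 1) * length(init),
                               -log10(start_box), log10(start_box)),
                  nrow = n_starts - 1)
    starts[-1, ] <- sweep(jit, 2, log10(init), `+`)
  }
  starts <- pmin(pmax(starts, matrix(log10(lo), n_starts, length(init),
                                     byrow = TRUE)),
                 matrix(log10(hi), n_starts, length(init), byrow = TRUE))

  best <- NULL
  conv <- logical(n_starts)
  for (s in seq_len(n_starts)) {
    f <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[s, ],
        lower = log10(lo), upper = log10(hi),
        fn = fit_residuals,
        fit_names = fit_names, fd = fd, td0 = td_params, dox0 = dox_params,
        trz0 = trz_params, weights = weights, dt = dt,
        control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-10,
                                             ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(f)) next
    conv[s] <- f$info %in% 1:4
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best)) stop("fit_td: no optimization start converged")

  est_log10 <- stats::setNames(best$par, fit_names)
  est <- 10^est_log10
  ssr <- best$deviance
  n_obs <- fd$n; p <- length(fit_names)

  # Gauss-Newton curvature on the log10 scale
  hess <- as.matrix(best$hessian)
  sigma2 <- ssr / max(n_obs - p, 1)
  # pseudo-inverse: flat (non-identifiable) directions produce huge, not
  # failing, standard errors
  sv <- svd(hess)
  pos <- sv$d > max(sv$d) * 1e-12
  dinv <- ifelse(pos, 1 / sv$d, 1e12 / max(sv$d))
  cov_log10 <- sigma2 * (sv$v %*% (dinv * t(sv$u)))
  sd_log10 <- sqrt(pmax(diag(cov_log10), 0))
  rse <- sd_log10 * log(10) * 100  # approx CV% of the natural-scale estimate
  names(rse) <- fit_names
  flagged <- fit_names[!is.finite(rse) | rse > identifiability_rse]

  ll <- -n_obs / 2 * (log(2 * pi * ssr / n_obs) + 1)
  aic <- -2 * ll + 2 * p
  bic <- -2 * ll + p * log(n_obs)
  bicc <- bic + log(n_obs / (2 * pi)) # small-sample corrected variant

  full <- apply_fit_params(est, td_params, dox_params)
  structure(list(
    estimates = est, log10_estimates = est_log10, rse_pct = rse,
    fitted = fit_names, flagged_nonidentifiable = flagged,
    objective = ssr, n_obs = n_obs, n_par = p,
    aic = aic, bic = bic, bicc = bicc,
    converged = any(conv), n_starts = n_starts,
    td_params = full$td, dox_params = full$dox,
    info = best$info, message = best$message),
    class = "td_fit")
}

#' @export
print.td_fit <- function(x, ...) {
  cat("<td_fit>", x$n_par, "parameters,", x$n_obs, "observations; SSR =",
      signif(x$objective, 5), "\n")
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    rse_pct = round(x$rse_pct, 1))
  print(tab)
  if (length(x$flagged_nonidentifiable))
    cat("flagged non-identifiable:",
        paste(x$flagged_nonidentifiable, collapse = ", "), "\n")
  invisible(x)
}

#' Stage 1: system parameters from doxorubicin-only data
#'
#' Estimates the system-dependent parameters (`k_in_ATP`, `k_in_MMP`, `CN`,
#' `n`) together with the doxorubicin individual-dependent parameters
#' (`k_inj`, `tau`, `EC50_kinMMP`) from the doxorubicin arms of a dataset.
#'
#' @param dataset an [invitro_dataset()]; trastuzumab arms are dropped.
#' @param init named initial values; defaults to the `"dox_only"` preset.
#' @param ... passed to [fit_td()].
#' @return A `td_fit` (stage label `"stage1_dox"`).
#' @export
fit_stage1_dox <- function(dataset, init = NULL, ...) {
  keep <- dataset$design$arm[dataset$design$trz_conc == 0]
  design <- dataset$design[dataset$design$arm %in% keep, , drop = FALSE]
  data <- dataset$data[dataset$data$arm %in% keep, , drop = FALSE]
  ds <- invitro_dataset(design, data, control_arm = dataset$control_arm)
  concs <- unique(design$dox_conc[design$dox_conc > 0])
  if (length(concs) < 2)
    warning("fit_stage1_dox: single doxorubicin concentration; ",
            "EC50_kinMMP is expected to be non-identifiable")
  if (is.null(init)) {
    p0 <- td_preset("dox_only")
    init <- c(unclass(p0)[c("k_in_ATP", "k_in_MMP", "n", "k_inj", "tau",
                            "EC50_kinMMP")],
              CN = unname(dox_cellular_params()[["CN"]]))[.stage1_params]
    init <- init[.stage1_params]
  }
  fit <- fit_td(ds, .stage1_params, init = init,
                td_params = td_preset("dox_only"), ...)
  fit$stage <- "stage1_dox"
  fit
}

#' Stage 2: simultaneous fit on interaction data
#'
#' Simultaneously estimates the system-dependent and all individual-dependent
#' parameters (adding `Emax_kinATP`, `EC50_kinATP`, `k_TRZ_ATP50`, `k_e`)
#' from a dataset containing trastuzumab-alone, sequential and concurrent
#' arms. Stage-1 results may be supplied as initial values.
#'
#' @param dataset an [invitro_dataset()] with interaction arms.
#' @param init named initial values, or a stage-1 `td_fit` whose estimates
#'   seed the shared parameters; defaults to the `"interaction"` preset.
#' @param ... passed to [fit_td()].
#' @return A `td_fit` (stage label `"stage2_interaction"`).
#' @export
fit_stage2_interaction <- function(dataset, init = NULL, ...) {
  has_combo <- any(dataset$design$dox_conc > 0 & dataset$design$trz_conc > 0)
  if (!any(dataset$design$trz_conc > 0))
    stop("fit_stage2_interaction: no trastuzumab arms in dataset")
  if (!has_combo)
    warning("fit_stage2_interaction: no sequential/concurrent arms; ",
            "k_e is expected to be non-identifiable")
  defaults <- c(unclass(td_preset("interaction")),
                CN = unname(dox_cellular_params()[["CN"]]))
  ini <- defaults[.stage2_params]
  if (inherits(init, "td_fit")) {
    ini[names(init$estimates)] <- init$estimates
  } else if (!is.null(init)) {
    ini[names(init)] <- init
  }
  fit <- fit_td(dataset, .stage2_params, init = ini, ...)
  fit$stage <- "stage2_interaction"
  fit
}

#' Bootstrap cross-check of fit uncertainties
#'
#' Nonparametric replicate-level bootstrap: wells (replicates) are resampled
#' with replacement within every arm, the model is refit from the original
#' estimates, and the spread of the refitted estimates cross-checks the
#' curvature-based relative standard errors of [fit_td()].
#'
#' @param fit a `td_fit`.
#' @param dataset the [invitro_dataset()] the fit was obtained from.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param ... passed to [fit_td()] (e.g. `dt`).
#' @return data.frame of bootstrap estimates (one row per resample), with
#'   bootstrap RSEs (%) attached as attribute `"rse_pct"`.
#' @export
bootstrap_fit <- function(fit, dataset, n_boot = 200, seed = 1, ...) {
  stopifnot(inherits(fit, "td_fit"))
  reps <- sort(unique(dataset$data$replicate))
  set.seed(as.integer(seed))
  out <- matrix(NA_real_, n_boot, length(fit$fitted),
                dimnames = list(NULL, fit$fitted))
  for (b in seq_len(n_boot)) {
    draw <- sample(reps, length(reps), replace = TRUE)
    pieces <- lapply(seq_along(draw), function(k) {
      d <- dataset$data[dataset$data$replicate == draw[k], , drop = FALSE]
      d$replicate <- k
      d
    })
    ds_b <- invitro_dataset(dataset$design, do.call(rbind, pieces),
                            control_arm = dataset$control_arm)
    fb <- tryCatch(
      fit_td(ds_b, fit$fitted, init = fit$estimates,
             td_params = fit$td_params, dox_params = fit$dox_params,
             n_starts = 1, seed = seed + b, ...),
      error = function(e) NULL)
    if (!is.null(fb)) out[b, ] <- fb$estimates
  }
  out <- as.data.frame(out)
  attr(out, "rse_pct") <- vapply(out, function(x)
    stats::sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE) * 100, numeric(1))
  out
}

#' Parameter-recovery simulation study
#'
#' Generates replicate synthetic datasets at a known truth, refits, and
#' summarizes the recovered estimates. Used by the package's own validation
#' of estimator consistency.
#'
#' @param preset design preset name (`"fig1a"` for stage 1, `"fig1b"` for
#'   stage 2).
#' @param stage 1 or 2.
#' @param n_replicates number of generate/fit replicates.
#' @param cv measurement noise CV.
#' @param seed master seed; replicate r uses `seed + r - 1`.
#' @param truth generating `td_parameters`.
#' @param n_starts optimization starts per fit.
#' @param dt engine step.
#' @return data.frame of per-replicate estimates (one column per fitted
#'   parameter), with the truth attached as attribute `"truth"`.
#' @export
recovery_study <- function(preset = c("fig1b", "fig1a"), stage = 2,
                           n_replicates = 20, cv = 0.10, seed = 1,
                           truth = td_preset(if (stage == 2) "interaction"
                                             else "dox_only"),
                           n_starts = 3, dt = 0.05) {
  preset <- match.arg(preset)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    ds <- generate_dataset(preset, td_params = truth,
                           noise = noise_model(cv = cv),
                           seed = seed + r - 1, dt = dt)
    fit <- if (stage == 1)
      fit_stage1_dox(ds, n_starts = n_starts, seed = seed + r - 1, dt = dt)
    else
      fit_stage2_interaction(ds, n_starts = n_starts, seed = seed + r - 1,
                             dt = dt)
    out[[r]] <- fit$estimates
  }
  res <- as.data.frame(do.call(rbind, out))
  attr(res, "truth") <- truth
  res
}
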