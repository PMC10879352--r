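# Shared fixtures and independent reference integrators for oracle checks.

# fixed-step classical RK4 on a deSolve-style rhs(t, y) returning a vector
rk4_integrate <- function(rhs, y0, t_end, dt, t_out = NULL) {
  n <- ceiling(t_end / dt)
  y <- y0
  t <- 0
  keep <- if (is.null(t_out)) NULL else
    matrix(NA_real_, length(t_out), length(y0),
           dimnames = list(NULL, names(y0)))
  ko <- 1
  record <- function(tt, yy) {
    while (ko <= length(t_out) && t_out[ko] <= tt + 1e-12) {
      keep[ko, ] <<- yy
      ko <<- ko + 1
    }
  }
  if (!is.null(t_out)) record(0, y)
  for (i in seq_len(n)) {
    h <- min(dt, t_end - t)
    k1 <- rhs(t, y)
    k2 <- rhs(t + h / 2, y + h / 2 * k1)
    k3 <- rhs(t + h / 2, y + h / 2 * k2)
    k4 <- rhs(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    if (!is.null(t_out)) record(t, y)
  }
  if (!is.null(t_out) && ko <= length(t_out)) {
    # flush trailing outputs lost to floating-point drift of the step sum
    for (k in ko:length(t_out)) keep[k, ] <- y
  }
  if (is.null(t_out)) y else keep
}

# numeric root of the intracellular doxorubicin mass balance (independent
# oracle for the closed-form binding solution)
free_dox_root <- function(C_total, CN, kd) {
  if (C_total == 0) return(0)
  stats::uniroot(function(cf) cf + CN * cf / (kd + cf) - C_total,
                 c(0, C_total), tol = 1e-14)$root
}

tiny_cohort <- function(n = 5, seed = 42) sample_patients(n, seed)
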