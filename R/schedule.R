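#' Extracellular exposure schedule
#'
#' A per-drug description of the extracellular concentration over time:
#' either an ordered set of piecewise-constant exposure windows (the in-vitro
#' case: dosing followed by washout) or a sampled continuous profile on a time
#' grid (the in-vivo case, produced by [heart_interstitial_profiles()]).
#'
#' @param windows data.frame with columns `t_start`, `t_end` (h) and `conc`
#'   (umol/L for doxorubicin, nmol/L for trastuzumab). Windows must be
#'   non-overlapping, nonnegative and increasing. Omit for a profile schedule.
#' @param profile list with numeric vectors `time` (h, increasing) and `conc`
#'   (same length); linearly interpolated, constant extrapolation 0 beyond the
#'   grid. Omit for a window schedule.
#' @param drug `"dox"` or `"trz"`.
#' @param unit concentration unit string, recorded for provenance.
#' @return An object of class `exposure_schedule`.
#' @export
exposure_schedule <- function(windows = NULL, profile = NULL,
                              drug = c("dox", "trz"),
                              unit = if (drug == "dox") "umol/L" else "nmol/L") {
  drug <- match.arg(drug)
  if (is.null(windows) == is.null(profile))
    stop("exposure_schedule: give exactly one of `windows` or `profile`")
  if (!is.null(windows)) {
    windows <- as.data.frame(windows)
    need <- c("t_start", "t_end", "conc")
    if (!all(need %in% names(windows)))
      stop("exposure_schedule: `windows` needs columns ",
           paste(need, collapse = ", "))
    windows <- windows[order(windows$t_start), , drop = FALSE]
    if (nrow(windows)) {
      if (any(windows$t_start < 0) || any(windows$t_end <= windows$t_start))
        stop("exposure_schedule: window times must be nonnegative with t_end > t_start")
      if (any(windows$conc < 0))
        stop("exposure_schedule: concentrations must be nonnegative")
      if (nrow(windows) > 1 &&
          any(windows$t_start[-1] < windows$t_end[-nrow(windows)]))
        stop("exposure_schedule: windows must not overlap")
    }
    obj <- list(type = "windows", windows = windows, drug = drug, unit = unit)
  } else {
    if (!is.numeric(profile$time) || !is.numeric(profile$conc) ||
        length(profile$time) != length(profile$conc))
      stop("exposure_schedule: `profile` needs equal-length numeric `time` and `conc`")
    if (is.unsorted(profile$time, strictly = TRUE))
      stop("exposure_schedule: profile times must be strictly increasing")
    if (any(profile$time < 0) || any(profile$conc < 0))
      stop("exposure_schedule: profile times and concentrations must be nonnegative")
    obj <- list(type = "profile", profile = profile, drug = drug, unit = unit)
  }
  structure(obj, class = "exposure_schedule")
}

#' Constant single-window exposure with washout
#'
#' Convenience wrapper for the in-vitro design arms: concentration `conc`
#' between `t_start` and `t_end`, zero elsewhere.
#'
#' @inheritParams exposure_schedule
#' @param conc concentration during the window.
#' @param t_start,t_end window boundaries (h).
#' @export
constant_exposure <- function(conc, t_start = 0, t_end, drug = c("dox", "trz")) {
  drug <- match.arg(drug)
  if (conc == 0) {
    return(exposure_schedule(
      windows = data.frame(t_start = numeric(), t_end = numeric(),
                           conc = numeric()),
      drug = drug))
  }
  exposure_schedule(
    windows = data.frame(t_start = t_start, t_end = t_end, conc = conc),
    drug = drug)
}

#' Evaluate a schedule's extracellular concentration at given times
#'
#' Window schedules are piecewise-constant (right-open windows); profile
#' schedules are linearly interpolated with zero outside the grid.
#'
#' @param schedule an [exposure_schedule()].
#' @param times numeric vector of times (h).
#' @return Numeric vector of concentrations.
#' @export
schedule_conc <- function(schedule, times) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  if (schedule$type == "windows") {
    out <- numeric(length(times))
    w <- schedule$windows
    if (nrow(w)) {
      for (i in seq_len(nrow(w))) {
        sel <- times >= w$t_start[i] & times < w$t_end[i]
        out[sel] <- w$conc[i]
      }
    }
    out
  } else {
    stats::approx(schedule$profile$time, schedule$profile$conc, xout = times,
                  yleft = 0, yright = 0, rule = 1, ties = "ordered")$y -> y
    y[is.na(y)] <- 0
    y
  }
}

# forcing evaluation inside an integration segment: window schedules are
# piecewise-constant and evaluated frozen at the segment midpoint `tm`
# (exact; keeps discontinuities out of the solver's error test), continuous
# profiles at the actual time
sched_eval <- function(schedule, t, tm) {
  if (schedule$type == "windows") schedule_conc(schedule, tm)
  else schedule_conc(schedule, t)
}

# time points at which the exposure is discontinuous (integration restarts)
schedule_breaks <- function(schedule) {
  if (is.null(schedule)) return(numeric())
  if (schedule$type == "windows") {
    sort(unique(c(schedule$windows$t_start, schedule$windows$t_end)))
  } else {
    numeric()
  }
}

#' @export
print.exposure_schedule <- function(x, ...) {
  cat("<exposure_schedule>", x$drug, sprintf("[%s]", x$unit), "-", x$type, "\n")
  if (x$type == "windows") print(x$windows) else
    cat("  profile on", length(x$profile$time), "time points, max",
        signif(max(x$profile$conc), 4), "\n")
  invisible(x)
}
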