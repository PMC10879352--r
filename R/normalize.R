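#' Two-step normalization of a single measurement
#'
#' `(raw / baseline) / control_ratio`: the raw well measurement is first
#' normalized to the same well's pre-treatment (baseline) value to remove
#' inter-well variability, then to the contemporaneous control ratio to
#' remove shared temporal drift (circadian effects).
#'
#' @param raw raw measurement at time t.
#' @param baseline same well's measurement at t = 0 (> 0).
#' @param control_ratio control well's `raw(t)/baseline` ratio at the same
#'   time (> 0).
#' @return Normalized value; vectorized.
#' @export
normalize_two_step <- function(raw, baseline, control_ratio) {
  if (any(baseline <= 0)) stop("normalize_two_step: baseline must be > 0")
  if (any(control_ratio <= 0)) stop("normalize_two_step: control ratio must be > 0")
  (raw / baseline) / control_ratio
}

#' In-vitro dataset container
#'
#' Bundles an experimental design (one row per arm and drug window) with
#' normalized measurement records. Validates the structural invariants:
#' nonnegative values, at least two time points per arm, and a control arm.
#'
#' @param design data.frame with columns `arm`, `dox_start`, `dox_end`,
#'   `dox_conc`, `trz_start`, `trz_end`, `trz_conc`.
#' @param data data.frame with columns `arm`, `endpoint` (one of `ACF`,
#'   `SF`, `ATP`, `MMP`), `time_h`, `value`, `replicate`.
#' @param control_arm id of the control (drug-free) arm.
#' @param raw optional data.frame of raw (un-normalized) records, same shape.
#' @return An object of class `invitro_dataset`.
#' @export
invitro_dataset <- function(design, data, control_arm = "control", raw = NULL) {
  need_d <- c("arm", "dox_start", "dox_end", "dox_conc",
              "trz_start", "trz_end", "trz_conc")
  if (!all(need_d %in% names(design)))
    stop("invitro_dataset: design needs columns ",
         paste(setdiff(need_d, names(design)), collapse = ", "))
  need_m <- c("arm", "endpoint", "time_h", "value", "replicate")
  miss <- setdiff(need_m, names(data))
  if (length(miss))
    stop("invitro_dataset: data is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!control_arm %in% design$arm)
    stop("invitro_dataset: control arm '", control_arm, "' not in design")
  if (any(data$value < 0, na.rm = TRUE))
    stop("invitro_dataset: negative measurement values")
  tp <- tapply(data$time_h, data$arm, function(x) length(unique(x)))
  if (any(tp < 2))
    stop("invitro_dataset: arms with < 2 time points: ",
         paste(names(tp)[tp < 2], collapse = ", "))
  structure(list(design = design, data = data, control_arm = control_arm,
                 raw = raw),
            class = "invitro_dataset")
}

#' @export
print.invitro_dataset <- function(x, ...) {
  cat("<invitro_dataset>", nrow(x$design), "arms,",
      nrow(x$data), "normalized records,",
      length(unique(x$data$endpoint)), "endpoints\n")
  invisible(x)
}

#' Apply the two-step normalization to raw well measurements
#'
#' Each record is divided by its own well's baseline (t = 0) value and then
#' by the matched control replicate's ratio at the same time point, per
#' endpoint. The control arm therefore maps to exactly 1 at every time.
#'
#' @param raw data.frame with columns `arm`, `endpoint`, `time_h`, `value`,
#'   `replicate`; must contain `time_h == 0` for every
#'   (arm, endpoint, replicate) and a complete control arm.
#' @param design design data.frame (see [invitro_dataset()]).
#' @param control_arm id of the control arm in `raw`.
#' @return An [invitro_dataset()] with normalized values (raw kept).
#' @export
normalize_raw <- function(raw, design, control_arm = "control") {
  need <- c("arm", "endpoint", "time_h", "value", "replicate")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("normalize_raw: raw data is missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- raw$value <= 0 & raw$arm == control_arm
  if (any(bad))
    stop("normalize_raw: nonpositive control measurements at time(s) ",
         paste(unique(raw$time_h[bad]), collapse = ", "))

  key <- function(a, e, r) paste(a, e, r, sep = "\r")
  tkey <- function(e, r, t) paste(e, r, t, sep = "\r")

  base_idx <- raw$time_h == 0
  baseline <- stats::setNames(raw$value[base_idx],
                              key(raw$arm[base_idx], raw$endpoint[base_idx],
                                  raw$replicate[base_idx]))
  b <- baseline[key(raw$arm, raw$endpoint, raw$replicate)]
  if (any(is.na(b)))
    stop("normalize_raw: missing baseline (t = 0) wells for ",
         paste(unique(raw$arm[is.na(b)]), collapse = ", "))
  if (any(b <= 0))
    stop("normalize_raw: nonpositive baseline in well(s) ",
         paste(unique(key(raw$arm, raw$endpoint, raw$replicate)[b <= 0]),
               collapse = "; "))

  ctrl <- raw[raw$arm == control_arm, ]
  cb <- baseline[key(ctrl$arm, ctrl$endpoint, ctrl$replicate)]
  cratio <- stats::setNames(ctrl$value / cb,
                            tkey(ctrl$endpoint, ctrl$replicate, ctrl$time_h))
  cr <- cratio[tkey(raw$endpoint, raw$replicate, raw$time_h)]
  if (any(is.na(cr)))
    stop("normalize_raw: control series does not cover all time points")

  norm <- raw
  norm$value <- (raw$value / b) / cr
  invitro_dataset(design, norm, control_arm = control_arm, raw = raw)
}

# drug descriptor strings for the flat CSV schema ("DOX;TRZ" etc.)
design_descriptors <- function(design) {
  desc <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    parts <- list()
    if (d$dox_conc > 0)
      parts$dox <- c(drug = "DOX", conc = d$dox_conc, unit = "umol/L",
                     s = d$dox_start, e = d$dox_end)
    if (d$trz_conc > 0)
      parts$trz <- c(drug = "TRZ", conc = d$trz_conc, unit = "nmol/L",
                     s = d$trz_start, e = d$trz_end)
    if (!length(parts))
      return(c(drug = "none", conc = "0", conc_unit = "",
               exposure_start_h = "", exposure_end_h = ""))
    c(drug = paste(vapply(parts, `[[`, "", "drug"), collapse = ";"),
      conc = paste(vapply(parts, `[[`, "", "conc"), collapse = ";"),
      conc_unit = paste(vapply(parts, `[[`, "", "unit"), collapse = ";"),
      exposure_start_h = paste(vapply(parts, `[[`, "", "s"), collapse = ";"),
      exposure_end_h = paste(vapply(parts, `[[`, "", "e"), collapse = ";"))
  })
  cbind(arm = design$arm, as.data.frame(do.call(rbind, desc)))
}

#' Write / read the flat in-vitro dataset CSV
#'
#' Flat schema with one row per measurement: `arm, drug, conc, conc_unit,
#' exposure_start_h, exposure_end_h, endpoint, time_h, value, replicate`.
#' Multi-drug arms carry `;`-separated descriptor fields.
#'
#' @param dataset an [invitro_dataset()].
#' @param path file path.
#' @return `read_invitro_csv` returns an [invitro_dataset()].
#' @export
write_invitro_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "invitro_dataset"))
  desc <- design_descriptors(dataset$design)
  out <- cbind(dataset$data,
               desc[match(dataset$data$arm, desc$arm), -1, drop = FALSE])
  cols <- c("arm", "drug", "conc", "conc_unit", "exposure_start_h",
            "exposure_end_h", "endpoint", "time_h", "value", "replicate")
  utils::write.csv(out[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_invitro_csv
#' @param control_arm id of the control arm.
#' @export
read_invitro_csv <- function(path, control_arm = "control") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("arm", "drug", "conc", "conc_unit", "exposure_start_h",
            "exposure_end_h", "endpoint", "time_h", "value", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_invitro_csv: missing column(s): ", paste(miss, collapse = ", "))
  # rebuild the design from the descriptor fields
  u <- df[!duplicated(df$arm),
          c("arm", "drug", "conc", "conc_unit",
            "exposure_start_h", "exposure_end_h")]
  parse_arm <- function(r) {
    drugs <- strsplit(as.character(r[["drug"]]), ";")[[1]]
    conc <- strsplit(as.character(r[["conc"]]), ";")[[1]]
    s <- strsplit(as.character(r[["exposure_start_h"]]), ";")[[1]]
    e <- strsplit(as.character(r[["exposure_end_h"]]), ";")[[1]]
    out <- c(dox_start = 0, dox_end = 0, dox_conc = 0,
             trz_start = 0, trz_end = 0, trz_conc = 0)
    for (j in seq_along(drugs)) {
      if (toupper(drugs[j]) == "DOX") {
        out["dox_start"] <- as.numeric(s[j]); out["dox_end"] <- as.numeric(e[j])
        out["dox_conc"] <- as.numeric(conc[j])
      } else if (toupper(drugs[j]) == "TRZ") {
        out["trz_start"] <- as.numeric(s[j]); out["trz_end"] <- as.numeric(e[j])
        out["trz_conc"] <- as.numeric(conc[j])
      }
    }
    out
  }
  design <- cbind(arm = u$arm,
                  as.data.frame(t(apply(u, 1, parse_arm))))
  data <- df[, c("arm", "endpoint", "time_h", "value", "replicate")]
  invitro_dataset(design, data, control_arm = control_arm)
}
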