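#' Read a voltage/impedance spectrum from CSV
#'
#' Expects a header row with columns `frequency_hz`, `current_a_rms` and
#' `voltage_v_rms` (one row per frequency). Unit-suffixed variants are
#' converted on read: `voltage_mv_rms` (millivolts), `current_ma_rms` /
#' `current_ua_rms` (milli-/microamps). Malformed cells are reported with
#' their row number.
#'
#' @param path Path to a CSV file.
#' @return A `spectrum` data frame (see [impedance_from_voltage()]).
#' @export
read_spectrum_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  get_col <- function(stems) {
    for (s in names(stems)) {
      if (s %in% names(raw)) {
        return(suppressWarnings(as.numeric(raw[[s]])) * stems[[s]])
      }
    }
    stop(sprintf("missing column: one of %s",
                 paste(names(stems), collapse = ", ")), call. = FALSE)
  }
  f <- get_col(list(frequency_hz = 1, frequency_khz = 1e3))
  i <- get_col(list(current_a_rms = 1, current_ma_rms = 1e-3,
                    current_ua_rms = 1e-6))
  v <- get_col(list(voltage_v_rms = 1, voltage_mv_rms = 1e-3))
  bad <- which(!is.finite(f) | !is.finite(i) | !is.finite(v) | i <= 0)
  if (length(bad) > 0) {
    stop(sprintf("malformed measurement row(s): %s (non-numeric value or non-positive current)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  impedance_from_voltage(f, i, v)
}

#' Read a conductivity table from CSV
#'
#' First column `frequency_hz`; each remaining column holds conductivities
#' (S/m) for the lumen diameter in mm given by its header.
#'
#' @param path Path to a CSV file.
#' @return A [conductivity_table()].
#' @export
read_conductivity_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (names(raw)[1] != "frequency_hz") {
    stop("first column must be frequency_hz", call. = FALSE)
  }
  d_mm <- suppressWarnings(as.numeric(names(raw)[-1]))
  if (anyNA(d_mm)) {
    stop("diameter column headers must be numeric (mm)", call. = FALSE)
  }
  conductivity_table(raw$frequency_hz, d_mm * 1e-3,
                     as.matrix(raw[, -1, drop = FALSE]))
}

#' Read a bath-thickness conductance series from CSV
#'
#' Columns: `bath_thickness_mm`, then one `G_total_mS_<f>kHz` column per
#' frequency.
#'
#' @param path Path to a CSV file.
#' @return A [bath_series()].
#' @export
read_bath_series_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (names(raw)[1] != "bath_thickness_mm") {
    stop("first column must be bath_thickness_mm", call. = FALSE)
  }
  gcols <- grep("^G_total_mS_", names(raw), value = TRUE)
  if (length(gcols) == 0) {
    stop("no G_total_mS_<f>kHz columns found", call. = FALSE)
  }
  f_khz <- as.numeric(sub("^G_total_mS_(.*)kHz$", "\\1", gcols))
  if (anyNA(f_khz)) {
    stop("conductance column headers must be G_total_mS_<f>kHz",
         call. = FALSE)
  }
  bath_series(raw$bath_thickness_mm * 1e-3,
              as.matrix(raw[, gcols, drop = FALSE]) * 1e-3,
              f_khz * 1e3)
}

#' Serialize an estimate or agreement summary as JSON
#'
#' Produces a schema-versioned JSON report with stable key order and
#' unit-suffixed field names (`d_b_mm`, `G_mS`, ...). Non-converged
#' estimates carry a `warning` field.
#'
#' @param x A `diameter_estimate` or `agreement_stats` object.
#' @return A JSON string (class `json`).
#' @export
report_json <- function(x) {
  if (inherits(x, "diameter_estimate")) {
    dc <- x$decomposition
    out <- list(
      schema = "condsize/diameter_estimate/1",
      d_b_mm = x$d_b_m * 1e3,
      converged = x$converged,
      iterations = x$iterations,
      mismatch_rel = x$mismatch,
      R_ohm = x$R_ohm,
      G_mS = dc$G * 1e3, Gb_mS = dc$G_b * 1e3,
      Gt_mS = dc$G_t * 1e3, Gbath_mS = dc$G_bath * 1e3,
      sigma_b_used = x$sigma_b_used
    )
    if (!x$converged) {
      out$warning <- "did not converge within tolerance"
    }
  } else if (inherits(x, "agreement_stats")) {
    out <- list(
      schema = "condsize/agreement_stats/1",
      n = x$n, mean_diff_mm = x$mean_diff, sd_diff_mm = x$sd_diff,
      repeatability_mm = x$repeatability,
      frac_within_1sd = x$frac_within_1sd,
      frac_within_2sd = x$frac_within_2sd,
      loa_lower_mm = unname(x$loa[["lower"]]),
      loa_upper_mm = unname(x$loa[["upper"]]),
      slope = x$slope, intercept = x$intercept, r2 = x$r2
    )
  } else {
    stop("unsupported object for report_json", call. = FALSE)
  }
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null")
}
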