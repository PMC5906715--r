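#' Conductivity lookup table (frequency x lumen diameter)
#'
#' Holds the effective ("ideal") conductivity of the lumen fluid as a
#' function of excitation frequency and lumen diameter, as obtained from
#' phantom calibration. The apparent diameter dependence absorbs field
#' non-uniformity, so the table is treated as an empirical lookup, not a
#' material property.
#'
#' @param frequencies_hz Increasing frequencies, Hz.
#' @param diameters_m Increasing lumen diameters, m.
#' @param sigma Matrix of conductivities, S/m; rows = frequencies,
#'   columns = diameters.
#' @return An object of class `conductivity_table`.
#' @seealso [saline_conductivity_table()] for the packaged 0.45%-saline
#'   default, [conductivity_lookup()] for interpolation.
#' @export
conductivity_table <- function(frequencies_hz, diameters_m, sigma) {
  sigma <- as.matrix(sigma)
  if (length(frequencies_hz) == 0 || length(diameters_m) == 0) {
    stop("empty conductivity table", call. = FALSE)
  }
  if (nrow(sigma) != length(frequencies_hz) ||
      ncol(sigma) != length(diameters_m)) {
    stop("sigma must be frequencies x diameters", call. = FALSE)
  }
  if (is.unsorted(frequencies_hz, strictly = TRUE) ||
      is.unsorted(diameters_m, strictly = TRUE)) {
    stop("frequencies and diameters must be strictly increasing",
         call. = FALSE)
  }
  if (any(sigma <= 0)) stop("conductivities must be positive", call. = FALSE)
  structure(
    list(frequencies_hz = as.numeric(frequencies_hz),
         diameters_m = as.numeric(diameters_m), sigma = unname(sigma)),
    class = "conductivity_table"
  )
}

#' @export
print.conductivity_table <- function(x, ...) {
  cat(sprintf("<conductivity table>  %d frequencies (%g-%g kHz) x %d diameters (%g-%g mm)\n",
              length(x$frequencies_hz), min(x$frequencies_hz) / 1e3,
              max(x$frequencies_hz) / 1e3, length(x$diameters_m),
              min(x$diameters_m) * 1e3, max(x$diameters_m) * 1e3))
  invisible(x)
}

#' Packaged 0.45% saline conductivity table (5-5-5 guidewire)
#'
#' Phantom-calibrated effective conductivity of 0.45% NaCl solution at room
#' temperature, measured with the 5-5-5 peripheral guidewire in rigid
#' phantoms of 1.75-8 mm diameter over 10-80 kHz. Conductivity increases
#' with frequency and decreases with phantom diameter.
#'
#' @return A [conductivity_table()].
#' @export
saline_conductivity_table <- function() {
  path <- system.file("extdata", "saline_conductivity_555.csv",
                      package = "condsize", mustWork = TRUE)
  read_conductivity_csv(path)
}

#' Interpolate a conductivity table
#'
#' Bilinear interpolation in (log10 frequency, diameter), exact at grid
#' nodes. Queries outside the grid are clamped to the nearest edge rather
#' than extrapolated.
#'
#' @param tbl A [conductivity_table()].
#' @param frequency_hz Query frequency, Hz.
#' @param d_b_m Query lumen diameter, m.
#' @return Conductivity in S/m.
#' @examples
#' conductivity_lookup(saline_conductivity_table(), 10e3, 4e-3)  # 0.95
#' @export
conductivity_lookup <- function(tbl, frequency_hz, d_b_m) {
  stopifnot(inherits(tbl, "conductivity_table"))
  lf <- log10(clamp(frequency_hz, min(tbl$frequencies_hz),
                    max(tbl$frequencies_hz)))
  d <- clamp(d_b_m, min(tbl$diameters_m), max(tbl$diameters_m))
  lfs <- log10(tbl$frequencies_hz)
  ds <- tbl$diameters_m
  i <- findInterval(lf, lfs, rightmost.closed = TRUE, all.inside = TRUE)
  j <- findInterval(d, ds, rightmost.closed = TRUE, all.inside = TRUE)
  tf <- (lf - lfs[i]) / (lfs[i + 1] - lfs[i])
  td <- (d - ds[j]) / (ds[j + 1] - ds[j])
  (1 - tf) * (1 - td) * tbl$sigma[i, j] +
    tf * (1 - td) * tbl$sigma[i + 1, j] +
    (1 - tf) * td * tbl$sigma[i, j + 1] +
    tf * td * tbl$sigma[i + 1, j + 1]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Fluid conductivity from a phantom (or introducer-catheter) measurement
#'
#' In a rigid tube of known diameter there is no parallel pathway, so the
#' whole system resistance is the lumen annulus and
#' \deqn{\sigma_b = 4 L / (\pi R (d^2 - d_{GW}^2)),}
#' the exact inverse of [lumen_conductance()]. The in-vivo variant measures
#' blood aspirated into the introducing catheter of known inner diameter.
#'
#' @param R_ohm System resistance from the two-frequency model, ohms.
#' @param d_phantom_m Phantom (or catheter inner) diameter, m.
#' @param gw A [guidewire()].
#' @return Conductivity in S/m.
#' @export
phantom_conductivity <- function(R_ohm, d_phantom_m, gw) {
  stopifnot(inherits(gw, "guidewire"))
  if (R_ohm <= 0) stop("R must be positive", call. = FALSE)
  if (d_phantom_m <= gw$d_gw_m) {
    stop("guidewire larger than phantom lumen", call. = FALSE)
  }
  4 * gw$L_m / (pi * R_ohm * (d_phantom_m^2 - gw$d_gw_m^2))
}

#' Wall-tissue conductivity from an ex-vivo measurement
#'
#' Given the wall conductance (total minus lumen, measured with the vessel
#' suspended so there is no surrounding pathway) and the optically measured
#' geometry, the wall conductivity is
#' \deqn{\sigma_t = G_t L / (\pi d_b^2 TR (1+TR)),}
#' the exact inverse of [wall_conductance()].
#'
#' @param G_t_s Wall-tissue conductance, siemens.
#' @param d_b_m Lumen diameter, m.
#' @param TR Wall-thickness to lumen-diameter ratio (> 0).
#' @param gw A [guidewire()].
#' @return Conductivity in S/m.
#' @examples
#' tissue_conductivity_from_exvivo(2.97e-3, 3.2e-3, 0.79,
#'                                 guidewire("5-5-5"))  # ~0.39
#' @export
tissue_conductivity_from_exvivo <- function(G_t_s, d_b_m, TR, gw) {
  stopifnot(inherits(gw, "guidewire"))
  if (G_t_s < 0) stop("conductance must be >= 0", call. = FALSE)
  if (TR <= 0) {
    if (G_t_s == 0) return(0)
    stop("TR must be positive when G_t > 0", call. = FALSE)
  }
  G_t_s * gw$L_m / (pi * d_b_m^2 * TR * (1 + TR))
}
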