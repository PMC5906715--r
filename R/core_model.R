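#' Lumen (fluid annulus) conductance
#'
#' Axial conductance of the conducting fluid filling the annulus between the
#' guidewire shaft and the lumen wall, over the sensing-electrode separation
#' `L`:
#' \deqn{G_b = \sigma_b \pi (d_b^2 - d_{GW}^2) / (4 L)}
#'
#' @param sigma_b Fluid (blood or saline) conductivity, S/m.
#' @param d_b_m Lumen diameter, m.
#' @param gw A [guidewire()].
#' @return Conductance in siemens.
#' @examples
#' lumen_conductance(1.4, 3.2e-3, guidewire("5-5-5")) * 1e3  # ~1.73 mS
#' @export
lumen_conductance <- function(sigma_b, d_b_m, gw) {
  stopifnot(inherits(gw, "guidewire"))
  if (any(sigma_b < 0)) stop("conductivity must be >= 0", call. = FALSE)
  if (any(d_b_m <= gw$d_gw_m)) {
    stop("guidewire larger than lumen (d_b <= d_gw)", call. = FALSE)
  }
  sigma_b * pi * (d_b_m^2 - gw$d_gw_m^2) / (4 * gw$L_m)
}

#' Vessel-wall conductance
#'
#' Axial conductance of the wall-tissue annulus of thickness `TR * d_b`
#' surrounding the lumen, over the sensing separation `L`:
#' \deqn{G_t = \sigma_t \pi d_b^2 TR (1 + TR) / L}
#' which is the coaxial-annulus form \eqn{\sigma_t \pi (r_o^2 - r_i^2)/L}
#' with inner radius `d_b/2` and outer radius `d_b/2 + TR d_b`.
#'
#' @param sigma_t Wall-tissue conductivity, S/m.
#' @param d_b_m Lumen diameter, m.
#' @param TR Wall-thickness to lumen-diameter ratio.
#' @param gw A [guidewire()].
#' @return Conductance in siemens.
#' @examples
#' wall_conductance(0.39, 3.2e-3, 0.79, guidewire("5-5-5")) * 1e3  # ~2.96 mS
#' @export
wall_conductance <- function(sigma_t, d_b_m, TR, gw) {
  stopifnot(inherits(gw, "guidewire"))
  if (any(sigma_t < 0)) stop("conductivity must be >= 0", call. = FALSE)
  if (any(TR < 0)) stop("TR must be >= 0", call. = FALSE)
  sigma_t * pi * d_b_m^2 * TR * (1 + TR) / gw$L_m
}

#' Closed-form lumen diameter from system resistance
#'
#' Inverts the two-pathway conductance balance `1/R = G_b + G_t` for the
#' lumen diameter when the vessel has no surrounding conducting medium:
#' \deqn{d_b = \sqrt{\frac{4L + \pi R \sigma_b d_{GW}^2}
#'                        {\pi R (\sigma_b + 4 \sigma_t TR (1+TR))}}}
#'
#' @param R_ohm Ohmic system resistance from the two-frequency model, ohms.
#' @param sigma_b Lumen-fluid conductivity, S/m.
#' @param sigma_t Wall-tissue conductivity, S/m.
#' @param TR Wall-thickness to lumen-diameter ratio.
#' @param gw A [guidewire()].
#' @return Lumen diameter in metres.
#' @examples
#' gw <- guidewire("5-5-5")
#' G <- lumen_conductance(1.0, 4e-3, gw) + wall_conductance(0.4, 4e-3, 0.5, gw)
#' invert_diameter_closed_form(1 / G, 1.0, 0.4, 0.5, gw) * 1e3  # 4 mm
#' @export
invert_diameter_closed_form <- function(R_ohm, sigma_b, sigma_t, TR, gw) {
  stopifnot(inherits(gw, "guidewire"))
  if (R_ohm <= 0) stop("R must be positive", call. = FALSE)
  if (sigma_b <= 0) stop("fluid conductivity must be positive", call. = FALSE)
  if (sigma_t < 0 || TR < 0) stop("sigma_t and TR must be >= 0", call. = FALSE)
  d_b <- sqrt((4 * gw$L_m + pi * R_ohm * sigma_b * gw$d_gw_m^2) /
                (pi * R_ohm * (sigma_b + 4 * sigma_t * TR * (1 + TR))))
  if (d_b < gw$d_gw_m) {
    stop("measurement inconsistent with geometry (d_b < guidewire diameter)",
         call. = FALSE)
  }
  d_b
}

#' Forward conductance decomposition of a measurement scenario
#'
#' Composes the total measured conductance `G = G_b + G_t + G_bath = 1/R`
#' from the lumen, wall and surrounding-medium pathways. The surrounding-bath
#' term is the radial field-kernel integral of [parallel_conductance_model()].
#'
#' @param scn A [vessel_scenario()].
#' @param sigma_b Lumen-fluid conductivity, S/m.
#' @param sigma_t Wall-tissue conductivity, S/m.
#' @param gw A [guidewire()].
#' @param kernel A [field_kernel()]; only used when the scenario has a bath.
#' @return An object of class `conductance_decomposition`: list with `G`,
#'   `G_b`, `G_t`, `G_bath` (siemens) and `R` (ohms).
#' @export
total_resistance_forward <- function(scn, sigma_b, sigma_t, gw,
                                     kernel = field_kernel()) {
  stopifnot(inherits(scn, "vessel_scenario"), inherits(gw, "guidewire"))
  G_b <- lumen_conductance(sigma_b, scn$d_b_m, gw)
  G_t <- wall_conductance(sigma_t, scn$d_b_m, scn$TR, gw)
  G_bath <- bath_conductance(scn, gw, kernel)
  G <- G_b + G_t + G_bath
  structure(
    list(G = G, G_b = G_b, G_t = G_t, G_bath = G_bath, R = 1 / G),
    class = "conductance_decomposition"
  )
}

#' @export
print.conductance_decomposition <- function(x, ...) {
  cat(sprintf(
    "<conductance decomposition>  G = %.4g mS (lumen %.4g + wall %.4g + bath %.4g), R = %.4g ohm\n",
    x$G * 1e3, x$G_b * 1e3, x$G_t * 1e3, x$G_bath * 1e3, x$R))
  invisible(x)
}

#' Check the cylindricity (axially uniform field) assumption
#'
#' The excitation field is approximately axially uniform across the sensing
#' segment only when the excitation separation is at least twice the lumen
#' diameter. Returns `"ok"` or `"warning"` (with an R warning emitted); never
#' an error, since measurements remain interpretable with degraded accuracy.
#'
#' @param gw A [guidewire()].
#' @param d_b_m Lumen diameter, m.
#' @return `"ok"` or `"warning"`, invisibly carrying attribute `ratio`.
#' @export
cylindricity_check <- function(gw, d_b_m) {
  stopifnot(inherits(gw, "guidewire"))
  ratio <- gw$d_m / d_b_m
  status <- if (ratio < 2) "warning" else "ok"
  if (status == "warning") {
    warning(sprintf(
      "excitation separation (%.3g mm) is below twice the lumen diameter (%.3g mm): field may not be cylindrical",
      gw$d_m * 1e3, d_b_m * 1e3), call. = FALSE)
  }
  structure(status, ratio = ratio)
}
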