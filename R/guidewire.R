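#' Tetrapolar sizing guidewire geometry
#'
#' Describes the electrode geometry of a conductance guidewire: an outer pair
#' of excitation electrodes a distance `d` apart (center to center) and an
#' inner pair of sensing electrodes a distance `L` apart, mounted on a shaft
#' of diameter `d_gw`. The two commercial spacings are `"5-5-5"` (peripheral,
#' 0.035 inch shaft) and `"2-2-2"` (coronary, 0.014 inch shaft), where the
#' label gives the inter-electrode gaps in mm. Center-to-center separations
#' add one electrode width per gap, so with the default 1 mm electrodes the
#' sensing separation is L = 6 mm (5-5-5) or 3 mm (2-2-2) and the excitation
#' separation is d = 18 mm or 9 mm.
#'
#' @param label `"5-5-5"`, `"2-2-2"`, or `"custom"`.
#' @param electrode_width_mm Axial electrode width in mm (default 1).
#' @param L_m,d_m,d_gw_m For `label = "custom"`: sensing separation,
#'   excitation separation and shaft diameter, all in metres.
#' @return An object of class `guidewire` with fields `label`, `gap_mm`,
#'   `electrode_width_mm`, `L_m`, `d_m`, `d_gw_m`.
#' @examples
#' gw <- guidewire("5-5-5")
#' gw$L_m    # 0.006
#' gw$d_m    # 0.018
#' @export
guidewire <- function(label = c("5-5-5", "2-2-2", "custom"),
                      electrode_width_mm = 1,
                      L_m = NULL, d_m = NULL, d_gw_m = NULL) {
  label <- match.arg(label)
  if (label == "custom") {
    if (is.null(L_m) || is.null(d_m) || is.null(d_gw_m)) {
      stop("custom guidewire requires L_m, d_m and d_gw_m", call. = FALSE)
    }
    gap_mm <- NA_real_
  } else {
    gap_mm <- if (label == "5-5-5") 5 else 2
    pitch_mm <- gap_mm + electrode_width_mm   # center-to-center per gap
    L_m <- pitch_mm * 1e-3
    d_m <- 3 * pitch_mm * 1e-3
    # 0.035" and 0.014" shafts, exact inch conversion
    d_gw_m <- if (label == "5-5-5") 0.035 * 0.0254 else 0.014 * 0.0254
  }
  if (L_m <= 0) stop("sensing separation L must be positive", call. = FALSE)
  if (d_m <= L_m) stop("excitation separation d must exceed L", call. = FALSE)
  if (d_gw_m <= 0) stop("guidewire diameter must be positive", call. = FALSE)
  structure(
    list(label = label, gap_mm = gap_mm,
         electrode_width_mm = electrode_width_mm,
         L_m = L_m, d_m = d_m, d_gw_m = d_gw_m),
    class = "guidewire"
  )
}

#' @export
print.guidewire <- function(x, ...) {
  cat(sprintf("<guidewire %s>  L = %g mm, d = %g mm, shaft = %.4g mm\n",
              x$label, x$L_m * 1e3, x$d_m * 1e3, x$d_gw_m * 1e3))
  invisible(x)
}

#' Vessel-and-surroundings measurement scenario
#'
#' A cylindrical three-layer description of the measurement site: a lumen of
#' diameter `d_b` carrying conductive fluid, a vessel wall of thickness
#' `t_w = TR * d_b`, and a surrounding conducting medium (tissue or saline
#' bath) of radial extent `bath_thickness` beyond the wall.
#'
#' @param d_b_m Lumen diameter in metres.
#' @param TR Wall-thickness-to-lumen-diameter ratio (dimensionless, >= 0).
#'   Give either `TR` or `t_w_m`.
#' @param t_w_m Wall thickness in metres (alternative to `TR`).
#' @param bath_thickness_m Radial extent of the surrounding medium beyond the
#'   wall outer surface, in metres (default 0: vessel suspended in air).
#' @param sigma_bath Conductivity of the surrounding medium in S/m.
#' @return An object of class `vessel_scenario`.
#' @examples
#' vessel_scenario(3.2e-3, TR = 0.79, bath_thickness_m = 20.868e-3,
#'                 sigma_bath = 0.18)
#' @export
vessel_scenario <- function(d_b_m, TR = NULL, t_w_m = NULL,
                            bath_thickness_m = 0, sigma_bath = 0) {
  if (d_b_m <= 0) stop("lumen diameter must be positive", call. = FALSE)
  if (is.null(TR) && is.null(t_w_m)) {
    stop("supply TR or t_w_m", call. = FALSE)
  }
  if (is.null(TR)) TR <- t_w_m / d_b_m
  if (is.null(t_w_m)) t_w_m <- TR * d_b_m
  if (TR < 0) stop("TR must be non-negative", call. = FALSE)
  if (abs(t_w_m - TR * d_b_m) > 1e-9 * max(d_b_m, t_w_m)) {
    stop("inconsistent TR and t_w_m", call. = FALSE)
  }
  if (bath_thickness_m < 0) stop("bath thickness must be >= 0", call. = FALSE)
  if (sigma_bath < 0) stop("bath conductivity must be >= 0", call. = FALSE)
  structure(
    list(d_b_m = d_b_m, t_w_m = t_w_m, TR = TR,
         bath_thickness_m = bath_thickness_m, sigma_bath = sigma_bath),
    class = "vessel_scenario"
  )
}

#' @export
print.vessel_scenario <- function(x, ...) {
  cat(sprintf(
    "<vessel scenario>  d_b = %.3g mm, t_w = %.3g mm (TR = %.3g), bath %.3g mm @ %.3g S/m\n",
    x$d_b_m * 1e3, x$t_w_m * 1e3, x$TR, x$bath_thickness_m * 1e3, x$sigma_bath))
  invisible(x)
}
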