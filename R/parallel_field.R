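#' Radial field-decay kernel for the surrounding-medium conductance
#'
#' The current escaping the lumen samples the surrounding layers with a
#' weight that decays with radial distance from the lumen wall (the
#' excitation field falls off away from the electrodes). The kernel gives
#' that weight `w(x)` for distance `x >= 0` measured from the lumen wall:
#' `w(0) = 1`, non-increasing, `w` in `[0, 1]`. The surrounding-medium
#' integral therefore starts at weight `w(t_w)`: a thicker vessel wall
#' pushes the bath into an already-decayed region of the field, which is
#' why the parallel-conductance fraction falls as TR rises.
#'
#' Kinds:
#' * `"exponential"` (default): `w(x) = exp(-x / scale)`; the scale is
#'   typically fitted to a measured bath-thickness series with
#'   [fit_kernel_scale()].
#' * `"dipole"`: `w(x) = (1 + x / scale)^-3`, the far-field decay of a
#'   source-sink electrode pair.
#' * `"uniform"`: `w(x) = 1` (no decay; the homogeneous-annulus limit).
#'
#' @param kind Kernel family.
#' @param scale_m Radial decay length, m (ignored for `"uniform"`).
#' @return An object of class `field_kernel` with a `weight(x)` function.
#' @export
field_kernel <- function(kind = c("exponential", "dipole", "uniform"),
                         scale_m = 5e-3) {
  kind <- match.arg(kind)
  if (kind != "uniform" && scale_m <= 0) {
    stop("kernel scale must be positive", call. = FALSE)
  }
  weight <- switch(kind,
    exponential = function(x) exp(-x / scale_m),
    dipole = function(x) (1 + x / scale_m)^(-3),
    uniform = function(x) rep(1, length(x))
  )
  structure(list(kind = kind, scale_m = scale_m, weight = weight),
            class = "field_kernel")
}

#' @export
print.field_kernel <- function(x, ...) {
  cat(sprintf("<field kernel>  %s%s\n", x$kind,
              if (x$kind == "uniform") ""
              else sprintf(", scale = %.3g mm", x$scale_m * 1e3)))
  invisible(x)
}

#' Conductance of the surrounding medium (bath / perivascular tissue)
#'
#' Kernel-weighted annular-shell integral over the surrounding medium,
#' from the wall outer surface out to the bath extent, with the kernel
#' distance measured from the lumen wall:
#' \deqn{G_{bath} = \frac{2 \pi \sigma_{bath}}{L}
#'       \int_0^{t_{bath}} w(t_w + x) (r_{wo} + x)\, dx}
#' where `r_wo = d_b/2 + t_w` is the wall outer radius. Evaluated by
#' fixed-step composite Simpson quadrature.
#'
#' @param scn A [vessel_scenario()] (carries bath thickness and
#'   conductivity).
#' @param gw A [guidewire()].
#' @param kernel A [field_kernel()].
#' @param n_steps Number of radial quadrature steps (default 1000; rounded
#'   up to even).
#' @return Conductance in siemens.
#' @export
bath_conductance <- function(scn, gw, kernel = field_kernel(),
                             n_steps = 1000) {
  stopifnot(inherits(scn, "vessel_scenario"), inherits(gw, "guidewire"),
            inherits(kernel, "field_kernel"))
  t_bath <- scn$bath_thickness_m
  if (t_bath == 0 || scn$sigma_bath == 0) return(0)
  n <- n_steps + n_steps %% 2
  r_wo <- scn$d_b_m / 2 + scn$t_w_m
  x <- seq(0, t_bath, length.out = n + 1)
  fx <- kernel$weight(scn$t_w_m + x) * (r_wo + x)
  h <- t_bath / n
  simpson_w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  integral <- h / 3 * sum(simpson_w * fx)
  2 * pi * scn$sigma_bath / gw$L_m * integral
}

#' Parallel (wall + surrounding medium) conductance
#'
#' The total parallel pathway: the vessel-wall annulus plus the
#' kernel-weighted surrounding medium. Equals [wall_conductance()] exactly
#' when the bath is absent.
#'
#' @param scn A [vessel_scenario()].
#' @param sigma_t Wall-tissue conductivity, S/m.
#' @param gw A [guidewire()].
#' @param kernel A [field_kernel()].
#' @param n_steps Radial quadrature steps.
#' @return Conductance in siemens.
#' @export
parallel_conductance_model <- function(scn, sigma_t, gw,
                                       kernel = field_kernel(),
                                       n_steps = 1000) {
  wall_conductance(sigma_t, scn$d_b_m, scn$TR, gw) +
    bath_conductance(scn, gw, kernel, n_steps)
}

#' Bath-thickness conductance series
#'
#' Total measured conductance as a function of the radial extent of the
#' surrounding bath, at one or more frequencies. The zero-thickness entry
#' (vessel suspended in air) is the baseline lumen + wall conductance.
#'
#' @param bath_thicknesses_m Bath thicknesses, m (must include 0 for
#'   [bath_fraction_empirical()]).
#' @param G_total_s Matrix of total conductances, siemens; rows =
#'   thicknesses, columns = frequencies.
#' @param frequencies_hz Frequencies, Hz.
#' @return An object of class `bath_series`.
#' @seealso [exvivo_bath_series()] for the packaged ex-vivo series.
#' @export
bath_series <- function(bath_thicknesses_m, G_total_s, frequencies_hz) {
  G_total_s <- as.matrix(G_total_s)
  if (nrow(G_total_s) != length(bath_thicknesses_m) ||
      ncol(G_total_s) != length(frequencies_hz)) {
    stop("G_total_s must be thicknesses x frequencies", call. = FALSE)
  }
  if (is.unsorted(bath_thicknesses_m, strictly = TRUE)) {
    stop("bath thicknesses must be strictly increasing", call. = FALSE)
  }
  structure(
    list(bath_thicknesses_m = as.numeric(bath_thicknesses_m),
         G_total_s = unname(G_total_s),
         frequencies_hz = as.numeric(frequencies_hz)),
    class = "bath_series"
  )
}

#' Packaged ex-vivo bath-thickness series
#'
#' Total conductance of a bovine carotid artery (lumen diameter about
#' 3.2 mm, TR about 0.79, 0.45% saline perfusate, 5-5-5 guidewire) immersed
#' in a 0.1% saline bath whose radial extent was varied from 0 to about
#' 20.9 mm, at 10, 20 and 40 kHz.
#'
#' @return A [bath_series()].
#' @export
exvivo_bath_series <- function() {
  path <- system.file("extdata", "exvivo_bath_series.csv",
                      package = "condsize", mustWork = TRUE)
  read_bath_series_csv(path)
}

#' Empirical parallel-conductance fraction of a bath series
#'
#' The fraction of the total conductance carried by the surrounding bath,
#' referenced to the largest bath measured:
#' \deqn{frac(t, f) = \frac{G_{total}(t, f) - G_{total}(0, f)}
#'                         {G_{total}(t_{max}, f)}}
#'
#' @param series A [bath_series()] including the zero-thickness baseline.
#' @return Matrix of fractions in `[0, 1]` (thicknesses x frequencies) with
#'   thickness (mm) and frequency (Hz) dimnames.
#' @examples
#' round(100 * bath_fraction_empirical(exvivo_bath_series()), 2)
#' @export
bath_fraction_empirical <- function(series) {
  stopifnot(inherits(series, "bath_series"))
  t <- series$bath_thicknesses_m
  if (min(t) != 0) {
    stop("series must include the zero-bath baseline", call. = FALSE)
  }
  G <- series$G_total_s
  G0 <- G[which.min(t), , drop = TRUE]
  Gmax <- G[which.max(t), , drop = TRUE]
  frac <- sweep(sweep(G, 2, G0, "-"), 2, Gmax, "/")
  dimnames(frac) <- list(format(t * 1e3), format(series$frequencies_hz))
  frac
}

#' Model-predicted parallel-conductance fraction versus TR
#'
#' Forward-evaluates the three-pathway conductance model over a grid of bath
#' thicknesses for each wall-thickness ratio and reports the same
#' largest-bath-referenced fraction as [bath_fraction_empirical()]. Thinner
#' walls (smaller TR) leave more current to the surrounding medium, so the
#' fraction decreases with TR at fixed bath thickness.
#'
#' @param TR Vector of wall-thickness ratios.
#' @param bath_grid_m Bath thicknesses, m (should include 0).
#' @param d_b_m Lumen diameter, m.
#' @param sigma_b,sigma_t,sigma_bath Conductivities of lumen fluid, wall and
#'   bath, S/m.
#' @param gw A [guidewire()].
#' @param kernel A [field_kernel()].
#' @return Matrix of fractions (TR x bath thickness).
#' @export
bath_fraction_model <- function(TR, bath_grid_m, d_b_m, sigma_b, sigma_t,
                                sigma_bath, gw, kernel = field_kernel()) {
  out <- vapply(TR, function(tr) {
    G <- vapply(bath_grid_m, function(tb) {
      scn <- vessel_scenario(d_b_m, TR = tr, bath_thickness_m = tb,
                             sigma_bath = sigma_bath)
      total_resistance_forward(scn, sigma_b, sigma_t, gw, kernel)$G
    }, numeric(1))
    (G - G[which.min(bath_grid_m)]) / G[which.max(bath_grid_m)]
  }, numeric(length(bath_grid_m)))
  out <- t(out)
  dimnames(out) <- list(format(TR), format(bath_grid_m * 1e3))
  out
}

#' Fit the field-kernel decay scale to a measured bath series
#'
#' One-parameter least squares: finds the kernel scale whose predicted
#' bath conductance `G_bath(t)` best matches the measured increase
#' `G_total(t) - G_total(0)` over the bath-thickness series.
#'
#' @param series A [bath_series()] with at least 3 thicknesses including 0.
#' @param scn A [vessel_scenario()] template giving the vessel geometry and
#'   bath conductivity (its own bath thickness is ignored).
#' @param gw A [guidewire()].
#' @param frequency_hz Which frequency column of the series to fit
#'   (default: the first).
#' @param kind Kernel family to fit.
#' @return The fitted [field_kernel()], with attributes `residuals_s`
#'   (per-thickness misfit, siemens) and `rms_s`.
#' @export
fit_kernel_scale <- function(series, scn, gw,
                             frequency_hz = series$frequencies_hz[1],
                             kind = c("exponential", "dipole")) {
  stopifnot(inherits(series, "bath_series"))
  kind <- match.arg(kind)
  j <- match(frequency_hz, series$frequencies_hz)
  if (is.na(j)) stop("frequency not in series", call. = FALSE)
  t <- series$bath_thicknesses_m
  if (length(t) < 3) stop("need at least 3 bath thicknesses", call. = FALSE)
  G <- series$G_total_s[, j]
  if (min(t) != 0) stop("series must include the zero-bath baseline",
                        call. = FALSE)
  G_bath_meas <- G - G[which.min(t)]
  if (diff(range(G)) == 0) {
    stop("degenerate series: conductance does not vary", call. = FALSE)
  }
  predict_bath <- function(scale_m) {
    k <- field_kernel(kind, scale_m)
    vapply(t, function(tb) {
      s <- vessel_scenario(scn$d_b_m, TR = scn$TR, bath_thickness_m = tb,
                           sigma_bath = scn$sigma_bath)
      bath_conductance(s, gw, k)
    }, numeric(1))
  }
  obj <- function(log_scale) {
    sum((predict_bath(exp(log_scale)) - G_bath_meas)^2)
  }
  opt <- stats::optimize(obj, interval = log(c(1e-5, 1)))
  scale_hat <- exp(opt$minimum)
  res <- predict_bath(scale_hat) - G_bath_meas
  out <- field_kernel(kind, scale_hat)
  attr(out, "residuals_s") <- res
  attr(out, "rms_s") <- sqrt(mean(res^2))
  out
}
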