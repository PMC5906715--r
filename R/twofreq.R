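#' Build an impedance spectrum from voltage measurements
#'
#' Converts raw (frequency, rms current, rms voltage) triples to impedance
#' magnitudes `|Z| = V / I`.
#'
#' @param frequency_hz Excitation frequencies, Hz.
#' @param current_a_rms Excitation currents, A rms (recycled if length 1).
#' @param voltage_v_rms Measured sensing voltages, V rms.
#' @return A data frame of class `spectrum` with columns `frequency_hz`,
#'   `current_a_rms`, `voltage_v_rms`, `z_ohm`.
#' @examples
#' impedance_from_voltage(10e3, 100e-6, 52.47e-3)$z_ohm  # 524.7
#' @export
impedance_from_voltage <- function(frequency_hz, current_a_rms, voltage_v_rms) {
  n <- max(length(frequency_hz), length(voltage_v_rms))
  frequency_hz <- rep_len(frequency_hz, n)
  current_a_rms <- rep_len(current_a_rms, n)
  voltage_v_rms <- rep_len(voltage_v_rms, n)
  if (any(!is.finite(frequency_hz)) || any(frequency_hz <= 0)) {
    stop("frequencies must be positive", call. = FALSE)
  }
  if (any(!is.finite(current_a_rms)) || any(current_a_rms <= 0)) {
    stop("excitation current must be positive", call. = FALSE)
  }
  if (any(!is.finite(voltage_v_rms)) || any(voltage_v_rms < 0)) {
    stop("voltages must be non-negative", call. = FALSE)
  }
  out <- data.frame(frequency_hz = frequency_hz,
                    current_a_rms = current_a_rms,
                    voltage_v_rms = voltage_v_rms,
                    z_ohm = voltage_v_rms / current_a_rms)
  class(out) <- c("spectrum", "data.frame")
  out
}

#' Two-frequency series-RC resistance extraction
#'
#' Electrode polarization is modelled as a capacitance in series with the
#' ohmic system resistance, so the impedance magnitude obeys
#' \deqn{|Z(\omega)|^2 = R^2 + 1/(\omega C)^2.}
#' Two magnitudes at distinct frequencies determine `(R, C)` exactly by a
#' linear solve in \eqn{(R^2, 1/C^2)}. `|Z|` must not increase with
#' frequency; a flat pair is purely ohmic (`C` unbounded, reported as `Inf`).
#'
#' @param m1,m2 Single-row `spectrum` data frames (or any lists carrying
#'   `frequency_hz` and `z_ohm`), with `m1$frequency_hz < m2$frequency_hz`.
#' @return An object of class `twofreq_fit`: list with `R_ohm`, `C_f`
#'   (farads; `Inf` when unbounded), and `pair_hz`.
#' @examples
#' s <- impedance_from_voltage(c(10e3, 100e3), 100e-6,
#'                             c(52.472e-3, 50.0253e-3))
#' fit_series_rc(s[1, ], s[2, ])$R_ohm  # ~500
#' @export
fit_series_rc <- function(m1, m2) {
  f1 <- m1$frequency_hz; f2 <- m2$frequency_hz
  z1 <- m1$z_ohm;        z2 <- m2$z_ohm
  if (!(f1 < f2)) stop("m1 must be the lower frequency", call. = FALSE)
  if (z1 <= 0 || z2 <= 0) stop("impedance magnitudes must be positive",
                               call. = FALSE)
  w1 <- 2 * pi * f1; w2 <- 2 * pi * f2
  if (z2 > z1 * (1 + 1e-12)) {
    stop("|Z| increases with frequency: series-RC model violated",
         call. = FALSE)
  }
  # |Z|^2 = a + b / w^2 with a = R^2, b = 1/C^2
  b <- (z1^2 - z2^2) / (1 / w1^2 - 1 / w2^2)
  a <- z1^2 - b / w1^2
  if (a < 0) stop("negative R^2: series-RC model violated", call. = FALSE)
  C <- if (b <= 0) Inf else 1 / sqrt(b)
  structure(list(R_ohm = sqrt(a), C_f = C, pair_hz = c(f1, f2)),
            class = "twofreq_fit")
}

#' @export
print.twofreq_fit <- function(x, ...) {
  cat(sprintf("<two-frequency fit>  R = %.6g ohm, C = %s, pair = %s kHz\n",
              x$R_ohm,
              if (is.finite(x$C_f)) sprintf("%.4g nF", x$C_f * 1e9)
              else "unbounded (ohmic)",
              paste(format(x$pair_hz / 1e3), collapse = " / ")))
  invisible(x)
}

#' Multi-frequency series-RC fit with per-pair diagnostics
#'
#' Least-squares generalization of [fit_series_rc()] over a whole spectrum:
#' fits `|Z|^2 = R^2 + (1/C^2) / omega^2` by ordinary least squares in the
#' transformed variables, and also tabulates the per-pair `R` extracted from
#' every two-frequency combination (the grouped-pairs diagnostic: on clean
#' series-RC data all pairs agree).
#'
#' @param spectrum A `spectrum` data frame with at least two distinct
#'   frequencies.
#' @return A `twofreq_fit` with extra fields `pairs` (data frame
#'   `f_low_hz`, `f_high_hz`, `R_ohm`, `C_f`) and `rms_residual_ohm`
#'   (root-mean-square misfit of `|Z|`).
#' @export
fit_series_rc_multi <- function(spectrum) {
  spectrum <- spectrum[order(spectrum$frequency_hz), , drop = FALSE]
  f <- spectrum$frequency_hz
  z <- spectrum$z_ohm
  if (length(unique(f)) < 2) {
    stop("need at least two distinct frequencies", call. = FALSE)
  }
  x <- 1 / (2 * pi * f)^2
  fit <- stats::lm(I(z^2) ~ x)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  # physical constraints: 0 <= R^2 <= min |Z|^2 and 1/C^2 >= 0; on noisy
  # data the unconstrained optimum can sit just outside, so project back
  # onto the boundary and refit the other coefficient
  a_max <- min(z)^2
  if (b < 0) {
    b <- 0
    a <- min(mean(z^2), a_max)
  } else if (a > a_max) {
    a <- a_max
    b <- max(0, sum(x * (z^2 - a)) / sum(x^2))
  }
  if (a < 0) stop("negative R^2: series-RC model violated", call. = FALSE)
  C <- if (b <= 0) Inf else 1 / sqrt(b)
  z_hat <- sqrt(pmax(a + b * x, 0))
  combs <- utils::combn(seq_along(f), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    pf <- tryCatch(fit_series_rc(spectrum[i, ], spectrum[j, ]),
                   error = function(e) NULL)
    if (is.null(pf)) return(NULL)
    data.frame(f_low_hz = f[i], f_high_hz = f[j],
               R_ohm = pf$R_ohm, C_f = pf$C_f)
  }))
  structure(
    list(R_ohm = sqrt(a), C_f = C, pair_hz = range(f), pairs = pairs,
         rms_residual_ohm = sqrt(mean((z - z_hat)^2))),
    class = "twofreq_fit"
  )
}
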