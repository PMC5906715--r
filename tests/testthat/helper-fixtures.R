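# shared fixtures: exact series-RC spectra and standard scenarios

rc_spectrum <- function(R_ohm, C_f, frequencies_hz = c(10, 20, 40, 60, 80) * 1e3,
                        current_a = 100e-6, noise_cv = 0) {
  z <- sqrt(R_ohm^2 + 1 / (2 * pi * frequencies_hz * C_f)^2)
  v <- current_a * z
  if (noise_cv > 0) v <- v * (1 + stats::rnorm(length(v), sd = noise_cv))
  impedance_from_voltage(frequencies_hz, current_a, v)
}

gw555 <- guidewire("5-5-5")
gw222 <- guidewire("2-2-2")
saline_tbl <- saline_conductivity_table()

# reference ex-vivo total-conductance series (mS), thicknesses x frequencies
ref_bath_G_mS <- matrix(
  c(4.6579, 6.4886, 8.3578, 11.3277, 12.8155,
    4.6579, 6.6399, 8.6467, 11.9102, 13.4538,
    4.7826, 6.6144, 7.9449, 11.6696, 12.4735),
  ncol = 3,
  dimnames = list(NULL, c("10", "20", "40")))
ref_bath_t_mm <- c(0, 2.118, 4.868, 11.668, 20.868)
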