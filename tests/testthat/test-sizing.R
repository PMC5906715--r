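test_that("zero-bath estimate agrees with the closed-form inversion", {
  d_true <- 4e-3
  sb <- conductivity_lookup(saline_tbl, 10e3, d_true)
  cfg <- sim_config(vessel_scenario(d_true, TR = 0.5), sb, 0.4, gw = gw555)
  sp <- simulate_spectrum(cfg)
  est <- estimate_diameter(sp, saline_tbl, sigma_t = 0.4, TR = 0.5,
                           gw = gw555)
  expect_true(est$converged)
  expect_equal(est$d_b_m, d_true, tolerance = 0.02)
  closed <- invert_diameter_closed_form(est$R_ohm, est$sigma_b_used, 0.4,
                                        0.5, gw555)
  expect_equal(est$d_b_m, closed, tolerance = 1e-4)
  expect_lte(est$mismatch, 0.02)
})

test_that("known-kernel bath scenario is recovered without noise", {
  kernel <- field_kernel("exponential", 5e-3)
  d_true <- 4e-3
  sb <- conductivity_lookup(saline_tbl, 10e3, d_true)
  scn <- vessel_scenario(d_true, TR = 0.5, bath_thickness_m = 10e-3,
                         sigma_bath = 0.18)
  cfg <- sim_config(scn, sb, 0.4, gw = gw555, kernel = kernel)
  est <- estimate_diameter(simulate_spectrum(cfg), saline_tbl, 0.4, 0.5,
                           bath_thickness_m = 10e-3, sigma_bath = 0.18,
                           gw = gw555, kernel = kernel)
  expect_true(est$converged)
  expect_equal(est$d_b_m, d_true, tolerance = 0.02)
  expect_gt(est$decomposition$G_bath, 0)
})

test_that("noiseless randomized scenarios are recovered within tolerance", {
  set.seed(19)
  for (k in 1:30) {
    d <- runif(1, 2, 8) * 1e-3
    tr <- runif(1, 0.16, 0.9)
    st <- runif(1, 0.2, 0.6)
    gw <- if (d < 4e-3) gw222 else gw555
    sb <- conductivity_lookup(saline_tbl, 10e3, d)
    cfg <- sim_config(vessel_scenario(d, TR = tr), sb, st, gw = gw)
    est <- estimate_diameter(simulate_spectrum(cfg), saline_tbl, st, tr,
                             gw = gw)
    expect_equal(est$d_b_m, d, tolerance = 0.02)
  }
})

test_that("1% voltage noise leaves small bias and scatter; estimates are deterministic", {
  sb <- conductivity_lookup(saline_tbl, 10e3, 4e-3)
  rel_err <- vapply(1:50, function(i) {
    cfg <- sim_config(vessel_scenario(4e-3, TR = 0.5), sb, 0.4, gw = gw555,
                      noise_cv = 0.01, seed = 500 + i)
    estimate_diameter(simulate_spectrum(cfg), saline_tbl, 0.4, 0.5,
                      gw = gw555)$d_b_m / 4e-3 - 1
  }, numeric(1))
  expect_lt(abs(mean(rel_err)), 0.01)
  expect_lt(sd(rel_err), 0.03)
  cfg <- sim_config(vessel_scenario(4e-3, TR = 0.5), sb, 0.4, gw = gw555,
                    noise_cv = 0.01, seed = 77)
  e1 <- estimate_diameter(simulate_spectrum(cfg), saline_tbl, 0.4, 0.5,
                          gw = gw555)
  e2 <- estimate_diameter(simulate_spectrum(cfg), saline_tbl, 0.4, 0.5,
                          gw = gw555)
  expect_identical(e1$d_b_m, e2$d_b_m)
})

test_that("diameter scatter grows with the voltage-noise level", {
  sb <- conductivity_lookup(saline_tbl, 10e3, 4e-3)
  sds <- vapply(c(0.005, 0.01, 0.02), function(cv) {
    sd(vapply(1:40, function(i) {
      cfg <- sim_config(vessel_scenario(4e-3, TR = 0.5), sb, 0.4,
                        gw = gw555, noise_cv = cv, seed = 900 + i)
      estimate_diameter(simulate_spectrum(cfg), saline_tbl, 0.4, 0.5,
                        gw = gw555)$d_b_m
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("infeasible and unsolvable measurements raise informative errors", {
  # absurdly low total conductance: even the smallest candidate lumen
  # cannot account for it
  sp <- impedance_from_voltage(c(10e3, 20e3), 100e-6, c(2, 1.9999))
  expect_error(
    estimate_diameter(sp, saline_tbl, 0.4, 0.5, gw = gw555),
    "no solution|infeasible")
  expect_error(
    estimate_diameter(sp, saline_tbl, 0.4, 0.5, gw = gw555, tol = 0.7),
    "tol")
  # spectrum missing the working pair
  sp2 <- impedance_from_voltage(c(30e3, 40e3), 100e-6, c(0.05, 0.049))
  expect_error(estimate_diameter(sp2, saline_tbl, 0.4, 0.5, gw = gw555),
               "working frequency pair")
})

test_that("sensitivity to assumed wall parameters matches the closed form", {
  # frozen closed-form evaluations at sigma_b = 1.4, sigma_t = 0.4, 4 mm
  expect_equal(sensitivity_analysis(1.4, 0.4, 0.2, "t_w"), -2.487,
               tolerance = 1e-3)
  expect_equal(sensitivity_analysis(1.4, 0.4, 0.6, "t_w"), -6.819,
               tolerance = 1e-3)
  expect_equal(sensitivity_analysis(1.4, 0.4, 0.2, "sigma_t"), -2.085,
               tolerance = 1e-3)
  expect_equal(sensitivity_analysis(1.4, 0.4, 0.6, "sigma_t"), -4.854,
               tolerance = 1e-3)
  expect_equal(sensitivity_analysis(1.4, 0.4, 0.4, "t_w", fraction = 0), 0)
})

test_that("sensitivity bands over TR 0.2-0.6 stay within the reported ranges", {
  tr_grid <- seq(0.2, 0.6, by = 0.05)
  s_tw <- abs(vapply(tr_grid, function(tr)
    sensitivity_analysis(1.4, 0.4, tr, "t_w"), numeric(1)))
  s_st <- abs(vapply(tr_grid, function(tr)
    sensitivity_analysis(1.4, 0.4, tr, "sigma_t"), numeric(1)))
  expect_true(all(s_tw >= 1 & s_tw <= 9))
  expect_true(all(s_st >= 1.5 & s_st <= 6))
  # both sensitivities grow with TR (thicker walls dominate the pathway)
  expect_true(all(diff(s_tw) > 0))
  expect_true(all(diff(s_st) > 0))
})
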