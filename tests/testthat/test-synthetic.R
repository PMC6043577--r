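test_that("two-state generator reproduces the reference design shape", {
  truth <- generate_two_state_system(seed = 1)
  expect_length(truth$dw_ppm, 22)
  expect_equal(truth$kinetics$temp_k, c(298.0, 300.5, 303.0, 305.5, 308.0))
  expect_equal(truth$fields, c(500, 700))
  expect_equal(dim(truth$r20), c(22, 2))
  tab <- generate_dispersion_intensities(truth, seed = 1)
  # 12 cpmg points + 1 reference row per residue/field/temperature
  expect_equal(nrow(tab), 22 * 2 * 5 * 13)
})

test_that("generated kinetics are thermodynamically self-consistent", {
  truth <- generate_two_state_system(seed = 2)
  kin <- truth$kinetics
  # ln(Ke) and ln(k_AB/T) exactly linear in 1/T
  expect_equal(unname(residuals(lm(log(kin$ke) ~ I(1 / kin$temp_k)))),
               rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(residuals(
    lm(log(kin$k_ab / kin$temp_k) ~ I(1 / kin$temp_k)))),
    rep(0, 5), tolerance = 1e-12)
  # population anchor: Ke(298) = 0.085/0.915
  expect_equal(kin$p_b[1], 0.085, tolerance = 1e-12)
  expect_equal(kin$k_ex[1], 812, tolerance = 1e-12)
})

test_that("zero excited-state enthalpy gives a temperature-independent Ke", {
  tt <- default_thermo_truth()
  tt$dh_ba <- 0
  kin <- kinetics_from_thermo(tt, c(298, 303, 308))
  expect_equal(diff(range(kin$ke)), 0, tolerance = 1e-14)
})

test_that("generator rejects unidentifiable or unphysical designs", {
  tt <- default_thermo_truth(pb_298 = 0.6)
  expect_error(generate_two_state_system(thermo_truth = tt), "p_B >= 0.5")
  expect_error(generate_two_state_system(temperatures = c(400, 410)),
               "250-350")
  expect_error(generate_two_state_system(temperatures = c(308, 298)),
               "increasing")
})

test_that("same seed regenerates bit-identical data", {
  t1 <- generate_two_state_system(seed = 9)
  t2 <- generate_two_state_system(seed = 9)
  expect_identical(t1, t2)
  d1 <- generate_dispersion_intensities(t1, seed = 4)
  d2 <- generate_dispersion_intensities(t2, seed = 4)
  expect_identical(d1, d2)
  r1 <- generate_relaxation_series(1.5, c(0.05, 0.1, 0.2), noise_fraction
                                   = 0.02, seed = 5)
  r2 <- generate_relaxation_series(1.5, c(0.05, 0.1, 0.2), noise_fraction
                                   = 0.02, seed = 5)
  expect_identical(r1, r2)
})

test_that("noiseless intensities invert back to the forward-model rates", {
  truth <- generate_two_state_system(n_residues = 2, noise_fraction = 0,
                                     seed = 6)
  tab <- generate_dispersion_intensities(truth, seed = 6)
  disp <- r2eff_from_intensities(tab)
  kin <- truth$kinetics
  for (fld in truth$fields) {
    expected <- bm_r2eff(kin$k_ab[1], kin$k_ba[1],
                         ppm_to_rad(truth$dw_ppm[1], fld),
                         truth$r20[1, as.character(fld)],
                         default_nu_cpmg())
    got <- disp$r2eff[disp$residue_id == "R01" & disp$field_mhz == fld &
                        disp$temp_k == kin$temp_k[1]]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("incompatible CPMG frequencies are rejected with the nearest valid value", {
  truth <- generate_two_state_system(n_residues = 1, seed = 1)
  expect_error(generate_dispersion_intensities(truth, nu_cpmg = 70),
               "closest valid")
})

test_that("relaxation series generator matches hand values", {
  s <- generate_relaxation_series(1.0, 0, i0 = 123)
  expect_equal(s$intensity, 123)
  s <- generate_relaxation_series(2.0, 0.5, i0 = 100)
  expect_equal(s$intensity, 100 * exp(-1))
  # the R2 delay series is accepted as-is
  d <- c(16.96, 33.92, 50.88, 67.84, 84.8, 101.76, 118.72, 135.68,
         203.52, 237.44) / 1000
  expect_silent(generate_relaxation_series(12, d))
})

test_that("titration generator follows the quadratic isotherm limits", {
  expect_equal(binding_isotherm(0, 50e-6, 2, 80e-6), 0)
  # stoichiometric limit: kd -> 0 with L0 >= P0 saturates at dw_max
  expect_equal(binding_isotherm(100e-6, 1e-12, 2, 80e-6), 2,
               tolerance = 1e-5)
  # and is piecewise linear below saturation: L0 = P0/2 gives dw_max/2
  expect_equal(binding_isotherm(40e-6, 1e-12, 2, 80e-6), 1,
               tolerance = 1e-3)
  tit <- generate_titration_shifts(50e-6, 2)
  expect_equal(attr(tit, "p_total"), 80e-6)
  expect_true(all(tit$l0_m >= 4.99e-6 & tit$l0_m <= 5.01e-4))
})

test_that("temperature-shift generator is exact when noiseless", {
  s <- generate_temp_shift_series(0, c(298, 303, 308))
  expect_equal(diff(range(s$h_ppm)), 0)
  s <- generate_temp_shift_series(-7, seq(298, 308, 2.5))
  tc <- temperature_coefficient(s)
  expect_equal(tc$slope_ppb_k, -7, tolerance = 1e-9)
})

test_that("hollow-shell fixture records the analytic cavity volume", {
  sc <- generate_hollow_structure(8)
  expect_equal(attr(sc, "true_cavity_volume"), 4 / 3 * pi * 512)
  # 8.4 A radius lands in the 2000-3000 A^3 range typical of PR-10 cavities
  sc2 <- generate_hollow_structure(8.4)
  expect_gt(attr(sc2, "true_cavity_volume"), 2000)
  expect_lt(attr(sc2, "true_cavity_volume"), 3000)
  expect_error(generate_hollow_structure(8, packing_spacing = 6), "leaky")
  expect_error(generate_hollow_structure(8, outer_radius = 10),
               "outer_radius")
})
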