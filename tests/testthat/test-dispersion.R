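test_that("intensity-to-rate conversion matches hand-inverted values", {
  tab <- peak_intensity_table(data.frame(
    residue_id = "R01", field_mhz = 500, temp_k = 298,
    condition = c("reference", "cpmg", "cpmg"),
    nu_cpmg_hz = c(NA, 100, 500),
    intensity = c(100, 100 * exp(-0.3), 100)))
  disp <- r2eff_from_intensities(tab, t_relax = 0.030, noise_sd = 1)
  expect_equal(disp$r2eff[disp$nu_cpmg_hz == 100], 10.0, tolerance = 1e-12)
  # identical intensities carry no relaxation
  expect_equal(disp$r2eff[disp$nu_cpmg_hz == 500], 0.0, tolerance = 1e-12)
  # noise-propagated error: sigma / (t_relax * I(500 Hz))
  expect_equal(disp$r2eff_err[disp$nu_cpmg_hz == 100], 1 / (0.030 * 100),
               tolerance = 1e-12)
})

test_that("missing or duplicated reference rows are hard errors", {
  tab <- data.frame(residue_id = "R01", field_mhz = 500, temp_k = 298,
                    condition = "cpmg", nu_cpmg_hz = 100, intensity = 50)
  expect_error(r2eff_from_intensities(tab), "reference")
  tab2 <- rbind(tab, data.frame(residue_id = "R01", field_mhz = 500,
                                temp_k = 298, condition = "reference",
                                nu_cpmg_hz = NA, intensity = -1))
  expect_error(r2eff_from_intensities(tab2), "positive")
})

test_that("non-positive CPMG intensities are flagged, not dropped silently", {
  tab <- peak_intensity_table(data.frame(
    residue_id = "R01", field_mhz = 500, temp_k = 298,
    condition = c("reference", "cpmg", "cpmg"),
    nu_cpmg_hz = c(NA, 100, 500), intensity = c(100, -5, 90)))
  expect_warning(disp <- r2eff_from_intensities(tab), "invalid")
  expect_true(is.na(disp$r2eff[disp$nu_cpmg_hz == 100]))
  expect_false(is.na(disp$r2eff[disp$nu_cpmg_hz == 500]))
})

test_that("rate errors follow the noise formula with a 3 percent floor", {
  # sigma/(T * I500) dominates: 1/(0.03*100) = 0.333
  expect_equal(r2eff_error(1, 100, 0.03, 5), 1 / 3, tolerance = 1e-12)
  # floor dominates at zero noise
  expect_equal(r2eff_error(0, 100, 0.03, 10), 0.3)
  # every emitted error respects the floor
  truth <- generate_two_state_system(n_residues = 3, seed = 8)
  tab <- generate_dispersion_intensities(truth, seed = 8)
  disp <- r2eff_from_intensities(tab, noise_sd = 0.03 * 1e6)
  ok <- is.finite(disp$r2eff)
  expect_true(all(disp$r2eff_err[ok] >= 0.03 * abs(disp$r2eff[ok]) - 1e-12))
})

test_that("dispersion model reduces to the intrinsic rate without exchange", {
  nu <- default_nu_cpmg()
  expect_equal(bm_r2eff(50, 900, 0, 12, nu), rep(12, 12), tolerance = 1e-10)
  expect_equal(carver_richards_r2eff(50, 900, 0, 12, nu), rep(12, 12))
  # vanishing minor state: no exchange contribution
  expect_equal(bm_r2eff(1e-4, 1000, ppm_to_rad(2, 500), 9, nu),
               rep(9, 12), tolerance = 1e-4)
  # full refocusing at very high pulsing rate
  expect_equal(carver_richards_r2eff(69, 743, ppm_to_rad(2, 500), 10, 1e5),
               10, tolerance = 1e-3)
})

test_that("dispersion curves decrease monotonically with pulsing frequency", {
  nu <- default_nu_cpmg()
  for (kex in c(200, 812, 3000)) for (pb in c(0.02, 0.085)) {
    for (dwppm in c(1, 3)) {
      r <- bm_r2eff(pb * kex, (1 - pb) * kex, ppm_to_rad(dwppm, 700), 10, nu)
      expect_true(all(diff(r) < 1e-8))
    }
  }
})

test_that("fast-exchange limit matches Luz-Meiboom within 5 percent", {
  nu <- default_nu_cpmg()
  for (kex in c(2000, 5000)) for (pb in c(0.02, 0.085)) {
    dw <- ppm_to_rad(0.5, 500)
    expect_true(kex >= 10 * dw)
    b <- bm_r2eff(pb * kex, (1 - pb) * kex, dw, 10, nu)
    l <- luz_meiboom_r2eff(pb * kex, (1 - pb) * kex, dw, 10, nu)
    expect_lt(max(abs(b - l) / pmax(l, 1)), 0.05)
  }
})

test_that("exchange filter keeps dispersing residues and drops flat ones", {
  # hand-built: residues with dw = 0 are flat, dw = 3 ppm disperse strongly
  nu <- default_nu_cpmg()
  rows <- do.call(rbind, lapply(1:6, function(i) {
    dw <- if (i <= 3) 0 else 3
    r2 <- bm_r2eff(69, 743, ppm_to_rad(dw, 500), 10, nu)
    data.frame(residue_id = sprintf("R%02d", i), field_mhz = 500,
               temp_k = 298, nu_cpmg_hz = nu, r2eff = r2,
               r2eff_err = pmax(0.03 * r2, 0.3))
  }))
  ds <- dispersion_dataset(rows)
  sel <- select_exchange_residues(ds)
  expect_setequal(sel$retained, c("R04", "R05", "R06"))
  # threshold is strict: delta exactly at threshold is not retained
  flat <- sel$delta_table[sel$delta_table$residue_id == "R01", ]
  expect_lt(flat$delta_r2eff, 5)
})

test_that("overlap-tagged residues are excluded regardless of dispersion", {
  nu <- default_nu_cpmg()
  r2 <- bm_r2eff(69, 743, ppm_to_rad(3, 500), 10, nu)
  rows <- data.frame(residue_id = "R01", field_mhz = 500, temp_k = 298,
                     nu_cpmg_hz = nu, r2eff = r2,
                     r2eff_err = pmax(0.03 * r2, 0.3))
  ds <- dispersion_dataset(rows,
                           excluded = data.frame(residue_id = "R01",
                                                 reason = "overlap"))
  expect_equal(nrow(ds), 0)
})
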