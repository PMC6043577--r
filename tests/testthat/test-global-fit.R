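test_that("chi-square vanishes at the generating truth on noiseless data", {
  fx <- small_noiseless_dataset()
  expect_lt(chi_square(params_from_truth(fx$truth), fx$dataset), 1e-12)
})

test_that("chi-square increases under any parameter perturbation", {
  fx <- small_noiseless_dataset()
  p0 <- params_from_truth(fx$truth)
  base <- chi_square(p0, fx$dataset)
  p1 <- p0; p1$r20[1, 1] <- p1$r20[1, 1] + 1
  expect_gt(chi_square(p1, fx$dataset), base + 1)
  p2 <- p0; p2$dw_ppm[2] <- p2$dw_ppm[2] * 1.2
  expect_gt(chi_square(p2, fx$dataset), base)
})

test_that("chi-square equals the explicit error-weighted sum", {
  # 2 residues, 1 field, 3 points, evaluated by hand
  nu <- c(133.3, 400, 1000)
  p <- two_state_params(
    data.frame(temp_k = 298, p_b = 0.08, k_ab = 60),
    c(R01 = 1.5, R02 = 2.5),
    matrix(c(11, 14), 2, 1, dimnames = list(c("R01", "R02"), "500")))
  rows <- do.call(rbind, lapply(1:2, function(i) {
    data.frame(residue_id = sprintf("R%02d", i), field_mhz = 500,
               temp_k = 298, nu_cpmg_hz = nu,
               r2eff = c(20, 15, 12) + i, r2eff_err = c(0.5, 0.6, 0.7))
  }))
  ds <- dispersion_dataset(rows)
  by_hand <- 0
  for (i in 1:2) {
    calc <- bm_r2eff(60, 60 * 0.92 / 0.08,
                     ppm_to_rad(p$dw_ppm[i], 500), p$r20[i, 1], nu)
    by_hand <- by_hand +
      sum(((calc - (c(20, 15, 12) + i)) / c(0.5, 0.6, 0.7))^2)
  }
  expect_equal(chi_square(p, ds), by_hand, tolerance = 1e-12)
})

test_that("missing parameter entries are reported by residue", {
  fx <- small_noiseless_dataset()
  p <- params_from_truth(fx$truth)
  p$dw_ppm <- p$dw_ppm[-1]
  expect_error(chi_square(p, fx$dataset), "R01")
})

test_that("noiseless global fit recovers the generating parameters", {
  fx <- small_noiseless_dataset(n_residues = 5, seed = 13)
  fit <- fit_global(fx$dataset, seed = 13, n_starts = 2)
  kin <- fx$truth$kinetics
  expect_lt(max(abs(fit$params$per_temperature$k_ex - kin$k_ex) / kin$k_ex),
            1e-3)
  expect_lt(max(abs(fit$params$per_temperature$p_b - kin$p_b) / kin$p_b),
            1e-3)
  expect_lt(max(abs(fit$params$dw_ppm[names(fx$truth$dw_ppm)] -
                      fx$truth$dw_ppm)), 1e-3)
  expect_true(fit$converged)
  # optimum cannot be worse than the truth
  expect_lte(fit$chi2,
             chi_square(params_from_truth(fx$truth), fx$dataset) + 1e-8)
  expect_equal(fit$n_par, 2 * 5 + 5 + 5 * 2)
})

test_that("fit is invariant to residue relabeling and row order", {
  fx <- small_noiseless_dataset(n_residues = 4, seed = 21)
  d <- as.data.frame(fx$dataset)
  fit1 <- fit_global(fx$dataset, seed = 1, n_starts = 1)
  shuffled <- d[sample(nrow(d)), ]
  fit2 <- fit_global(dispersion_dataset(shuffled), seed = 1, n_starts = 1)
  expect_equal(fit1$chi2, fit2$chi2, tolerance = 1e-6)
  expect_equal(fit1$params$per_temperature$k_ex,
               fit2$params$per_temperature$k_ex, tolerance = 1e-4)
  # relabel residues (a permutation of names)
  relab <- setNames(c("Z9", "A1", "M5", "K2"), unique(d$residue_id))
  d2 <- d; d2$residue_id <- unname(relab[d$residue_id])
  fit3 <- fit_global(dispersion_dataset(d2), seed = 1, n_starts = 1)
  expect_equal(sort(unname(fit3$params$dw_ppm)),
               sort(unname(fit1$params$dw_ppm)), tolerance = 1e-4)
})

test_that("underdetermined fits are refused", {
  fx <- small_noiseless_dataset(n_residues = 1, seed = 2)
  one <- as.data.frame(fx$dataset)
  one <- one[one$temp_k == 298 & one$field_mhz == 500, ][1:4, ]
  expect_error(fit_global(dispersion_dataset(one)), "underdetermined")
})

test_that("per-temperature mode returns one independent fit per temperature", {
  fx <- small_noiseless_dataset(n_residues = 3, seed = 5)
  fits <- fit_global(fx$dataset, seed = 5, n_starts = 1,
                     per_temperature = TRUE)
  expect_s3_class(fits, "global_fit_per_temperature")
  expect_length(fits$per_temperature_fits, 5)
  f298 <- fits$per_temperature_fits[["298"]]
  expect_equal(f298$params$per_temperature$k_ex,
               fx$truth$kinetics$k_ex[1], tolerance = 0.01)
})

test_that("covariance uncertainties shrink to zero on noiseless data", {
  fx <- small_noiseless_dataset(n_residues = 4, seed = 17)
  fit <- fit_global(fx$dataset, seed = 17, n_starts = 1)
  unc <- estimate_uncertainties(fit, fx$dataset, method = "covariance")
  # noiseless data still carry the 3 percent error floor, so "zero" here
  # means far below the parameter scale
  expect_lt(max(unc$per_temperature$se_k_ex /
                  fit$params$per_temperature$k_ex), 0.02)
  expect_true(all(unc$dw_ppm >= 0))
})

test_that("bootstrap uncertainties are seed-deterministic and consistent", {
  truth <- generate_two_state_system(n_residues = 4, noise_fraction = 0.03,
                                     seed = 31)
  tab <- generate_dispersion_intensities(truth, seed = 31)
  ds <- r2eff_from_intensities(tab, noise_sd = 0.03 * 1e6)
  fit <- fit_global(ds, seed = 31, n_starts = 2)
  b1 <- estimate_uncertainties(fit, ds, method = "bootstrap", n_boot = 20,
                               seed = 7)
  b2 <- estimate_uncertainties(fit, ds, method = "bootstrap", n_boot = 20,
                               seed = 7)
  expect_identical(b1, b2)
  # same order of magnitude as the covariance estimate
  cv <- estimate_uncertainties(fit, ds, method = "covariance")
  ratio <- b1$per_temperature$se_k_ex / cv$per_temperature$se_k_ex
  expect_true(all(ratio > 0.2 & ratio < 5))
})
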